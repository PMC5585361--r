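make_scores <- function(i_by_channel) {
  do.call(rbind, lapply(names(i_by_channel), function(ch) {
    x <- i_by_channel[[ch]]
    data.frame(compound_id = sprintf("c%02d", seq_along(x)), channel = ch,
               i_score = x, stringsAsFactors = FALSE)
  }))
}

test_that("Z-transform standardizes per channel under both SD conventions", {
  sc <- make_scores(list(GFP = c(0.5, 1.0, 1.5)))
  # sample-SD convention (default)
  z <- z_transform(sc)$z_score
  expect_equal(z, c(-1, 0, 1))
  # population-SD convention
  zp <- z_transform(sc, sd_convention = "population")$z_score
  expect_equal(zp, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(zp[2], 0)

  # standardization invariants over scored compounds in a channel
  set.seed(5)
  sc2 <- make_scores(list(GFP = runif(50), RFP = runif(50)))
  z2 <- z_transform(sc2)
  for (ch in c("GFP", "RFP")) {
    zc <- z2$z_score[z2$channel == ch]
    expect_equal(mean(zc), 0, tolerance = 1e-9)
    expect_equal(sd(zc), 1, tolerance = 1e-9)
  }

  # location invariance: shifting all I-scores leaves Z unchanged
  sc3 <- sc2; sc3$i_score <- sc3$i_score + 0.37
  expect_equal(z_transform(sc3)$z_score, z2$z_score, tolerance = 1e-12)

  expect_error(z_transform(make_scores(list(GFP = c(1, 1)))), ">= 3")
  expect_error(z_transform(make_scores(list(GFP = c(1, 1, 1)))), "degenerate")
})

test_that("classification reproduces the three threshold rules", {
  expect_equal(classify_hit(-2.5, -2.5), "dual_toxic")
  expect_equal(classify_hit(0, -1.5), "met_selective")
  expect_equal(classify_hit(-1.5, 0), "pri_selective")
  expect_equal(classify_hit(-0.7, -0.7), "unclassified")
  # boundary probes: thresholds are strict inequalities
  expect_equal(classify_hit(-2.4, -2.4), "unclassified")
  expect_equal(classify_hit(-0.5, -1.1), "unclassified")
  expect_equal(classify_hit(-0.499999, -1.0001), "met_selective")
  # between the dual and kill thresholds in one channel, deep in the other:
  # no published rule fires
  expect_equal(classify_hit(-3, -1.5), "unclassified")
  expect_error(classify_hit(NA_real_, 0), "finite")
})

test_that("categories partition the Z plane and respect region disjointness", {
  set.seed(31)
  z1 <- rnorm(10000, 0, 2); z2 <- rnorm(10000, 0, 2)
  cat <- classify_hit(z1, z2)
  expect_true(all(cat %in% c("dual_toxic", "met_selective", "pri_selective",
                             "unclassified")))
  # dual and selective regions are disjoint by their defining inequalities
  dual <- z1 < -2.4 & z2 < -2.4
  met <- z2 < -1 & z1 > -0.5
  pri <- z1 < -1 & z2 > -0.5
  expect_false(any(dual & met) || any(dual & pri) || any(met & pri))
  expect_equal(cat[dual], rep("dual_toxic", sum(dual)))
  expect_equal(cat[met], rep("met_selective", sum(met)))
  expect_equal(cat[pri], rep("pri_selective", sum(pri)))
  expect_equal(cat[!(dual | met | pri)],
               rep("unclassified", sum(!(dual | met | pri))))
})

test_that("hit calling is affine-invariant in raw per-channel signals", {
  sim <- simulate_coculture_screen(96, planted = planted_selective_hits(
    96, n_met = 3, n_pri = 3), seed = 8)
  calls <- call_hits(sim$dataset)

  # rescale each channel's raw signals by a different positive gain
  ds2 <- sim$dataset
  gain <- c(GFP = 3.7, RFP = 0.21)
  ds2$wells$signal <- ds2$wells$signal * gain[ds2$wells$channel]
  calls2 <- call_hits(ds2)
  expect_equal(calls2$z_gfp, calls$z_gfp, tolerance = 1e-9)
  expect_identical(calls2$category, calls$category)
})

test_that("channel swap exchanges the selective labels exactly", {
  sim <- simulate_coculture_screen(96, planted = planted_selective_hits(
    96, n_met = 3, n_pri = 3), seed = 8)
  calls <- call_hits(sim$dataset)
  swapped <- call_hits(sim$dataset, gfp_channel = "RFP", rfp_channel = "GFP")
  m <- merge(as.data.frame(calls), as.data.frame(swapped),
             by = "compound_id", suffixes = c("", ".sw"))
  expect_identical(m$category.sw[m$category == "met_selective"],
                   rep("pri_selective", sum(m$category == "met_selective")))
  expect_identical(m$category.sw[m$category == "pri_selective"],
                   rep("met_selective", sum(m$category == "pri_selective")))
  expect_identical(m$category.sw[m$category == "dual_toxic"],
                   m$category[m$category == "dual_toxic"])
})

test_that("call_hits recovers planted categories and handles inert screens", {
  # one-sided planting: the spared channel carries no effects, so its
  # Z-distribution is pure between-compound noise; a planted RFP kill is
  # always detected (z_rfp deep below -1) and is called met-selective
  # exactly when its GFP Z clears the spare threshold
  sim <- simulate_coculture_screen(384, planted = planted_selective_hits(
    384, n_met = 10, n_pri = 0, n_dual = 0, kill = 0.95), seed = 1234)
  calls <- call_hits(sim$dataset)
  planted <- sim$truth$compound_id[sim$truth$true_category == "met_selective"]
  expect_length(planted, 10)
  hit_rows <- calls[match(planted, calls$compound_id), ]
  expect_true(all(hit_rows$z_rfp < -1))
  expect_false(any(hit_rows$category %in% c("pri_selective", "dual_toxic")))
  expect_identical(hit_rows$category == "met_selective",
                   hit_rows$z_gfp > -0.5)
  expect_equal(sum(calls$category == "dual_toxic"), 0)

  # an all-inert screen has sd ~ noise only; nothing reaches the deep
  # selective thresholds with one channel spared
  sim0 <- simulate_coculture_screen(96, planted = NULL, seed = 5)
  calls0 <- call_hits(sim0$dataset)
  expect_true(all(sim0$truth$true_category == "unclassified"))

  # a one-channel dataset cannot be hit-called
  ds1 <- sim0$dataset
  ds1$wells <- ds1$wells[ds1$wells$channel == "GFP", ]
  expect_error(call_hits(ds1), "missing")
})
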