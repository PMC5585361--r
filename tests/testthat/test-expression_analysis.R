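test_that("background subtraction floors nonpositive values", {
  m <- matrix(c(100, 5, 50, 200), 2, 2)
  out <- background_subtract(m, background = 10, floor = 1)
  expect_equal(out[2, 1], 1)  # 5 - 10 floored
  expect_equal(out[1, 1], 90)
  expect_equal(attr(out, "n_floored"), 1)
})

test_that("quantile normalization maps columns onto the sorted-mean reference", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(10, 20, 30))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "s1"]), c(5.5, 11, 16.5))
  expect_equal(unname(out[, "s2"]), c(5.5, 11, 16.5))

  # output columns are exact permutations of one another
  set.seed(3)
  m2 <- matrix(rlnorm(500 * 4), 500, 4, dimnames = list(NULL, paste0("s", 1:4)))
  out2 <- quantile_normalize(m2)
  ref <- sort(out2[, 1])
  for (j in 2:4) expect_equal(sort(out2[, j]), ref)
  # rank order within each column is preserved
  for (j in 1:4) expect_equal(order(out2[, j]), order(m2[, j]))

  # duplicated column: already quantile-equal, output equals input
  m3 <- cbind(a = c(4, 1, 9), b = c(4, 1, 9))
  expect_equal(quantile_normalize(m3), m3)

  expect_error(quantile_normalize(m2[, 1, drop = FALSE]), ">= 2")
  expect_warning(quantile_normalize(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "constant")
})

test_that("pairwise Pearson concordance behaves at the extremes and at target r", {
  m <- cbind(x = c(1, 2, 3, 5), y = -c(1, 2, 3, 5), z = c(1, 2, 3, 5))
  res <- pairwise_pearson(m, rbind(c("x", "z"), c("x", "y")))
  expect_equal(res$r, c(1, -1))

  expect_warning(
    res0 <- pairwise_pearson(cbind(a = c(1, 1, 1), b = c(1, 2, 3)),
                             rbind(c("a", "b"))),
    "zero-variance")
  expect_true(is.na(res0$r))

  # triplet generated at target r = 0.9: observed r within +/- 0.03
  mat <- simulate_concordant_samples(n_probes = 10000, r_target = 0.9, seed = 77)
  res9 <- pairwise_pearson(mat, rbind(c("tumour", "PDX"), c("tumour", "PDC"),
                                      c("PDX", "PDC")))
  expect_true(all(abs(res9$r - 0.9) < 0.03))
})

test_that("fold-change selection uses strict more-than-fold boundaries", {
  m <- cbind(a1 = c(1, 1, 1), a2 = c(1, 1, 1),
             b1 = c(2.01, 2.0, 0.49), b2 = c(2.01, 2.0, 0.49))
  rownames(m) <- c("p1", "p2", "p3")
  d <- differential_probes(m, c("a1", "a2"), c("b1", "b2"), fold = 2)
  expect_equal(d$probe, c("p1", "p3"))
  expect_equal(d$direction, c("up", "down"))  # 2.0 exactly is excluded

  # identical groups select nothing
  expect_equal(nrow(differential_probes(m, c("a1", "a2"), c("a1", "a2"))), 0)

  # label symmetry: up(A,B) equals down(B,A)
  set.seed(8)
  m2 <- matrix(rlnorm(200 * 4), 200, 4,
               dimnames = list(sprintf("p%03d", 1:200), c("a1", "a2", "b1", "b2")))
  ab <- differential_probes(m2, c("a1", "a2"), c("b1", "b2"))
  ba <- differential_probes(m2, c("b1", "b2"), c("a1", "a2"))
  expect_setequal(ab$probe[ab$direction == "up"], ba$probe[ba$direction == "down"])
  expect_setequal(ab$probe[ab$direction == "down"], ba$probe[ba$direction == "up"])

  expect_warning(differential_probes(rbind(m, z = c(0, 0, 1, 1))[, , drop = FALSE],
                                     c("a1", "a2"), c("b1", "b2")),
                 "zero")
})

test_that("planted differential probes are recovered from noisy data", {
  sim <- simulate_expression_study(n_probes = 5000, n_planted = 50,
                                   planted_fold = 4, noise_cv = 0.1, seed = 21)
  norm <- quantile_normalize(sim$matrix)
  d <- differential_probes(norm, names(sim$groups)[sim$groups == "A"],
                           names(sim$groups)[sim$groups == "B"], fold = 2)
  up <- d$probe[d$direction == "up"]
  expect_gte(length(intersect(up, sim$truth$planted_probes)), 48)
  expect_lte(length(setdiff(up, sim$truth$planted_probes)), 5)
})

test_that("Fisher overrepresentation matches hand-enumerated tails", {
  u <- sprintf("g%02d", 1:10)
  res <- fisher_enrichment(u[1:5], u[1:5], u)
  expect_equal(res$p_value, 1 / 252)
  expect_equal(res$k, 5)

  # zero overlap with positive expectation: tail covers everything
  res0 <- fisher_enrichment(u[1:5], u[6:10], u)
  expect_equal(res0$p_value, 1)

  # genes outside the universe are ignored
  res2 <- fisher_enrichment(u[1:5], c(u[1:5], "zz"), u)
  expect_equal(res2$m, 5)

  expect_error(fisher_enrichment("g1", "g1", character(0)), "empty universe")
})

test_that("Fisher p equals the exhaustive enumeration and fisher.test for N <= 30", {
  for (N in c(5, 12, 30)) {
    u <- sprintf("g%03d", seq_len(N))
    for (m in c(1, N %/% 3, N - 1)) {
      for (n in c(1, N %/% 2)) {
        for (k in max(0, n + m - N):min(m, n)) {
          sel <- u[seq_len(n)]
          set <- c(u[seq_len(k)], rev(u)[seq_len(m - k)])
          res <- fisher_enrichment(sel, set, u)
          expect_equal(res$k, k)
          expect_equal(res$p_value, oracle_hypergeom_tail(k, m, n, N),
                       tolerance = 1e-12)
          ft <- fisher.test(matrix(c(k, n - k, m - k, N - n - m + k), 2),
                            alternative = "greater")
          expect_equal(res$p_value, ft$p.value, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("BH adjustment is monotone and bounded below by p", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  p <- runif(200)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
})

test_that("enrichment of a planted gene set is detected with FDR control", {
  sim <- simulate_expression_study(n_probes = 5000, n_planted = 50,
                                   planted_fold = 4, noise_cv = 0.1, seed = 21)
  norm <- quantile_normalize(sim$matrix)
  d <- differential_probes(norm, names(sim$groups)[sim$groups == "A"],
                           names(sim$groups)[sim$groups == "B"], fold = 2)
  res <- enrich_sets(d$probe, sim$collection)
  expect_true(res$significant[res$set_name == "PLANTED_SET"])
  expect_true(res$q_value[res$set_name == "PLANTED_SET"] < 1e-10)
  expect_false(any(res$significant[grepl("DECOY", res$set_name)]))
  expect_true(all(res$q_value >= res$p_value))
})

test_that("averaged-reference signatures flag only the elevated line", {
  # strict boundary: reference {1,1,4} -> 2.0; the 4-line is exactly 2-fold
  m <- matrix(c(1, 1, 4), 1, 3, dimnames = list("p1", c("l1", "l2", "l3")))
  gsc <- gene_set_collection(list(S = "p1"), "p1")
  out <- met_reference_signatures(m, gsc)
  expect_length(out$l3$elevated_probes, 0)

  # identical lines: nothing elevated anywhere
  m2 <- matrix(5, 10, 3, dimnames = list(sprintf("p%02d", 1:10),
                                         c("l1", "l2", "l3")))
  gsc2 <- gene_set_collection(list(S = sprintf("p%02d", 1:5)), rownames(m2))
  out2 <- met_reference_signatures(m2, gsc2)
  expect_true(all(vapply(out2, function(x) length(x$elevated_probes) == 0, TRUE)))

  # one line with a set uniformly 4-fold up: that set significant there only
  set.seed(14)
  probes <- sprintf("p%04d", 1:2000)
  base <- rlnorm(2000, log(100), 1)
  mat <- sapply(1:5, function(i) base * rlnorm(2000, 0, 0.1))
  dimnames(mat) <- list(probes, sprintf("Met%d", 1:5))
  in_set <- probes[1:40]
  mat[in_set, 1] <- mat[in_set, 1] * 4
  gsc3 <- gene_set_collection(list(UP_SET = in_set,
                                   DECOY = probes[1001:1040]), probes)
  out3 <- met_reference_signatures(mat, gsc3)
  sig_lines <- vapply(out3, function(x) {
    e <- x$enrichment
    isTRUE(e$significant[e$set_name == "UP_SET"])
  }, TRUE)
  expect_identical(unname(sig_lines), c(TRUE, FALSE, FALSE, FALSE, FALSE))
})
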