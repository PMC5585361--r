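#' Simulate a two-channel co-culture screen with planted effects
#'
#' Emulates a dual-fluorescence co-culture screen: two isogenic lines, one
#' per fluorescence channel, grown together in 384-well plates with DMSO
#' control wells on every plate. Each compound has a per-channel kill
#' fraction; the well signal is
#' `control_mean * (1 - kill) * (1 + eps)`, `eps ~ Normal(0, noise_sd)`,
#' and DMSO wells are `control_mean * (1 + eps)`. Plates hold
#' `384 - n_dmso` compound wells each and are filled in compound order.
#'
#' The returned truth table carries each compound's intended hit category:
#' the hit-calling rules applied to the noise-free effect sizes.
#'
#' @param n_compounds Number of library compounds.
#' @param planted data.frame `compound_id`, `kill_gfp`, `kill_rfp` with kill
#'   fractions in \[0, 1\]; compounds not listed are inert. `NULL` plants
#'   nothing.
#' @param control_mean Control fluorescence mean, arbitrary units (both
#'   channels), default 10000.
#' @param noise_sd Multiplicative noise SD as a fraction of the noise-free
#'   signal, default 0.05.
#' @param n_dmso DMSO control wells per plate per channel, default 16.
#' @param layout A [screen_layout()].
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List: `dataset` (a [screen_dataset()]) and `truth` (data.frame
#'   `compound_id`, `kill_gfp`, `kill_rfp`, `true_category`).
#' @export
simulate_coculture_screen <- function(n_compounds = 384, planted = NULL,
                                      control_mean = 10000, noise_sd = 0.05,
                                      n_dmso = 16, layout = screen_layout(),
                                      seed = 1L) {
  stopifnot(n_compounds >= 3, noise_sd >= 0, control_mean > 0,
            n_dmso >= layout$min_dmso_wells)
  set.seed(seed)
  ids <- sprintf("CPD%04d", seq_len(n_compounds))
  kill <- matrix(0, n_compounds, 2, dimnames = list(ids, c("GFP", "RFP")))
  if (!is.null(planted)) {
    stopifnot(all(c("compound_id", "kill_gfp", "kill_rfp") %in% names(planted)))
    if (any(planted$kill_gfp < 0 | planted$kill_gfp > 1 |
            planted$kill_rfp < 0 | planted$kill_rfp > 1)) {
      stop("kill fractions must lie in [0, 1]")
    }
    idx <- match(planted$compound_id, ids)
    if (any(is.na(idx))) stop("planted compound id(s) not in library")
    kill[idx, "GFP"] <- planted$kill_gfp
    kill[idx, "RFP"] <- planted$kill_rfp
  }

  per_plate <- 384L - n_dmso
  n_plates <- ceiling(n_compounds / per_plate)
  all_wells <- as.vector(outer(LETTERS[1:16], 1:24,
                               function(r, c) sprintf("%s%02d", r, c)))
  rows <- vector("list", n_plates * 2L)
  ri <- 0L
  for (p in seq_len(n_plates)) {
    on_plate <- ids[((p - 1L) * per_plate + 1L):min(p * per_plate, n_compounds)]
    wells <- all_wells[seq_len(length(on_plate) + n_dmso)]
    cmpd <- c(rep(layout$dmso_sentinel, n_dmso), on_plate)
    for (ch in c("GFP", "RFP")) {
      k <- c(rep(0, n_dmso), kill[on_plate, ch])
      mu <- control_mean * (1 - k)
      sig <- pmax(mu * (1 + stats::rnorm(length(mu), 0, noise_sd)), 0)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        plate_id = sprintf("P%02d", p), well = wells, compound_id = cmpd,
        concentration = NA_real_, channel = ch, signal = sig,
        role = ifelse(cmpd == layout$dmso_sentinel, "dmso_control", "compound"),
        stringsAsFactors = FALSE)
    }
  }
  wells_tab <- do.call(rbind, rows)
  ds <- screen_dataset(wells_tab, layout = layout)

  # intended categories: hit rules applied to the noise-free I-scores; a
  # channel with no planted effect is flat (sd 0) and contributes Z = 0
  i0 <- 1 - kill
  z0 <- apply(i0, 2L, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  truth <- data.frame(compound_id = ids,
                      kill_gfp = kill[, "GFP"], kill_rfp = kill[, "RFP"],
                      true_category = classify_hit(z0[, "GFP"], z0[, "RFP"]),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(dataset = ds, truth = truth)
}

#' Default planted selective-hit layout for a screen simulation
#'
#' Plants `n_met` metastatic-selective, `n_pri` primary-selective and
#' `n_dual` dual-toxic compounds at the given kill fraction, spread evenly
#' through the library.
#'
#' @param n_compounds Library size.
#' @param n_met,n_pri,n_dual Planted compounds per category.
#' @param kill Kill fraction in the targeted channel(s), default 0.95.
#' @return data.frame suitable for [simulate_coculture_screen()]'s `planted`.
#' @export
planted_selective_hits <- function(n_compounds = 384, n_met = 10, n_pri = 10,
                                   n_dual = 0, kill = 0.95) {
  n_hits <- n_met + n_pri + n_dual
  stopifnot(n_hits <= n_compounds)
  pos <- round(seq(1, n_compounds, length.out = n_hits))
  ids <- sprintf("CPD%04d", pos)
  cat <- rep(c("met", "pri", "dual"), c(n_met, n_pri, n_dual))
  data.frame(compound_id = ids,
             kill_gfp = ifelse(cat %in% c("pri", "dual"), kill, 0),
             kill_rfp = ifelse(cat %in% c("met", "dual"), kill, 0),
             stringsAsFactors = FALSE)
}

#' Simulate a dose-response viability series from 4PL truth
#'
#' Three-fold dilution ladder from a top dose, measured in replicate;
#' viability is the 4PL curve plus Gaussian noise in percentage points.
#'
#' @param top,bottom,hill,ic50 True 4PL parameters (`ic50` in molar units).
#' @param top_dose Highest tested dose in molar units (default 10 uM).
#' @param n_dilutions Number of doses in the 3-fold ladder, default 9.
#' @param dilution_factor Dilution step, default 3.
#' @param n_replicates Replicates per dose, default 3.
#' @param noise_sd Gaussian noise SD in viability percentage points.
#' @param seed Integer seed.
#' @return List: `series` (a [dose_series()]) and `truth` (named list of the
#'   generating parameters).
#' @export
simulate_dose_response <- function(top = 100, bottom = 0, hill = 1,
                                   ic50 = 1e-7, top_dose = 1e-5,
                                   n_dilutions = 9, dilution_factor = 3,
                                   n_replicates = 3, noise_sd = 5,
                                   seed = 1L) {
  stopifnot(noise_sd >= 0, ic50 > 0, top_dose > 0, n_dilutions >= 4)
  set.seed(seed)
  doses <- top_dose / dilution_factor^(seq_len(n_dilutions) - 1)
  doses <- sort(doses)
  d <- rep(doses, each = n_replicates)
  v <- fourpl(d, top, bottom, hill, ic50) +
    stats::rnorm(length(d), 0, noise_sd)
  list(series = dose_series(d, v),
       truth = list(top = top, bottom = bottom, hill = hill, ic50 = ic50,
                    top_dose = top_dose, noise_sd = noise_sd))
}

#' Simulate a two-condition expression study with planted gene-set signal
#'
#' Log-normal baseline intensities per probe; designated probes —
#' concentrated in a designated gene set — are raised `planted_fold`-fold in
#' group B; multiplicative log-normal noise at the given coefficient of
#' variation. Probe ids double as gene ids (1:1 mapping). A decoy gene-set
#' collection is built alongside: the planted set plus `n_decoy_sets` random
#' sets of the same size.
#'
#' @param n_probes Number of probes/genes, default 5000.
#' @param n_per_group Samples per condition, default 3.
#' @param n_planted Probes raised in group B, default 50.
#' @param planted_fold True fold elevation, default 4.
#' @param noise_cv Multiplicative noise coefficient of variation, default 0.1.
#' @param n_decoy_sets Random same-size decoy sets, default 20.
#' @param seed Integer seed.
#' @return List: `matrix` (probe x sample), `groups` (named vector A/B),
#'   `collection` ([gene_set_collection()], planted set named
#'   `"PLANTED_SET"`), `truth` (planted probe ids and fold).
#' @export
simulate_expression_study <- function(n_probes = 5000, n_per_group = 3,
                                      n_planted = 50, planted_fold = 4,
                                      noise_cv = 0.1, n_decoy_sets = 20,
                                      seed = 1L) {
  stopifnot(n_planted < n_probes, noise_cv >= 0, planted_fold > 1)
  set.seed(seed)
  probes <- sprintf("G%05d", seq_len(n_probes))
  base <- stats::rlnorm(n_probes, meanlog = log(200), sdlog = 1)
  planted <- sample(probes, n_planted)
  n_s <- 2L * n_per_group
  groups <- stats::setNames(rep(c("A", "B"), each = n_per_group),
                            paste0(rep(c("A", "B"), each = n_per_group),
                                   seq_len(n_per_group)))
  sdlog <- sqrt(log(1 + noise_cv^2))
  mat <- matrix(0, n_probes, n_s, dimnames = list(probes, names(groups)))
  for (j in seq_len(n_s)) {
    mu <- base
    if (groups[j] == "B") mu[probes %in% planted] <- mu[probes %in% planted] * planted_fold
    mat[, j] <- mu * stats::rlnorm(n_probes, -sdlog^2 / 2, sdlog)
  }
  sets <- c(list(PLANTED_SET = planted),
            stats::setNames(lapply(seq_len(n_decoy_sets), function(i)
              sample(probes, n_planted)),
              sprintf("DECOY_SET_%02d", seq_len(n_decoy_sets))))
  list(matrix = mat, groups = groups,
       collection = gene_set_collection(sets, probes),
       truth = list(planted_probes = planted, planted_fold = planted_fold))
}

#' Simulate correlated expression profiles at a target Pearson r
#'
#' Builds paired samples as shared signal plus independent noise with the
#' variance split chosen analytically so the expected Pearson correlation of
#' each pair equals `r_target`.
#'
#' @param n_probes Number of probes, default 10000.
#' @param n_samples Number of mutually concordant samples, default 3
#'   (tumour / xenograft / culture triplet).
#' @param r_target Target pairwise Pearson r, default 0.9.
#' @param seed Integer seed.
#' @return Probe x sample matrix.
#' @export
simulate_concordant_samples <- function(n_probes = 10000, n_samples = 3,
                                        r_target = 0.9, seed = 1L) {
  stopifnot(r_target > 0, r_target < 1)
  set.seed(seed)
  shared <- stats::rnorm(n_probes, 0, sqrt(r_target))
  mat <- vapply(seq_len(n_samples), function(j)
    shared + stats::rnorm(n_probes, 0, sqrt(1 - r_target)),
    numeric(n_probes))
  colnames(mat) <- c("tumour", "PDX", "PDC", paste0("S", seq_len(n_samples)))[seq_len(n_samples)]
  rownames(mat) <- sprintf("G%05d", seq_len(n_probes))
  mat
}

#' Simulate a two-arm xenograft growth study
#'
#' Tumour volumes follow exponential growth
#' `V(t) = v0 * exp(rate_arm * t)` with multiplicative log-normal
#' measurement noise; caliper length and width are back-solved assuming the
#' tumour is measured with width = length/2, so the ellipsoidal volume
#' formula recovers the noisy volume exactly.
#'
#' @param n_per_arm Animals per arm, default 6.
#' @param v0 Day-0 volume in mm^3, default 100.
#' @param control_rate,treated_rate Exponential growth rates per day
#'   (defaults 0.25 and 0.05).
#' @param days Measurement days (caliper every 2 days by default).
#' @param measurement_cv Log-normal measurement coefficient of variation,
#'   default 0.05.
#' @param treated_label Arm label for the treated group.
#' @param seed Integer seed.
#' @return List: `records` (caliper table) and `truth` (rates and v0).
#' @export
simulate_growth_study <- function(n_per_arm = 6, v0 = 100,
                                  control_rate = 0.25, treated_rate = 0.05,
                                  days = seq(0, 10, by = 2),
                                  measurement_cv = 0.05,
                                  treated_label = "treated:drug", seed = 1L) {
  stopifnot(n_per_arm >= 2, v0 > 0, measurement_cv >= 0, 0 %in% days)
  set.seed(seed)
  sdlog <- if (measurement_cv > 0) sqrt(log(1 + measurement_cv^2)) else 0
  arms <- c(control = control_rate, stats::setNames(treated_rate, treated_label))
  rows <- list()
  for (a in names(arms)) {
    for (i in seq_len(n_per_arm)) {
      v_true <- v0 * exp(arms[[a]] * days)
      noise <- if (sdlog > 0) stats::rlnorm(length(days), -sdlog^2 / 2, sdlog) else 1
      v_obs <- v_true * noise
      len <- (8 * v_obs)^(1 / 3)          # V = L^3/8 when W = L/2
      rows[[paste(a, i)]] <- data.frame(
        animal_id = sprintf("%s_%02d", sub(":.*", "", a), i), arm = a,
        day = as.integer(days), length = len, width = len / 2,
        stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, rows),
       truth = list(v0 = v0, control_rate = control_rate,
                    treated_rate = treated_rate,
                    measurement_cv = measurement_cv))
}
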