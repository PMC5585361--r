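# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# Complete-linkage agglomeration by exhaustive search: at every step merge
# the two clusters whose maximum pairwise Euclidean member distance is
# smallest; return the sorted merge heights.
oracle_complete_linkage_heights <- function(mat) {
  clusters <- lapply(seq_len(nrow(mat)), identity)
  d <- as.matrix(stats::dist(mat, method = "euclidean"))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}

# One-sided overrepresentation tail by explicit combinatorial enumeration.
oracle_hypergeom_tail <- function(k, m, n, N) {
  j <- seq(k, min(m, n))
  sum(choose(m, j) * choose(N - m, n - j)) / choose(N, n)
}

# Pooled-variance two-sample t-test from first principles.
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

# Small valid well table builder: one plate, one or two channels.
make_well_table <- function(n_compounds = 8, n_dmso = 8,
                            channels = c("GFP", "RFP"),
                            control_mean = 10000, signals = NULL) {
  all_wells <- as.vector(outer(LETTERS[1:16], 1:24,
                               function(r, c) sprintf("%s%02d", r, c)))
  ids <- sprintf("CPD%04d", seq_len(n_compounds))
  cmpd <- c(rep("DMSO", n_dmso), ids)
  wells <- all_wells[seq_along(cmpd)]
  do.call(rbind, lapply(channels, function(ch) {
    sig <- if (is.null(signals)) rep(control_mean, length(cmpd)) else signals[[ch]]
    data.frame(plate_id = "P01", well = wells, compound_id = cmpd,
               concentration = NA_real_, channel = ch, signal = sig,
               role = ifelse(cmpd == "DMSO", "dmso_control", "compound"),
               stringsAsFactors = FALSE)
  }))
}
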