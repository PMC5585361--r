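#' Background-subtract an intensity matrix
#'
#' Subtracts per-probe (or scalar) background control values; nonpositive
#' results are floored at a small positive constant so downstream log and
#' ratio operations stay defined.
#'
#' @param mat Probe x sample intensity matrix.
#' @param background Scalar, per-probe vector, or matrix of background values.
#' @param floor Positive flooring constant (arbitrary units), default 1.
#' @return Background-subtracted, floored matrix.
#' @export
background_subtract <- function(mat, background, floor = 1) {
  stopifnot(is.matrix(mat), floor > 0)
  out <- mat - background
  n_floored <- sum(out < floor)
  if (n_floored) out[out < floor] <- floor
  attr(out, "n_floored") <- n_floored
  out
}

#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' reference is the row-wise mean of the column-sorted values, and ties share
#' the mean of the reference values they span. After normalization every
#' column is an exact permutation of every other.
#'
#' @param mat Probe x sample matrix, >= 2 samples, all entries finite.
#' @return Quantile-normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2L) stop("quantile normalization needs >= 2 samples")
  if (any(!is.finite(mat))) stop("matrix entries must be finite")
  cst <- apply(mat, 2L, function(x) length(unique(x)) == 1L)
  if (any(cst)) {
    warning("constant column(s) mapped onto the reference distribution: ",
            paste(colnames(mat)[cst], collapse = ", "))
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Pearson concordance between paired samples
#'
#' Pearson product-moment correlation r over all paired probes, for
#' cross-model comparisons (patient tumour vs. PDX vs. PDC).
#'
#' @param mat Probe x sample matrix.
#' @param pairs Two-column matrix or data.frame of sample names/indices.
#' @return data.frame with columns `sample_a`, `sample_b`, `r`.
#' @export
pairwise_pearson <- function(mat, pairs) {
  stopifnot(is.matrix(mat))
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  res <- data.frame(sample_a = character(0), sample_b = character(0),
                    r = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (!(a %in% colnames(mat)) || !(b %in% colnames(mat))) {
      stop("pair references unknown sample(s): ", a, ", ", b)
    }
    xa <- mat[, a]; xb <- mat[, b]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
      warning("zero-variance sample in pair (", a, ", ", b,
              "); r undefined, reported NA")
      r <- NA_real_
    } else {
      r <- stats::cor(xa, xb, method = "pearson")
    }
    res[i, ] <- list(as.character(a), as.character(b), r)
  }
  res
}

#' Select differentially expressed probes by fold change
#'
#' Probes whose group-B to group-A ratio of mean linear-scale normalized
#' intensity is strictly greater than `fold` are flagged `up`, strictly
#' smaller than `1/fold` flagged `down` ("more than twofold" is a strict
#' inequality). Probes with a zero group-A mean are skipped with a warning.
#'
#' @param mat Probe x sample matrix of normalized intensities.
#' @param group_a,group_b Column names/indices of the two groups (A is the
#'   reference/denominator).
#' @param fold Fold-change threshold, default 2.
#' @return data.frame `probe`, `ratio`, `direction` (`"up"`/`"down"`),
#'   restricted to selected probes.
#' @export
differential_probes <- function(mat, group_a, group_b, fold = 2) {
  stopifnot(is.matrix(mat), fold > 1, length(group_a) >= 1, length(group_b) >= 1)
  ma <- rowMeans(mat[, group_a, drop = FALSE])
  mb <- rowMeans(mat[, group_b, drop = FALSE])
  probes <- rownames(mat)
  if (is.null(probes)) probes <- as.character(seq_len(nrow(mat)))
  zero <- ma == 0
  if (any(zero)) {
    warning(sum(zero), " probe(s) with zero reference-group mean skipped")
  }
  ratio <- ifelse(zero, NA_real_, mb / ma)
  dir <- ifelse(ratio > fold, "up", ifelse(ratio < 1 / fold, "down", NA))
  keep <- !is.na(dir)
  data.frame(probe = probes[keep], ratio = ratio[keep], direction = dir[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-sided Fisher overrepresentation test of a gene set
#'
#' Tests whether the overlap k between a selected gene list (size n) and a
#' gene set (size m within the universe of N measured genes) is larger than
#' expected under hypergeometric sampling; p is the upper tail
#' P(overlap >= k) of the 2x2 table's exact distribution (equivalent to a
#' one-sided Fisher exact test).
#'
#' @param selected Character vector of selected genes (subset of universe).
#' @param set Character vector, the gene set (intersected with universe).
#' @param universe Character vector of all measured genes.
#' @return data.frame row: `k`, `m`, `n`, `N`, `p_value`.
#' @export
fisher_enrichment <- function(selected, set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  selected <- unique(intersect(selected, universe))
  set <- unique(intersect(set, universe))
  k <- length(intersect(selected, set))
  m <- length(set); n <- length(selected); N <- length(universe)
  p <- stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
  data.frame(k = k, m = m, n = n, N = N, p_value = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @return Step-up adjusted q-values (monotone in p rank, each >= its p).
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# collapse selected probes to genes via the probe->gene map
probes_to_genes <- function(probes, probe_gene_map,
                            collapse = c("any", "all")) {
  collapse <- match.arg(collapse)
  if (is.null(probe_gene_map)) return(unique(probes))  # 1:1 probe = gene
  sel_genes <- unique(probe_gene_map$gene[probe_gene_map$probe %in% probes])
  if (collapse == "any") return(sel_genes)
  by_gene <- split(probe_gene_map$probe, probe_gene_map$gene)
  names(by_gene)[vapply(by_gene, function(p) all(p %in% probes), TRUE)]
}

#' Gene-set overrepresentation of a selected gene list
#'
#' Runs [fisher_enrichment()] for every set in a collection, adjusts p-values
#' by Benjamini-Hochberg, and calls significance at the configured threshold
#' on either the adjusted (default) or raw p-value.
#'
#' @param selected Selected genes.
#' @param collection A [gene_set_collection()].
#' @param alpha Significance threshold (default 0.05).
#' @param use_adjusted Threshold the FDR-adjusted q (default) or the raw p.
#' @return data.frame of class `enrichment_result`, one row per set:
#'   `set_name`, `k`, `m`, `n`, `N`, `p_value`, `q_value`, `significant`;
#'   the thresholding mode is recorded in attribute `"criterion"`.
#' @export
enrich_sets <- function(selected, collection, alpha = 0.05,
                        use_adjusted = TRUE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  rows <- lapply(names(collection$sets), function(nm) {
    cbind(set_name = nm,
          fisher_enrichment(selected, collection$sets[[nm]],
                            collection$universe),
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(set_name = character(0), k = integer(0), m = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0))
  }
  res$q_value <- fdr_adjust(res$p_value)
  res$significant <- if (use_adjusted) res$q_value < alpha else res$p_value < alpha
  res <- res[order(res$p_value, res$set_name), ]
  rownames(res) <- NULL
  attr(res, "criterion") <- list(alpha = alpha,
                                 on = if (use_adjusted) "q_value" else "p_value")
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Elevated-expression signatures against an averaged multi-line reference
#'
#' For a panel of metastatic PDC lines, the reference is the per-probe mean
#' of normalized expression across all lines. Probes strictly more than
#' `fold`-fold above the reference in a given line are that line's
#' "elevated" probes and are tested for gene-set overrepresentation.
#'
#' @param line_matrix Probe x line matrix of normalized expression (one
#'   column per metastatic line; >= 2 lines).
#' @param collection A [gene_set_collection()].
#' @param fold Elevation threshold (default 2, strict).
#' @param alpha,use_adjusted Passed to [enrich_sets()].
#' @param probe_gene_map Optional data.frame `probe`, `gene`; default treats
#'   probe ids as gene ids (1:1).
#' @return Named list per line: `elevated_probes` and `enrichment`.
#' @export
met_reference_signatures <- function(line_matrix, collection, fold = 2,
                                     alpha = 0.05, use_adjusted = TRUE,
                                     probe_gene_map = NULL) {
  stopifnot(is.matrix(line_matrix), ncol(line_matrix) >= 2L)
  reference <- rowMeans(line_matrix)
  zero <- reference == 0
  if (any(zero)) warning(sum(zero), " probe(s) with zero reference mean skipped")
  probes <- rownames(line_matrix)
  if (is.null(probes)) probes <- as.character(seq_len(nrow(line_matrix)))
  out <- list()
  for (ln in colnames(line_matrix)) {
    elev <- !zero & line_matrix[, ln] / ifelse(zero, NA, reference) > fold
    sel_genes <- probes_to_genes(probes[which(elev)], probe_gene_map)
    out[[ln]] <- list(elevated_probes = probes[which(elev)],
                      enrichment = enrich_sets(sel_genes, collection,
                                               alpha = alpha,
                                               use_adjusted = use_adjusted))
  }
  out
}
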