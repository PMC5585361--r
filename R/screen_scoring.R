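#' Inhibition score of a compound well
#'
#' Ratio of a compound well's signal to the median DMSO-control signal on the
#' same plate and channel: 1 means no effect, 0 complete kill, and values
#' above 1 indicate growth stimulation.
#'
#' @param signal Compound-well signal (arbitrary units, >= 0).
#' @param dmso_median Median DMSO-control signal (> 0).
#' @return Dimensionless I-score `signal / dmso_median`.
#' @examples
#' i_score(500, 2000)  # 0.25
#' @export
i_score <- function(signal, dmso_median) {
  if (any(!is.finite(dmso_median)) || any(dmso_median <= 0)) {
    stop("degenerate DMSO control: median must be positive and finite")
  }
  if (any(signal < 0)) stop("signal must be non-negative")
  signal / dmso_median
}

#' Percent inhibition from an I-score
#'
#' `(1 - I) * 100`. Negative values (growth stimulation, I > 1) are retained,
#' not clipped.
#'
#' @param i I-score(s), >= 0.
#' @return Percent inhibition.
#' @export
percent_inhibition <- function(i) {
  if (any(i < 0)) stop("I-score must be non-negative")
  (1 - i) * 100
}

# DMSO medians per plate/channel (scope = "plate") or one per channel
# across the whole screen (scope = "screen")
dmso_medians <- function(ds, scope = c("plate", "screen")) {
  scope <- match.arg(scope)
  ctrl <- ds$wells[ds$wells$role == "dmso_control", , drop = FALSE]
  if (scope == "plate") {
    stats::aggregate(signal ~ plate_id + channel, data = ctrl, FUN = stats::median)
  } else {
    med <- stats::aggregate(signal ~ channel, data = ctrl, FUN = stats::median)
    plates <- unique(ds$wells$plate_id)
    out <- expand.grid(plate_id = plates, channel = med$channel,
                       stringsAsFactors = FALSE)
    out$signal <- med$signal[match(out$channel, med$channel)]
    out
  }
}

#' Score a screen: per-compound inhibition by channel
#'
#' Each well is normalized to its plate/channel DMSO median (the I-score);
#' replicate wells of the same compound are then pooled by median (or mean).
#' Per-plate normalization before pooling absorbs plate-to-plate intensity
#' differences.
#'
#' @param ds A [screen_dataset()].
#' @param aggregate Replicate aggregator, `"median"` (default) or `"mean"`.
#' @param dmso_scope `"plate"` (default) computes the DMSO median per plate
#'   per channel; `"screen"` uses one median per channel across all plates.
#' @return data.frame of class `compound_scores` with one row per compound x
#'   channel: `compound_id`, `channel`, `line`, `n_wells`, `i_score`,
#'   `percent_inhibition`.
#' @export
score_screen <- function(ds, aggregate = c("median", "mean"),
                         dmso_scope = c("plate", "screen")) {
  stopifnot(inherits(ds, "screen_dataset"))
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "median") stats::median else mean
  med <- dmso_medians(ds, match.arg(dmso_scope))

  cw <- ds$wells[ds$wells$role == "compound", , drop = FALSE]
  idx <- match(paste(cw$plate_id, cw$channel),
               paste(med$plate_id, med$channel))
  cw$i <- i_score(cw$signal, med$signal[idx])

  untested <- setdiff(ds$compounds$compound_id, cw$compound_id)
  if (length(untested)) {
    warning("compound(s) with zero wells skipped: ",
            paste(utils::head(untested, 5), collapse = ", "))
  }
  grp <- interaction(cw$compound_id, cw$channel, drop = TRUE)
  pooled <- data.frame(
    compound_id = tapply(cw$compound_id, grp, `[[`, 1L),
    channel = tapply(cw$channel, grp, `[[`, 1L),
    n_wells = as.integer(tapply(cw$i, grp, length)),
    i_score = as.numeric(tapply(cw$i, grp, agg_fun)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pooled$line <- unname(ds$lines[pooled$channel])
  pooled$percent_inhibition <- percent_inhibition(pooled$i_score)
  pooled <- pooled[order(pooled$compound_id, pooled$channel),
                   c("compound_id", "channel", "line", "n_wells",
                     "i_score", "percent_inhibition")]
  rownames(pooled) <- NULL
  class(pooled) <- c("compound_scores", "data.frame")
  pooled
}

#' Compound-by-line percent-inhibition matrix with display mask
#'
#' Rows are compounds, columns cell lines, entries percent inhibition;
#' untested pairs are `NA`. The display mask flags entries below
#' `min_display` percent (shown grey in heat maps); when `filter` is on,
#' rows with no entry at or above the threshold are dropped so only
#' compounds with strong inhibition in at least one line remain.
#'
#' @param scores Output of [score_screen()] (possibly concatenated over
#'   several single-line screens).
#' @param min_display Display threshold in percent (default 50).
#' @param filter Drop rows with no entry >= `min_display`?
#' @return List of class `inhibition_matrix` with `matrix` and logical `mask`
#'   (`TRUE` = below threshold, displayed grey).
#' @export
inhibition_matrix <- function(scores, min_display = 50, filter = TRUE) {
  stopifnot(is.data.frame(scores),
            all(c("compound_id", "line", "percent_inhibition") %in% names(scores)))
  compounds <- sort(unique(scores$compound_id))
  lines <- sort(unique(scores$line))
  m <- matrix(NA_real_, nrow = length(compounds), ncol = length(lines),
              dimnames = list(compounds, lines))
  m[cbind(match(scores$compound_id, compounds),
          match(scores$line, lines))] <- scores$percent_inhibition
  if (filter) {
    keep <- apply(m, 1L, function(r) any(!is.na(r) & r >= min_display))
    m <- m[keep, , drop = FALSE]
  }
  mask <- !is.na(m) & m < min_display
  structure(list(matrix = m, mask = mask, min_display = min_display),
            class = "inhibition_matrix")
}

#' Cluster compound inhibition profiles
#'
#' Complete-linkage agglomerative clustering of compound rows on Euclidean
#' distances between their per-line inhibition profiles. Rows containing `NA`
#' are dropped with a warning. Ties between equal merge heights are broken
#' deterministically by row (compound id) order, and the returned leaf order
#' is the canonical recursive order from the merge tree.
#'
#' @param m An [inhibition_matrix()] or a plain numeric matrix.
#' @return List of class `profile_clustering`: `hclust` (a [stats::hclust]
#'   tree), `merges` (data.frame step/left/right/height), `leaf_order`
#'   (compound ids), `newick` (dendrogram as a Newick string).
#' @export
cluster_profiles <- function(m) {
  if (inherits(m, "inhibition_matrix")) m <- m$matrix
  stopifnot(is.matrix(m))
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    warning(sum(!complete), " profile(s) with missing entries dropped before clustering")
    m <- m[complete, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("clustering requires at least 2 complete profiles")
  m <- m[order(rownames(m)), , drop = FALSE]  # lexicographic tie-break base
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       left = hc$merge[, 1], right = hc$merge[, 2],
                       height = hc$height)
  structure(list(hclust = hc,
                 merges = merges,
                 leaf_order = hc$labels[hc$order],
                 newick = hclust_to_newick(hc)),
            class = "profile_clustering")
}

# Newick serialization of an hclust tree, branch lengths from merge heights
hclust_to_newick <- function(hc) {
  rec <- function(i, parent_h) {
    if (i < 0) {
      lab <- hc$labels[-i]
      sprintf("%s:%g", gsub("[,;:()\\s]", "_", lab, perl = TRUE), parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%g", rec(hc$merge[i, 1], h), rec(hc$merge[i, 2], h),
              parent_h - h)
    }
  }
  n <- nrow(hc$merge)
  h <- hc$height[n]
  paste0("(", rec(hc$merge[n, 1], h), ",", rec(hc$merge[n, 2], h), ");")
}
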