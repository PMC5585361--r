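#' Default hit-calling thresholds
#'
#' Dual toxicity requires both channels below the dual threshold (-2.4);
#' a selective hit requires the targeted channel below the kill threshold
#' (-1) while the other channel stays above the spare threshold (-0.5).
#'
#' @return Named numeric vector with elements `dual`, `kill`, `spare`.
#' @export
hit_thresholds <- function() c(dual = -2.4, kill = -1, spare = -0.5)

#' Z-score transform of per-channel I-scores
#'
#' For each channel, Z = (I - mean(I)) / sd(I) over the scored compounds of
#' that channel (DMSO wells are excluded from mean and sd by construction,
#' since only compound scores enter).
#'
#' @param scores A `compound_scores` data.frame from [score_screen()].
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"` (n denominator).
#' @return The input with a `z_score` column added, plus attribute `"params"`
#'   holding per-channel mean and sd.
#' @examples
#' \dontrun{z_transform(score_screen(ds))}
#' @export
z_transform <- function(scores, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  stopifnot(is.data.frame(scores),
            all(c("compound_id", "channel", "i_score") %in% names(scores)))
  params <- list()
  scores$z_score <- NA_real_
  for (ch in unique(scores$channel)) {
    idx <- scores$channel == ch
    x <- scores$i_score[idx]
    if (length(x) < 3L) stop("channel ", ch, ": need >= 3 scored compounds")
    mu <- mean(x)
    s <- stats::sd(x)
    if (sd_convention == "population") s <- s * sqrt((length(x) - 1) / length(x))
    if (!is.finite(s) || s <= 0) {
      stop("channel ", ch, ": degenerate I-score distribution (sd = 0)")
    }
    scores$z_score[idx] <- (x - mu) / s
    params[[ch]] <- c(mean = mu, sd = s)
  }
  attr(scores, "params") <- params
  scores
}

#' Classify a compound from its two channel Z-scores
#'
#' Three-way selective-toxicity rules on the (GFP, RFP) Z-score pair, GFP
#' reporting the primary-tumour line and RFP the metastatic line:
#' * `dual_toxic`: both Z below the dual threshold (-2.4);
#' * `met_selective`: RFP Z below the kill threshold (-1) while GFP Z stays
#'   above the spare threshold (-0.5);
#' * `pri_selective`: the mirror image (GFP Z < -1, RFP Z > -0.5);
#' * `unclassified` otherwise.
#' Rules are evaluated in that order; the dual and selective regions are
#' disjoint by construction (a selective call needs one Z above -0.5, a dual
#' call needs both below -2.4).
#'
#' @param z_gfp,z_rfp Finite Z-scores (vectorized).
#' @param thresholds Named vector as from [hit_thresholds()].
#' @return Character vector of categories.
#' @examples
#' classify_hit(-2.5, -2.5)  # dual_toxic
#' classify_hit(0, -1.5)     # met_selective
#' @export
classify_hit <- function(z_gfp, z_rfp, thresholds = hit_thresholds()) {
  if (any(!is.finite(z_gfp)) || any(!is.finite(z_rfp))) {
    stop("Z-scores must be finite")
  }
  stopifnot(length(z_gfp) == length(z_rfp))
  th <- thresholds
  out <- rep("unclassified", length(z_gfp))
  out[z_gfp < th["kill"] & z_rfp > th["spare"]] <- "pri_selective"
  out[z_rfp < th["kill"] & z_gfp > th["spare"]] <- "met_selective"
  out[z_gfp < th["dual"] & z_rfp < th["dual"]] <- "dual_toxic"
  out
}

#' Call selective-toxicity hits on a two-channel co-culture screen
#'
#' Scores the screen ([score_screen()]), Z-transforms each channel's
#' I-scores, and classifies every compound with [classify_hit()]. The
#' dataset must carry exactly the two fluorescence channels (GFP, RFP).
#'
#' @param ds A two-channel [screen_dataset()].
#' @param sd_convention Passed to [z_transform()].
#' @param thresholds Passed to [classify_hit()].
#' @param gfp_channel,rfp_channel Channel names reporting the primary and
#'   metastatic line respectively.
#' @return data.frame of class `hit_calls`: `compound_id`, `z_gfp`, `z_rfp`,
#'   `category`; category counts in attribute `"counts"`.
#' @export
call_hits <- function(ds, sd_convention = c("sample", "population"),
                      thresholds = hit_thresholds(),
                      gfp_channel = "GFP", rfp_channel = "RFP") {
  stopifnot(inherits(ds, "screen_dataset"))
  chans <- unique(ds$wells$channel)
  missing_ch <- setdiff(c(gfp_channel, rfp_channel), chans)
  if (length(missing_ch)) {
    stop("co-culture hit calling needs channels ", gfp_channel, " and ",
         rfp_channel, "; missing: ", paste(missing_ch, collapse = ", "))
  }
  scores <- z_transform(score_screen(ds), sd_convention = match.arg(sd_convention))
  g <- scores[scores$channel == gfp_channel, ]
  r <- scores[scores$channel == rfp_channel, ]
  ids <- intersect(g$compound_id, r$compound_id)
  calls <- data.frame(
    compound_id = ids,
    z_gfp = g$z_score[match(ids, g$compound_id)],
    z_rfp = r$z_score[match(ids, r$compound_id)],
    stringsAsFactors = FALSE
  )
  calls$category <- classify_hit(calls$z_gfp, calls$z_rfp, thresholds)
  calls <- calls[order(calls$compound_id), ]
  rownames(calls) <- NULL
  attr(calls, "counts") <- table(factor(calls$category,
    levels = c("dual_toxic", "met_selective", "pri_selective", "unclassified")))
  class(calls) <- c("hit_calls", "data.frame")
  calls
}

#' @export
print.hit_calls <- function(x, ...) {
  cnt <- table(factor(x$category,
    levels = c("dual_toxic", "met_selective", "pri_selective", "unclassified")))
  cat("hit_calls:", nrow(x), "compounds |",
      paste(names(cnt), as.integer(cnt), sep = "=", collapse = ", "), "\n")
  NextMethod()
}
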