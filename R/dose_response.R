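#' Normalize raw viability signals to percent of DMSO control
#'
#' @param raw Non-negative raw viability signals (e.g. luminescence).
#' @param dmso_wells Raw signals of the DMSO control wells (>= 1 well).
#' @return `100 * raw / mean(dmso_wells)`.
#' @export
normalize_viability <- function(raw, dmso_wells) {
  if (!length(dmso_wells)) stop("at least one DMSO control well is required")
  m <- mean(dmso_wells)
  if (!is.finite(m) || m <= 0) {
    stop("degenerate DMSO control: mean must be positive")
  }
  if (any(raw < 0)) stop("raw signals must be non-negative")
  100 * raw / m
}

#' Construct a dose-response series
#'
#' Viability (percent of control) at a ladder of strictly increasing molar
#' doses, possibly replicated. Replicate counts must be equal across doses.
#'
#' @param doses Strictly positive molar concentrations, one per measurement
#'   (repeated for replicates) or one per distinct dose.
#' @param viability Percent-of-control viability, same length as `doses`.
#' @param compound_id,line Optional labels.
#' @return Object of class `dose_series`.
#' @export
dose_series <- function(doses, viability, compound_id = NA_character_,
                        line = NA_character_) {
  stopifnot(length(doses) == length(viability), all(doses > 0),
            all(is.finite(viability)))
  ord <- order(doses)
  doses <- doses[ord]; viability <- viability[ord]
  ud <- sort(unique(doses))
  if (length(ud) < 4L) stop("at least 4 distinct doses are required")
  reps <- table(doses)
  if (length(unique(as.integer(reps))) != 1L) {
    stop("replicate counts must be equal across doses")
  }
  structure(list(doses = doses, viability = viability, unique_doses = ud,
                 n_replicates = as.integer(reps[1]),
                 compound_id = compound_id, line = line),
            class = "dose_series")
}

fourpl <- function(d, top, bottom, hill, ic50) {
  bottom + (top - bottom) / (1 + (d / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`
#' with the IC50 parameterized on log10-dose. Replicates are fitted as pooled
#' points so replicate scatter informs the residual sum of squares. The fit
#' is multi-start (IC50 initialized at every tested dose, Hill slope at 0.5,
#' 1 and 2) and the candidate with the lowest RSS is returned. Box
#' constraints: bottom in \[-10, 50\], top in \[50, 120\], hill in (0, 10\].
#'
#' The IC50 is censored ("greater than the highest tested dose") when the
#' fitted value exceeds the top tested dose or when the series never reaches
#' 50 percent inhibition; censored fits report the top tested dose as the
#' IC50 with `ic50_censored = TRUE`, mirroring the "IC50 > max" reporting
#' convention.
#'
#' @param series A [dose_series()], or doses when `viability` is given.
#' @param viability Optional viability vector (with `series` as doses).
#' @param hill_starts Hill-slope starting values for the multi-start grid.
#' @return Object of class `dose_response_fit` with elements `top`, `bottom`,
#'   `hill`, `ic50`, `ic50_censored`, `rss`, `n_points`, `fitted`,
#'   `converged`.
#' @export
fit_4pl <- function(series, viability = NULL, hill_starts = c(0.5, 1, 2)) {
  if (!inherits(series, "dose_series")) {
    series <- dose_series(series, viability)
  }
  d <- series$doses
  v <- series$viability
  ld <- log10(d)
  max_dose <- max(series$unique_doses)

  lower <- c(top = 50, bottom = -10, hill = 1e-3, lic50 = min(ld) - 3)
  upper <- c(top = 120, bottom = 50, hill = 10, lic50 = max(ld) + 3)

  best <- NULL
  for (lic0 in log10(series$unique_doses)) {
    for (h0 in hill_starts) {
      start <- list(top = min(max(max(v), 50), 120),
                    bottom = max(min(min(v), 50), -10),
                    hill = h0, lic50 = lic0)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          v ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - lic50))),
          start = start, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    stop("4PL fit failed to converge from any start (",
         length(series$unique_doses) * length(hill_starts), " starts, ",
         length(v), " points)")
  }
  p <- stats::coef(best$fit)
  ic50 <- 10^p[["lic50"]]

  # mean viability per dose; censor when inhibition never reaches 50%
  mean_v <- tapply(v, d, mean)
  max_inhibition <- 100 - min(mean_v)
  censored <- ic50 > max_dose || max_inhibition < 50
  structure(list(
    top = p[["top"]], bottom = p[["bottom"]], hill = p[["hill"]],
    ic50 = if (censored) max_dose else ic50,
    ic50_censored = censored,
    rss = best$rss, n_points = length(v),
    fitted = as.numeric(stats::fitted(best$fit)),
    converged = TRUE,
    compound_id = series$compound_id, line = series$line),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("4PL fit:", if (!is.na(x$compound_id)) x$compound_id else "", "\n")
  cat(sprintf("  IC50 %s%.4g (top %.1f, bottom %.1f, hill %.2f, RSS %.3g, n %d)\n",
              if (x$ic50_censored) "> " else "", x$ic50, x$top, x$bottom,
              x$hill, x$rss, x$n_points))
  invisible(x)
}

#' IC50 fold-sensitivity ratio between a resistant and a sensitive model
#'
#' `ic50_resistant / ic50_sensitive`; for example, a resistant line with
#' IC50 140 nM against a sensitive line at 14 nM gives a 10-fold difference.
#' If either fit is censored the ratio involves a bound rather than a point
#' estimate and is flagged as a lower bound (resistant censored) or
#' indeterminate upper-side bound (sensitive censored).
#'
#' @param fit_resistant,fit_sensitive `dose_response_fit` objects or bare
#'   IC50 values in the same units.
#' @return List with `fold` and `censored` (`"none"`, `"lower_bound"`,
#'   `"upper_bound"`).
#' @examples
#' fold_ratio(140, 14)$fold  # 10
#' @export
fold_ratio <- function(fit_resistant, fit_sensitive) {
  get <- function(f) {
    if (inherits(f, "dose_response_fit")) c(f$ic50, f$ic50_censored)
    else c(as.numeric(f), FALSE)
  }
  r <- get(fit_resistant); s <- get(fit_sensitive)
  if (s[1] == 0) stop("sensitive IC50 must be positive")
  censored <- if (r[2] > 0) "lower_bound" else if (s[2] > 0) "upper_bound" else "none"
  list(fold = r[1] / s[1], censored = censored)
}
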