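#' Modified ellipsoidal tumour volume from caliper dimensions
#'
#' `V = 1/2 * length * width^2`, the standard caliper approximation for a
#' subcutaneous tumour. Inputs where width exceeds length are swapped with a
#' warning.
#'
#' @param length,width Caliper dimensions in mm (positive).
#' @return Volume in mm^3.
#' @examples
#' ellipsoid_volume(20, 10)  # 1000 mm^3 = 1 cm^3
#' @export
ellipsoid_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) {
    stop("caliper dimensions must be positive")
  }
  swap <- width > length
  if (any(swap)) {
    warning(sum(swap), " measurement(s) had width > length; swapped")
    tmp <- length[swap]; length[swap] <- width[swap]; width[swap] <- tmp
  }
  0.5 * length * width^2
}

#' Tumour weight estimated from volume at unit tissue density
#'
#' Weight is not measured directly; it is estimated from volume assuming a
#' tissue density of 1 g/cm^3, i.e. `weight_g = volume_mm3 / 1000`.
#'
#' @param volume_mm3 Tumour volume in mm^3.
#' @return Estimated weight in grams.
#' @export
tumour_weight <- function(volume_mm3) {
  stopifnot(all(volume_mm3 >= 0))
  volume_mm3 / 1000
}

#' Assemble a growth study from caliper records
#'
#' Derives per-animal per-day ellipsoidal volumes from a validated caliper
#' table (see [read_caliper_table()]). Each grafted tumour (animal id) is the
#' experimental unit.
#'
#' @param records Caliper table (data.frame or CSV path) with columns
#'   `animal_id`, `arm`, `day`, `length`, `width`.
#' @return Object of class `growth_study` with element `volumes`
#'   (data.frame `animal_id`, `arm`, `day`, `volume`).
#' @export
growth_study <- function(records) {
  tab <- read_caliper_table(records)
  tab$volume <- ellipsoid_volume(tab$length, tab$width)
  arms <- unique(tab[, c("animal_id", "arm")])
  if (anyDuplicated(arms$animal_id)) {
    stop("animal(s) assigned to more than one arm")
  }
  structure(list(volumes = tab[, c("animal_id", "arm", "day", "volume")]),
            class = "growth_study")
}

volume_at <- function(vol, animal, day) {
  v <- vol$volume[vol$animal_id == animal & vol$day == day]
  if (!length(v)) NA_real_ else v
}

#' Tumour-growth-inhibition ratio (delta-T over average delta-C)
#'
#' For each treated tumour at a study day, the change in its volume from the
#' initial day of dosing (delta-T) divided by the average change across all
#' control tumours measured at that day (Average delta-C). A value of 1
#' means growth indistinguishable from control, 0 complete stasis, < 0
#' regression. Animals without a measurement on the requested day are
#' excluded (no imputation).
#'
#' @param study A [growth_study()].
#' @param day Study day (day 0 is the initial day of dosing).
#' @param treated_arm,control_arm Arm labels; defaults are every non-control
#'   arm vs. `"control"`.
#' @return data.frame `animal_id`, `arm`, `day`, `delta_t`, `avg_delta_c`,
#'   `delta_ratio`.
#' @export
delta_ratio <- function(study, day, treated_arm = NULL,
                        control_arm = "control") {
  stopifnot(inherits(study, "growth_study"))
  vol <- study$volumes
  ctrl_animals <- unique(vol$animal_id[vol$arm == control_arm])
  if (!length(ctrl_animals)) stop("no animals in control arm '", control_arm, "'")
  dc <- vapply(ctrl_animals, function(a) {
    volume_at(vol, a, day) - volume_at(vol, a, 0L)
  }, numeric(1))
  dc <- dc[!is.na(dc)]  # controls withdrawn before `day` drop out
  if (!length(dc)) stop("no control animal measured at day ", day)
  avg_dc <- mean(dc)

  if (is.null(treated_arm)) {
    treated_arm <- setdiff(unique(vol$arm), control_arm)
  }
  tr <- unique(vol[vol$arm %in% treated_arm, c("animal_id", "arm")])
  dt <- vapply(tr$animal_id, function(a) {
    volume_at(vol, a, day) - volume_at(vol, a, 0L)
  }, numeric(1))
  keep <- !is.na(dt)
  ratio <- if (avg_dc == 0) {
    warning("Average delta-C is 0 at day ", day, "; ratio undefined")
    rep(NA_real_, sum(keep))
  } else dt[keep] / avg_dc
  data.frame(animal_id = tr$animal_id[keep], arm = tr$arm[keep], day = day,
             delta_t = dt[keep], avg_delta_c = avg_dc, delta_ratio = ratio,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sample endpoint t-test between study arms
#'
#' Two-tailed Student's t-test (equal-variance by default; Welch via
#' `var_equal = FALSE`) comparing endpoint tumour burden between two arms.
#' Inputs are volumes in mm^3; the comparison is equivalently on estimated
#' weights since weight = volume x density 1 g/cm^3.
#'
#' @param arm_a,arm_b Numeric endpoint volumes (>= 2 animals each).
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return List `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
endpoint_ttest <- function(arm_a, arm_b, var_equal = TRUE) {
  if (length(arm_a) < 2L || length(arm_b) < 2L) {
    stop("insufficient replication: need >= 2 animals per arm")
  }
  if (stats::sd(arm_a) == 0 && stats::sd(arm_b) == 0) {
    # degenerate: no within-arm variance
    if (mean(arm_a) == mean(arm_b)) {
      return(list(t = 0, p = 1, df = length(arm_a) + length(arm_b) - 2,
                  mean_a = mean(arm_a), mean_b = mean(arm_b)))
    }
    stop("zero variance in both arms with unequal means: t undefined")
  }
  tt <- stats::t.test(arm_a, arm_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(arm_a), mean_b = mean(arm_b))
}

#' Per-arm per-day volume summaries
#'
#' Mean and standard error of the mean (sd/sqrt(n)) of tumour volume per arm
#' per day; the s.e.m. is `NA` for single-animal groups.
#'
#' @param study A [growth_study()].
#' @return data.frame `arm`, `day`, `n`, `mean`, `sem`.
#' @export
summarize_arms <- function(study) {
  stopifnot(inherits(study, "growth_study"))
  vol <- study$volumes
  grp <- interaction(vol$arm, vol$day, drop = TRUE)
  out <- data.frame(
    arm = tapply(vol$arm, grp, `[[`, 1L),
    day = as.integer(tapply(vol$day, grp, `[[`, 1L)),
    n = as.integer(tapply(vol$volume, grp, length)),
    mean = as.numeric(tapply(vol$volume, grp, mean)),
    sem = as.numeric(tapply(vol$volume, grp, function(x) {
      if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
    })),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$arm, out$day), ]
}
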