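#' Cohort-mean CC-view contralateral ratio from ground truth
#'
#' Mean over subjects of the ratio of the two CC-view ground-truth breast
#' averages; the quantity the generator calibrations target.
#'
#' @param subjects List of `subject_scans`.
#' @return Scalar mean ratio.
#' @export
true_cc_ratio_mean <- function(subjects) {
  mean(vapply(subjects, function(s) {
    contralateral_ratio(s$true_averages[["LCC"]], s$true_averages[["RCC"]])
  }, numeric(1)))
}

#' Calibrate the healthy asymmetry scale to a target mean CC ratio
#'
#' Finds the glandular-fraction asymmetry scale at which a seeded healthy
#' cohort's ground-truth mean CC contralateral ratio equals the target
#' (root-finding on the deterministic seed-fixed cohort). The clinically
#' reported healthy CC mean, 1.05, is the default target.
#'
#' @param target Target mean CC ratio.
#' @param n_subjects Healthy cohort size.
#' @param seed Master cohort seed (the calibrated cohort is the one this
#'   seed generates).
#' @param grid A [grid_spec()].
#' @param interval Search interval for the scale.
#' @param tol Ratio tolerance at the root.
#' @param ... Extra [cohort_spec()] arguments.
#' @return The calibrated asymmetry scale.
#' @export
calibrate_asymmetry_scale <- function(target = 1.05, n_subjects = 20,
                                      seed = 1L, grid = grid_spec(),
                                      interval = c(0, 0.8), tol = 1e-4, ...) {
  f <- function(scale) {
    subj <- generate_cohort(cohort_spec(
      n_healthy = n_subjects, n_cancer = 0, asymmetry_scale = scale,
      seed = seed, grid = grid, ...))
    true_cc_ratio_mean(subj) - target
  }
  stats::uniroot(f, interval, tol = tol)$root
}

#' Calibrate the tumor contrast to a target cancer-cohort mean CC ratio
#'
#' Finds the fractional tumor contrast (scaling of the underlying tissue
#' inside the inclusion) at which a seeded cancer cohort's ground-truth mean
#' CC contralateral ratio equals the target; the clinically reported cancer
#' CC mean, 1.15, is the default target.
#'
#' @param target Target mean CC ratio.
#' @param n_subjects Cancer cohort size.
#' @param asymmetry_scale Healthy asymmetry scale underlying the cohort
#'   (typically the [calibrate_asymmetry_scale()] result).
#' @param seed Master cohort seed.
#' @param grid A [grid_spec()].
#' @param interval Search interval for the fractional contrast.
#' @param tol Ratio tolerance at the root.
#' @param ... Extra [cohort_spec()] arguments.
#' @return The calibrated fractional tumor contrast.
#' @export
calibrate_tumor_contrast <- function(target = 1.15, n_subjects = 14,
                                     asymmetry_scale = 0.2, seed = 2L,
                                     grid = grid_spec(),
                                     interval = c(0, 3), tol = 1e-4, ...) {
  f <- function(contrast) {
    subj <- generate_cohort(cohort_spec(
      n_healthy = 0, n_cancer = n_subjects,
      asymmetry_scale = asymmetry_scale, tumor_contrast = contrast,
      seed = seed, grid = grid, ...))
    true_cc_ratio_mean(subj) - target
  }
  stats::uniroot(f, interval, tol = tol)$root
}
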