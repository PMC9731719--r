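# Published clinical baselines for pulmonary nodule assessment: the Mayo
# Clinic and Veterans Affairs logistic models and the clinical CEA cutoff.
# Coefficients are fixed as published; nothing here is refit.

logistic <- function(x) exp(x) / (1 + exp(x))

#' Mayo Clinic probability of nodule malignancy
#'
#' `p = e^x / (1 + e^x)` with
#' `x = -6.8272 + 0.0391*age + 0.7917*smoking + 1.3388*cancer +
#'  0.1274*diameter + 1.0407*spiculation + 0.7838*upper_lobe`.
#'
#' @param age age in years (>= 0).
#' @param smoking 1 for ever-smokers (current or former), else 0.
#' @param cancer 1 for a history of extrathoracic cancer diagnosed more than
#'   five years ago, else 0.
#' @param diameter nodule diameter in mm (> 0).
#' @param spiculation 1 if the nodule margin is spiculated, else 0.
#' @param upper_lobe 1 if the nodule sits in an upper lobe, else 0.
#' @return probability in (0, 1); vectorised over inputs.
#' @export
#' @examples
#' mayo_probability(age = 65, smoking = 1, diameter = 10)
mayo_probability <- function(age, smoking = 0, cancer = 0, diameter,
                             spiculation = 0, upper_lobe = 0) {
  args <- list(age = age, smoking = smoking, cancer = cancer,
               diameter = diameter, spiculation = spiculation,
               upper_lobe = upper_lobe)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]]))) stop_input("non-finite `%s`", nm)
  }
  if (any(age < 0)) stop_input("`age` must be >= 0")
  if (any(diameter <= 0)) stop_input("`diameter` must be > 0 mm")
  if (any(!smoking %in% c(0, 1)) || any(!cancer %in% c(0, 1)) ||
      any(!spiculation %in% c(0, 1)) || any(!upper_lobe %in% c(0, 1))) {
    stop_input("indicator covariates must be 0 or 1")
  }
  x <- -6.8272 + 0.0391 * age + 0.7917 * smoking + 1.3388 * cancer +
    0.1274 * diameter + 1.0407 * spiculation + 0.7838 * upper_lobe
  logistic(x)
}

#' Veterans Affairs probability of nodule malignancy
#'
#' `p = e^x / (1 + e^x)` with
#' `x = -8.404 + 2.061*smoke + 0.779*age10 + 0.112*diameter -
#'  0.567*years_quit10`.
#'
#' @param smoke 1 for ever-smokers, else 0.
#' @param age10 age in years divided by 10.
#' @param diameter nodule diameter in mm (> 0).
#' @param years_quit10 years since quitting smoking divided by 10 (0 for
#'   never-smokers).
#' @return probability in (0, 1); vectorised over inputs.
#' @export
#' @examples
#' va_probability(smoke = 0, age10 = 6, diameter = 10)
va_probability <- function(smoke = 0, age10, diameter, years_quit10 = 0) {
  args <- list(smoke = smoke, age10 = age10, diameter = diameter,
               years_quit10 = years_quit10)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]]))) stop_input("non-finite `%s`", nm)
  }
  if (any(age10 < 0) || any(years_quit10 < 0)) {
    stop_input("`age10` and `years_quit10` must be >= 0")
  }
  if (any(!smoke %in% c(0, 1))) stop_input("`smoke` must be 0 or 1")
  if (any(smoke == 0 & years_quit10 != 0)) {
    stop_input("`years_quit10` must be 0 for never-smokers")
  }
  if (any(diameter <= 0)) stop_input("`diameter` must be > 0 mm")
  x <- -8.404 + 2.061 * smoke + 0.779 * age10 + 0.112 * diameter -
    0.567 * years_quit10
  logistic(x)
}

#' Dichotomize CEA at the clinical cutoff
#'
#' Positive iff CEA strictly exceeds the cutoff (5 ng/mL by default, per
#' assay manufacturer recommendation); a value exactly at the cutoff is
#' negative. The boundary convention is configurable via `strict`.
#'
#' @param cea serum CEA in ng/mL (>= 0).
#' @param cutoff positivity cutoff in ng/mL.
#' @param strict use `>` (default) rather than `>=` at the boundary.
#' @return logical vector: TRUE = positive.
#' @export
cea_classify <- function(cea, cutoff = 5, strict = TRUE) {
  if (any(!is.finite(cea)) || any(cea < 0)) {
    stop_input("`cea` must be finite and >= 0 ng/mL")
  }
  check_number(cutoff, "cutoff", lower = 0)
  if (strict) cea > cutoff else cea >= cutoff
}

#' Batch clinical scores for a cohort table
#'
#' Adds `mayo_prob`, `va_prob` and `cea_call` columns computed from the
#' cohort covariates; nodule-model probabilities are NA outside the nodule
#' subset.
#'
#' @param records cohort metadata as produced by [generate_cohort()].
#' @param cea_cutoff CEA positivity cutoff in ng/mL.
#' @return `records` with the three columns appended.
#' @export
add_clinical_scores <- function(records, cea_cutoff = 5) {
  n <- nrow(records)
  mayo <- rep(NA_real_, n)
  va <- rep(NA_real_, n)
  idx <- which(records$nodule_present)
  if (length(idx)) {
    r <- records[idx, ]
    mayo[idx] <- mayo_probability(
      age = r$age, smoking = as.numeric(r$smoker_ever),
      cancer = as.numeric(r$extrathoracic_cancer_gt5y),
      diameter = r$nodule_diameter,
      spiculation = as.numeric(r$spiculation),
      upper_lobe = as.numeric(r$upper_lobe))
    va[idx] <- va_probability(
      smoke = as.numeric(r$smoker_ever), age10 = r$age / 10,
      diameter = r$nodule_diameter, years_quit10 = r$years_quit / 10)
  }
  records$mayo_prob <- mayo
  records$va_prob <- va
  records$cea_call <- cea_classify(records$cea, cea_cutoff)
  records
}
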