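# Annual BMI dynamics: autoregressive model on log BMI plus the preventive
# weight-reduction intervention.

#' BMI category
#'
#' WHO-style cut-offs: underweight < 18.5, normal 18.5-24.9, overweight
#' 25.0-29.9, obese >= 30.0 (half-open boundaries, so 25.0 is overweight and
#' 30.0 is obese).
#' @param bmi numeric vector of BMI values (kg/m^2, > 0).
#' @return factor with levels underweight, normal, overweight, obese.
#' @export
bmi_category <- function(bmi) {
  stopifnot(all(bmi > 0))
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"))
}

# linear predictor of the log-BMI model (vectorized over individuals of one
# sex); region is an integer level index
.bmi_lp <- function(coeffs, log_bmi, age, edu, income, region) {
  coeffs$intercept + coeffs$lag * log_bmi + coeffs$age * age +
    coeffs$edu * (edu - 2.5) + coeffs$income * (income - 3) +
    coeffs$region[region]
}

#' One annual autoregressive BMI update
#'
#' New BMI is `exp(lp + noise)` where the linear predictor includes the
#' lagged log BMI, age, education, income, and region, with sex-specific
#' coefficients, and the noise is normal with the model's residual sd. The
#' result is clamped to the configured plausible range (default 12-70), and
#' the number of clamped values is reported via the `"clamped"` attribute.
#'
#' @param bmi current BMI values (> 10).
#' @param age,edu,income,region covariate vectors (same length as `bmi`).
#' @param sex integer vector, 1 = male, 2 = female.
#' @param bmi_model the `bmi_model` component of an `oa_params` object.
#' @param noise standard-normal draws (same length as `bmi`); pass zeros for
#'   a deterministic update.
#' @return numeric vector of updated BMI values.
#' @export
update_bmi <- function(bmi, age, edu, income, region, sex, bmi_model, noise) {
  stopifnot(all(bmi > 10))
  lp <- numeric(length(bmi))
  for (s in 1:2) {
    idx <- sex == s
    if (!any(idx)) next
    cf <- bmi_model[[c("male", "female")[s]]]
    lp[idx] <- .bmi_lp(cf, log(bmi[idx]), age[idx], edu[idx], income[idx],
                       region[idx]) + cf$sd * noise[idx]
  }
  new <- exp(lp)
  lo <- bmi_model$bounds[1]; hi <- bmi_model$bounds[2]
  clamped <- sum(new < lo | new > hi)
  out <- pmin(pmax(new, lo), hi)
  attr(out, "clamped") <- clamped
  out
}

#' Apply the preventive BMI reduction
#'
#' Individuals at or above the eligibility threshold (default BMI 25) lose
#' `reduction` units; eligibility is re-assessed every year on the current
#' BMI, so a person may drop below the threshold and later re-enter the
#' intervention. Individuals below the threshold are never changed.
#'
#' @param bmi numeric vector of BMI values.
#' @param reduction annual reduction in kg/m^2 (>= 0).
#' @param threshold eligibility threshold (default 25).
#' @return numeric vector of BMI values after the intervention year.
#' @export
apply_bmi_reduction <- function(bmi, reduction, threshold = 25) {
  if (reduction < 0) stop("reduction must be >= 0", call. = FALSE)
  ifelse(bmi >= threshold, bmi - reduction, bmi)
}
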