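# OA onset hazard, OA staging, and the eight-attribute HUI3 health state:
# hierarchical proportional-odds update and multi-attribute utility scoring.

#' Annual OA onset hazard
#'
#' `base(age band, sex) / 1000` scaled by the BMI-category relative risk for
#' that sex. Vectorized over individuals.
#' @param age,sex,bmi covariate vectors (sex: 1 = male, 2 = female).
#' @param model the `oa_incidence` component of an `oa_params` object.
#' @return hazard per person-year.
#' @export
oa_hazard <- function(age, sex, bmi, model) {
  base <- model$base_per_1000[cbind(age_band(age), sex)] / 1000
  cat <- as.integer(bmi_category(bmi))
  base * model$rr_bmi[cbind(cat, sex)]
}

#' Sample OA onset
#'
#' Bernoulli with probability `1 - exp(-hazard)`; OA is absorbing, so this
#' is only meaningful for OA-free individuals.
#' @param hazard annual hazard vector.
#' @param u uniform draws of the same length.
#' @return logical vector of onsets.
#' @export
sample_oa_onset <- function(hazard, u) u < 1 - exp(-hazard)

#' OA stage
#'
#' Stages are: no OA; OA diagnosed less than 5 years ago; OA diagnosed 5 or
#' more years ago; joint replacement less than 5 years ago; joint
#' replacement 5 or more years ago. Surgery stages take precedence over
#' diagnosis-duration stages.
#'
#' @param has_oa logical vector.
#' @param oa_onset_year,last_jrs_year calendar years (NA when not
#'   applicable).
#' @param year current calendar year.
#' @return factor with levels none, oa_lt5, oa_ge5, postjrs_lt5,
#'   postjrs_ge5.
#' @export
oa_stage <- function(has_oa, oa_onset_year, last_jrs_year, year) {
  code <- .oa_stage_code(has_oa, oa_onset_year, last_jrs_year, year)
  factor(c("none", .stages)[code + 1L],
         levels = c("none", .stages))
}

# integer stage code: 0 none, 1 oa_lt5, 2 oa_ge5, 3 postjrs_lt5, 4 postjrs_ge5
.oa_stage_code <- function(has_oa, oa_onset_year, last_jrs_year, year) {
  out <- integer(length(has_oa))
  oa <- which(has_oa)
  if (!length(oa)) return(out)
  jrs <- !is.na(last_jrs_year[oa])
  out[oa] <- ifelse(jrs,
                    ifelse(year - last_jrs_year[oa] < 5, 3L, 4L),
                    ifelse(year - oa_onset_year[oa] < 5, 1L, 2L))
  out
}

#' Proportional-odds category probabilities
#'
#' For strictly increasing cutpoints `c_1 < ... < c_{K-1}` and a linear
#' predictor `lp`, the cumulative probabilities are
#' `P(Y <= k) = logistic(c_k - lp)` and category probabilities are their
#' successive differences.
#' @param lp scalar linear predictor.
#' @param cutpoints strictly increasing numeric vector.
#' @return probability vector over `length(cutpoints) + 1` categories.
#' @export
ordinal_probs <- function(lp, cutpoints) {
  if (length(cutpoints) > 1 && any(diff(cutpoints) <= 0))
    stop("cutpoints must be strictly increasing", call. = FALSE)
  cum <- plogis(cutpoints - lp)
  diff(c(0, cum, 1))
}

# compile attribute models into the flat structure the C++ kernel expects:
# in update order, beta aligned to .xcols, concurrent coefficients keyed by
# update position (entries referring to not-yet-updated attributes dropped)
.compile_hui_models <- function(params) {
  ord <- params$hui3_order
  lapply(seq_along(ord), function(i) {
    m <- params$hui3[[ord[i]]]
    conc <- setNames(numeric(length(ord)), ord)
    earlier <- intersect(names(m$conc)[m$conc != 0], ord[seq_len(i - 1)])
    conc[earlier] <- m$conc[earlier]
    list(beta = unname(m$beta[.xcols]), lag_coef = m$lag_coef,
         conc = unname(conc), cutpoints = m$cutpoints)
  })
}

# design matrix for the HUI3 models; idx selects rows of the population
.hui_design <- function(P, idx, year) {
  stage <- .oa_stage_code(P$has_oa[idx], P$oa_onset_year[idx],
                          P$last_jrs_year[idx], year)
  cbind(
    age_c = (P$age[idx] - 50) / 10,
    female = as.numeric(P$sex[idx] == 2L),
    edu_c = P$edu[idx] - 2.5,
    inc_c = P$income[idx] - 3,
    smoke_former = as.numeric(P$smoking[idx] == 2L),
    smoke_current = as.numeric(P$smoking[idx] == 3L),
    bmi_c = (P$bmi[idx] - 26) / 5,
    oa_lt5 = as.numeric(stage == 1L),
    oa_ge5 = as.numeric(stage == 2L),
    postjrs_lt5 = as.numeric(stage == 3L),
    postjrs_ge5 = as.numeric(stage == 4L),
    diabetes = as.numeric(P$diabetes[idx]),
    htn = as.numeric(P$htn[idx]),
    cvd = as.numeric(P$cvd[idx]),
    stroke = as.numeric(P$stroke[idx]),
    ulcer = as.numeric(P$ulcer[idx]),
    dysp = as.numeric(.dysp_active(P$dysp_year[idx], year)),
    year_c = rep((year - 2020) / 10, length(idx))
  )
}

#' Hierarchical HUI3 update
#'
#' Updates the eight ordinal attributes one at a time in the configured
#' order (pain last). Each attribute's proportional-odds linear predictor
#' combines the shared covariate row, the attribute's own lagged level, and
#' the already-updated levels of earlier attributes.
#'
#' @param X numeric design matrix (rows = individuals, columns as produced
#'   by the package's internal design builder).
#' @param lag integer matrix of current attribute levels (n x 8, update
#'   order).
#' @param models compiled model list (one element per attribute, in update
#'   order, with fields beta, lag_coef, conc, cutpoints).
#' @param U matrix of uniforms (n x 8), one column per attribute.
#' @return integer matrix of new levels (n x 8).
#' @export
update_hui3 <- function(X, lag, models, U) {
  hui3_update_cpp(X, lag, models, U)
}

#' HUI3 multi-attribute utility
#'
#' Multiplicative multi-attribute form: utility is an affine function of the
#' product of per-attribute level factors, scaled so that all-best levels
#' give exactly 1 and the worst state gives the configured floor (default
#' -0.36, the published HUI3 minimum; the collapsed-level factor table is a
#' documented stand-in, not an estimate).
#'
#' @param levels integer matrix (n x 8) of attribute levels, columns in the
#'   canonical attribute order.
#' @param map the `utility_map` component of an `oa_params` object.
#' @return numeric utility vector (<= 1).
#' @export
hui3_utility <- function(levels, map) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1)
  prod_f <- rep(1, nrow(levels))
  for (a in seq_along(.attributes)) {
    f <- map$factors[[.attributes[a]]]
    lv <- levels[, a]
    if (any(lv < 1 | lv > length(f)))
      stop("attribute level out of range for ", .attributes[a],
           call. = FALSE)
    prod_f <- prod_f * f[lv]
  }
  pmax(map$scale * prod_f - map$shift, map$floor)
}

#' Apply a sampled pain improvement
#'
#' Decrements the pain level by an integer improvement, clamped to the valid
#' range 1-5. Improvements from multiple drugs are applied in the fixed drug
#' order (acetaminophen, NSAID, coxib, opioid); since each is a clamped
#' decrement this equals clamping the summed improvement.
#'
#' @param pain integer pain levels in 1..5.
#' @param improvement nonnegative integer improvements.
#' @return new pain levels.
#' @export
apply_pain_change <- function(pain, improvement) {
  stopifnot(all(pain >= 1 & pain <= 5))
  pmax(pain - improvement, 1L)
}

# dyspepsia is a remitting state: active for `dyspepsia_duration` years
# after the most recent episode
.dysp_active <- function(dysp_year, year, duration = 3) {
  !is.na(dysp_year) & (year - dysp_year) < duration
}

# sample an improvement from a per-drug distribution c(p0, p1, p2) given
# uniforms
.sample_improvement <- function(effect, u) {
  (u > effect[1]) + (u > effect[1] + effect[2])
}
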