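# Analgesic use, drug side effects, joint replacement surgery (JRS), and
# treatment-attributable mortality.

#' Point-prevalence medication probabilities
#'
#' Table lookup per drug at (5-year age band, sex, OA stage, pain level).
#' Only individuals with OA use analgesics in this model; the caller is
#' expected to pass OA members (stage codes 1-4).
#'
#' @param age,sex,stage_code,pain vectors over individuals; `stage_code` as
#'   produced by [oa_stage()] (1 = oa_lt5 ... 4 = postjrs_ge5).
#' @param medications the `medications` component of an `oa_params` object.
#' @return numeric matrix (n x 4) of probabilities, columns acetaminophen,
#'   nsaid, coxib, opioid.
#' @export
medication_probabilities <- function(age, sex, stage_code, pain,
                                     medications) {
  stopifnot(all(stage_code %in% 1:4), all(pain %in% 1:5))
  idx <- cbind(age_band(age), sex, stage_code, pain)
  out <- vapply(.drugs, function(d) medications[[d]]$prevalence[idx],
                numeric(length(age)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, .drugs))
  out
}

#' Multiply the odds of a probability
#'
#' `p' = m p / (1 - p + m p)`: the probability whose odds are `m` times the
#' odds of `p`. The identity at `m = 1`, fixed points at `p = 0` and
#' `p = 1`; the degenerate case `p = 1, m = 0` returns 0 by the limit
#' convention.
#' @param p probabilities in `[0, 1]`.
#' @param m odds multiplier (>= 0), scalar or vector.
#' @return adjusted probabilities.
#' @export
apply_odds_multiplier <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), all(m >= 0))
  out <- m * p / (1 - p + m * p)
  out[m == 0] <- 0
  out
}

#' Sample medication use
#'
#' Independent Bernoulli draws per drug; all four drugs may be co-used.
#' @param probs matrix (n x 4) of use probabilities.
#' @param U matrix (n x 4) of uniforms.
#' @return logical matrix (n x 4).
#' @export
sample_medications <- function(probs, U) U < probs

# combined annual GI excess rate for a user, by age and used drugs
.gi_excess <- function(se, users, age) {
  p_no <- rep(1, nrow(users))
  scale <- exp(se$gi_age_slope * (age - 50))
  for (d in .drugs)
    p_no <- p_no * ifelse(users[, d], 1 - pmin(se$gi_excess50[[d]] * scale,
                                               1), 1)
  1 - p_no
}

#' Sample one year of medication side effects
#'
#' Five processes: serious GI complications (excess rate among users of
#' linked drugs, increasing with age), cardiovascular disease and stroke
#' (age/sex baseline incidence for everyone, multiplied by the user relative
#' risks of the linked drugs), dyspepsia (rate among users), and lethal
#' opioid overdose (users only). GI, CVD and stroke carry case fatality;
#' survivors acquire persistent comorbidity flags.
#'
#' Attribution is exact under common random numbers: for CVD and stroke the
#' same uniform decides both the baseline and the user-risk event, so an
#' event is treatment-attributable precisely when `baseline < u <= user
#' risk`; GI excess events and overdoses are attributable by construction.
#'
#' @param users logical matrix (n x 4) of current-year drug use.
#' @param age,sex covariates; `sex` 1 = male, 2 = female.
#' @param has_cvd,has_stroke,has_dysp existing comorbidity flags (new events
#'   are only sampled for those without the condition).
#' @param params an `oa_params` object.
#' @param U named uniform matrix with columns gi, cvd, stroke, dysp,
#'   overdose, gi_fatal, cvd_fatal, stroke_fatal.
#' @return list of logical event vectors: gi, cvd, cvd_excess, stroke,
#'   stroke_excess, dysp, overdose_death, gi_death, cvd_death, stroke_death,
#'   death (any fatal outcome), trt_death (treatment-attributable fatal
#'   outcome).
#' @export
sample_side_effects <- function(users, age, sex, has_cvd, has_stroke,
                                has_dysp, params, U) {
  se <- params$side_effects
  tm <- params$treatment_mortality
  n <- nrow(users)

  gi <- U[, "gi"] < .gi_excess(se, users, age)

  cvd_base <- pmin(se$cvd_baseline50[sex] * exp(se$cvd_age_slope * (age - 50)),
                   se$cvd_baseline_cap)
  rr_cvd <- rep(1, n)
  rr_stroke <- rep(1, n)
  for (d in .drugs) {
    u_d <- users[, d]
    rr_cvd[u_d] <- rr_cvd[u_d] * se$cvd_rr[[d]]
    rr_stroke[u_d] <- rr_stroke[u_d] * se$stroke_rr[[d]]
  }
  p_cvd_base <- pmin(cvd_base, 1)
  p_cvd_user <- pmin(cvd_base * rr_cvd, 1)
  cvd <- !has_cvd & U[, "cvd"] < p_cvd_user
  cvd_excess <- cvd & U[, "cvd"] >= p_cvd_base

  stroke_base <- pmin(se$stroke_baseline50[sex] *
                        exp(se$stroke_age_slope * (age - 50)),
                      se$stroke_baseline_cap)
  p_st_base <- pmin(stroke_base, 1)
  p_st_user <- pmin(stroke_base * rr_stroke, 1)
  stroke <- !has_stroke & U[, "stroke"] < p_st_user
  stroke_excess <- stroke & U[, "stroke"] >= p_st_base

  p_dysp <- rep(0, n)
  dscale <- exp(se$dyspepsia_age_slope * (age - 50))
  for (d in .drugs)
    p_dysp <- 1 - (1 - p_dysp) *
      ifelse(users[, d], 1 - pmin(se$dyspepsia_rate50[[d]] * dscale, 1), 1)
  dysp <- !has_dysp & U[, "dysp"] < p_dysp

  overdose_death <- users[, "opioid"] &
    U[, "overdose"] < se$opioid_overdose_death

  gi_death <- gi & U[, "gi_fatal"] < tm$gi_cf
  cvd_death <- cvd & U[, "cvd_fatal"] < tm$cvd_cf
  stroke_death <- stroke & U[, "stroke_fatal"] < tm$stroke_cf

  list(gi = gi, cvd = cvd, cvd_excess = cvd_excess, stroke = stroke,
       stroke_excess = stroke_excess, dysp = dysp,
       overdose_death = overdose_death, gi_death = gi_death,
       cvd_death = cvd_death, stroke_death = stroke_death,
       death = overdose_death | gi_death | cvd_death | stroke_death,
       trt_death = overdose_death | gi_death | (cvd_death & cvd_excess) |
         (stroke_death & stroke_excess))
}

#' Annual joint-replacement hazard
#'
#' Poisson log-rate model in age, sex and calendar year, scaled by the
#' pain-level odds modifier normalized so that the population-average
#' modifier is 1 (odds approximate rate ratios for rare events).
#'
#' @param age,sex,pain covariates (sex 1 = male, 2 = female).
#' @param year calendar year.
#' @param model the `jrs` component of an `oa_params` object.
#' @return primary-surgery hazard per person-year.
#' @export
jrs_rate <- function(age, sex, pain, year, model) {
  lambda <- exp(model$intercept + model$age_coef * (age - model$ref_age) +
                  model$female_coef * (sex == 2L) +
                  model$year_coef * (year - model$ref_year))
  lambda * model$pain_or[pain] / model$or_norm
}

#' Sample primary and revision joint replacement
#'
#' Primary surgery probability is `1 - exp(-multiplier * hazard)`, blocked
#' once the individual has had the maximum number of primaries (4); revision
#' hazard applies only to those with at least one primary and is not
#' affected by the scenario multiplier unless configured.
#'
#' @param age,sex,pain,year covariates as in [jrs_rate()].
#' @param n_primary number of primary surgeries so far.
#' @param model the `jrs` component of an `oa_params` object.
#' @param multiplier scenario hazard multiplier per individual (vector or
#'   scalar; 1 = base case).
#' @param u_primary,u_revision uniform draws.
#' @param revision_multiplier logical; apply the multiplier to revisions too.
#' @return list with logical vectors `primary` and `revision`.
#' @export
sample_jrs <- function(age, sex, pain, year, n_primary, model, multiplier,
                       u_primary, u_revision, revision_multiplier = FALSE) {
  lam_p <- jrs_rate(age, sex, pain, year, model) * multiplier
  primary <- n_primary < model$max_primary & u_primary < 1 - exp(-lam_p)
  lam_r <- model$revision_rate *
    exp(model$revision_year_coef * (year - model$ref_year))
  if (revision_multiplier) lam_r <- lam_r * multiplier
  revision <- n_primary >= 1 & u_revision < 1 - exp(-lam_r)
  list(primary = primary, revision = revision)
}
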