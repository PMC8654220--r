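# Open-population cohort: initial synthetic population and annual
# demographic dynamics (aging, death, emigration, entry at 20, immigration).

# initialization substreams (offsets from .streams$init)
.init_off <- c(sex = 0L, age = 1L, edu = 2L, income = 3L, region = 4L,
               smoking = 5L, bmi = 6L, oa = 7L, duration = 8L, jrs = 9L,
               jrs_when = 10L, diabetes = 11L, htn = 12L, cvd = 13L,
               stroke = 14L, ulcer = 15L, dysp = 16L)

.sample_cat <- function(u, probs) {
  cp <- cumsum(probs) / sum(probs)
  findInterval(u, cp, left.open = TRUE) + 1L
}

# steady-state prevalence by (age, sex, bmi category), rescaled so the
# marginal over the stationary BMI mix equals the calibrated prevalence
.prev_tables <- function(params, ages = 20:100) {
  marg <- calibrate_steady_state_prevalence(params, ages)
  arr <- array(0, dim = c(length(ages), 2L, 4L))
  for (s in 1:2) {
    sex <- c("male", "female")[s]
    bm <- params$bmi_model[[sex]]
    pm <- marg$prevalence[marg$sex == sex]
    for (i in seq_along(ages)) {
      a <- ages[i]
      pc <- .prevalence_by_category(params, a, sex)
      mu <- bm$stationary_mean45 +
        params$bmi_model$age_slope_per_year * (a - 45)
      p_le <- pnorm((log(c(18.5, 25, 30)) - mu) / bm$stationary_sd)
      w <- c(p_le[1], diff(p_le), 1 - p_le[3])
      mix <- sum(w * pc)
      arr[i, s, ] <- if (mix > 0) pmin(pc * pm[i] / mix, 1) else 0
    }
  }
  arr
}

# draw covariates and health history for a set of new person ids
.draw_persons <- function(params, ids, year, seed, age = NULL,
                          prev_tables = NULL) {
  d <- params$demography
  u <- function(off) substream_uniform(seed, ids, .streams$init + off, year)
  n <- length(ids)
  sex <- ifelse(u(.init_off["sex"]) < d$sex_female, 2L, 1L)
  if (is.null(age)) {
    age <- integer(n)
    for (s in 1:2) {
      pyr <- if (s == 1) d$age_pyramid_male else d$age_pyramid_female
      idx <- sex == s
      age[idx] <- d$ages[.sample_cat(u(.init_off["age"])[idx], pyr)]
    }
  } else if (length(age) == 1L) age <- rep(as.integer(age), n)
  edu <- .sample_cat(u(.init_off["edu"]), d$edu_probs)
  income <- .sample_cat(u(.init_off["income"]), d$income_probs)
  region <- .sample_cat(u(.init_off["region"]), d$region_probs)
  smoking <- .sample_cat(u(.init_off["smoking"]), d$smoking_probs)

  # stationary log-BMI draw at the person's age
  z <- qnorm(u(.init_off["bmi"]))
  bmi <- numeric(n)
  for (s in 1:2) {
    bm <- params$bmi_model[[c("male", "female")[s]]]
    idx <- sex == s
    mu <- bm$stationary_mean45 +
      params$bmi_model$age_slope_per_year * (age[idx] - 45)
    bmi[idx] <- exp(mu + bm$stationary_sd * z[idx])
  }
  bmi <- pmin(pmax(bmi, params$bmi_model$bounds[1]),
              params$bmi_model$bounds[2])

  # prevalent OA, tilted by current BMI category
  if (is.null(prev_tables)) prev_tables <- .prev_tables(params)
  cat <- as.integer(bmi_category(bmi))
  p_oa <- prev_tables[cbind(pmin(age, 100L) - 19L, sex, cat)]
  has_oa <- u(.init_off["oa"]) < p_oa

  # OA duration: onset age weighted by the incidence schedule
  oa_onset_year <- rep(NA_integer_, n)
  u_dur <- u(.init_off["duration"])
  for (i in which(has_oa)) {
    dmax <- age[i] - 20L
    w <- params$oa_incidence$base_per_1000[
      age_band(age[i] - 0:dmax), c("male", "female")[sex[i]]]
    dur <- .sample_cat(u_dur[i], w) - 1L
    oa_onset_year[i] <- year - dur
  }

  # prior joint replacement among prevalent OA
  dur <- ifelse(has_oa, year - oa_onset_year, 0)
  had_jrs <- has_oa & u(.init_off["jrs"]) < 1 - exp(-0.04 * dur)
  last_jrs_year <- rep(NA_integer_, n)
  last_jrs_year[had_jrs] <- year -
    as.integer(floor(u(.init_off["jrs_when"])[had_jrs] * (dur[had_jrs] + 1)))

  # background comorbidities (age-graded prevalences)
  diabetes <- u(.init_off["diabetes"]) < pmin(0.02 + 0.002 * (age - 20), 0.25)
  htn <- u(.init_off["htn"]) < pmin(0.04 + 0.004 * (age - 20), 0.50)
  cvd <- u(.init_off["cvd"]) < pmin(pmax(0.0015 * (age - 40), 0) +
                                      0.005, 0.30)
  stroke <- u(.init_off["stroke"]) < pmin(pmax(0.0008 * (age - 45), 0) +
                                            0.002, 0.15)
  ulcer <- u(.init_off["ulcer"]) < 0.03
  u_dysp <- u(.init_off["dysp"])
  dysp_year <- rep(NA_real_, n)
  has_d <- u_dysp < 0.06
  dysp_year[has_d] <- year - floor((u_dysp[has_d] / 0.06) * 3)

  list(id = as.integer(ids), sex = sex, age = as.integer(age),
       age0 = as.integer(age), edu = edu,
       income = income, region = region, smoking = smoking, bmi = bmi,
       has_oa = has_oa, oa_onset_year = oa_onset_year,
       hui = matrix(1L, n, 8L), med = matrix(FALSE, n, 4L,
                                             dimnames = list(NULL, .drugs)),
       diabetes = diabetes, htn = htn, cvd = cvd, stroke = stroke,
       ulcer = ulcer, dysp_year = dysp_year,
       n_primary = integer(n), n_revision = integer(n),
       last_jrs_year = last_jrs_year,
       alive = rep(TRUE, n), in_pop = rep(TRUE, n))
}

.bind_persons <- function(P, new) {
  for (f in names(new)) {
    if (is.matrix(new[[f]])) P[[f]] <- rbind(P[[f]], new[[f]])
    else P[[f]] <- c(P[[f]], new[[f]])
  }
  P
}

#' Initialize the synthetic open population
#'
#' Draws `n` individuals aged 20+ with the configured covariate structure
#' (age pyramid, sex ratio, stationary BMI distribution, education, income,
#' region, smoking, background comorbidities), assigns prevalent OA from the
#' calibrated steady-state prevalence (tilted by current BMI category), and
#' brings the HUI3 health state and medication use to their joint
#' near-stationary distribution with a short burn-in of annual updates.
#'
#' @param params an `oa_params` object.
#' @param n number of individuals (> 0).
#' @param start_year first simulated calendar year (default 2020).
#' @param seed master seed.
#' @param burnin logical; run the HUI3/medication burn-in (default TRUE).
#' @return an `oa_population` object.
#' @export
initialize_population <- function(params, n, start_year = 2020, seed = 1L,
                                  burnin = TRUE) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  prev_tables <- .prev_tables(params)
  P <- .draw_persons(params, seq_len(n), start_year - 1L, seed,
                     prev_tables = prev_tables)
  P$year <- start_year - 1L
  P$seed <- seed
  P$n_initial <- as.integer(n)
  P$next_id <- as.integer(n + 1L)
  class(P) <- "oa_population"
  attr(P, "prev_tables") <- prev_tables
  if (burnin) P <- .burnin_population(P, params)
  P
}

#' Sample background (non-treatment) death
#'
#' Gompertz-style annual probability `a_sex * exp(b * age)` with a secular
#' improvement factor per calendar year, multiplied by configured
#' comorbidity relative risks and capped.
#'
#' @param age,sex vectors (sex 1 = male, 2 = female).
#' @param year calendar year.
#' @param comorbid_rr per-person multiplicative hazard adjustment (product of
#'   configured relative risks for present comorbidities); use 1 for none.
#' @param params an `oa_params` object.
#' @param u uniform draws.
#' @return logical vector of deaths.
#' @export
sample_background_death <- function(age, sex, year, comorbid_rr, params,
                                    u) {
  u < .death_prob(age, sex, year, comorbid_rr, params)
}

.death_prob <- function(age, sex, year, comorbid_rr, params) {
  m <- params$demography$mortality
  a <- ifelse(sex == 1L, m$a_male, m$a_female)
  q <- a * exp(m$b * age) * (1 - m$improvement)^(year - 2020)
  pmin(q * comorbid_rr, m$cap)
}

.comorbid_rr <- function(P, idx, params) {
  rr <- params$demography$mortality_rr
  out <- rep(1, length(idx))
  out <- out * ifelse(P$diabetes[idx], rr[["diabetes"]], 1)
  out <- out * ifelse(P$htn[idx], rr[["htn"]], 1)
  out <- out * ifelse(P$cvd[idx], rr[["cvd"]], 1)
  out <- out * ifelse(P$stroke[idx], rr[["stroke"]], 1)
  out <- out * ifelse(P$ulcer[idx], rr[["ulcer"]], 1)
  out
}

#' Advance demographics by one year
#'
#' Ages every surviving member by one year, samples background mortality and
#' emigration, and adds the configured counts of new 20-year-olds and
#' immigrants. Entry counts are exogenous (proportional to the initial
#' population size), so population identity and person ids are independent
#' of within-scenario events — a requirement for common-random-number
#' coupling across scenarios.
#'
#' @param pop an `oa_population` object.
#' @param params an `oa_params` object.
#' @return list with elements `population` (updated), `tally` (named counts:
#'   deaths, emigrants, entrants, immigrants), and index vectors
#'   `deaths`, `emigrants`, `new` into the updated population.
#' @export
advance_demographics <- function(pop, params) {
  P <- pop
  year <- P$year + 1L
  P$year <- year
  alive <- which(P$alive & P$in_pop)
  P$age[alive] <- P$age[alive] + 1L

  u_death <- substream_uniform(P$seed, P$id[alive], .streams$death, year)
  died <- sample_background_death(P$age[alive], P$sex[alive], year,
                                  .comorbid_rr(P, alive, params), params,
                                  u_death)
  death_idx <- alive[died]
  P$alive[death_idx] <- FALSE

  survivors <- alive[!died]
  u_emig <- substream_uniform(P$seed, P$id[survivors], .streams$emigration,
                              year)
  emig_idx <- survivors[u_emig < params$demography$emigration_rate]
  P$in_pop[emig_idx] <- FALSE

  n_entry <- as.integer(round(params$demography$entry_rate * P$n_initial))
  n_imm <- as.integer(round(params$demography$immigration_rate * P$n_initial))
  new_idx <- integer(0)
  if (n_entry + n_imm > 0) {
    ids <- seq.int(P$next_id, length.out = n_entry + n_imm)
    prev_tables <- attr(pop, "prev_tables")
    if (is.null(prev_tables)) prev_tables <- .prev_tables(params)
    entrants <- if (n_entry > 0)
      .draw_persons(params, ids[seq_len(n_entry)], year, P$seed, age = 20L,
                    prev_tables = prev_tables)
    imm <- if (n_imm > 0) {
      pp <- params
      amax <- params$demography$immigrant_age_max
      keep <- params$demography$ages <= amax
      pp$demography$age_pyramid_male <- params$demography$age_pyramid_male *
        keep
      pp$demography$age_pyramid_female <-
        params$demography$age_pyramid_female * keep
      .draw_persons(pp, ids[n_entry + seq_len(n_imm)], year, P$seed,
                    prev_tables = prev_tables)
    }
    new <- if (is.null(entrants)) imm
           else if (is.null(imm)) entrants
           else Map(function(a, b) if (is.matrix(a)) rbind(a, b) else c(a, b),
                    entrants, imm)
    n_before <- length(P$id)
    P <- .bind_persons(P, new)
    new_idx <- n_before + seq_along(ids)
    P$next_id <- as.integer(P$next_id + length(ids))
  }
  class(P) <- "oa_population"
  attr(P, "prev_tables") <- attr(pop, "prev_tables")
  list(population = P,
       tally = c(deaths = length(death_idx), emigrants = length(emig_idx),
                 entrants = n_entry, immigrants = n_imm),
       deaths = death_idx, emigrants = emig_idx, new = new_idx)
}

#' Export a population snapshot
#'
#' One row per person: id, sex, age, bmi, OA status, pain level, medication
#' flags, surgery counts, vital status.
#' @param pop an `oa_population` object.
#' @return a data frame.
#' @export
population_snapshot <- function(pop) {
  data.frame(id = pop$id, year = pop$year,
             sex = c("male", "female")[pop$sex], age = pop$age,
             bmi = pop$bmi, has_oa = pop$has_oa, pain = pop$hui[, 8L],
             acetaminophen = pop$med[, 1L], nsaid = pop$med[, 2L],
             coxib = pop$med[, 3L], opioid = pop$med[, 4L],
             n_primary_jrs = pop$n_primary, n_revision_jrs = pop$n_revision,
             alive = pop$alive, in_population = pop$in_pop)
}
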