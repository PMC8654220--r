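# Intervention scenarios: the base case and the eight counterfactuals
# (two medication, two surgery, four BMI-reduction scenarios), plus the
# suppressed-treatment counterfactual used to compute total OA DALYs.

.scenario_names <- c("Base-case", "Medication x2", "Medication x3",
                     "Surgery x2", "Surgery x3", "BMI-0.1", "BMI-0.3",
                     "BMI-0.5", "BMI-1.0")

#' Names of the nine inter-strategy comparison scenarios
#' @return character vector.
#' @export
scenario_names <- function() .scenario_names

.empty_mods <- function() {
  data.frame(drug = character(), multiplier = numeric(),
             pain_lo = numeric(), pain_hi = numeric(), age_lo = numeric(),
             age_hi = numeric(), stringsAsFactors = FALSE)
}

# targeted medication modifiers: acetaminophen for pain >= 2 at any age;
# NSAIDs and coxibs for pain >= 2 at ages 20-69 but only pain >= 3 at 70+;
# opioids for pain >= 3 at any age. Target groups exclude the cells where
# net harm is expected (older users with mild pain; opioids at mild pain).
.med_modifiers <- function(m) {
  data.frame(
    drug = c("acetaminophen", "nsaid", "nsaid", "coxib", "coxib", "opioid"),
    multiplier = m,
    pain_lo = c(2, 2, 3, 2, 3, 3),
    pain_hi = 5,
    age_lo = c(20, 20, 70, 20, 70, 20),
    age_hi = c(Inf, 69, Inf, 69, Inf, Inf),
    stringsAsFactors = FALSE)
}

.new_scenario <- function(name, family, med_modifiers = .empty_mods(),
                          jrs_multiplier = 1, bmi_reduction = 0,
                          start_year = 2020) {
  structure(list(name = name, family = family, start_year = start_year,
                 med_modifiers = med_modifiers,
                 jrs_multiplier = jrs_multiplier, jrs_min_pain = 2,
                 revision_multiplier = FALSE,
                 bmi_reduction = bmi_reduction, bmi_threshold = 25,
                 suppress_treatment = FALSE),
            class = "oa_scenario")
}

#' Build a named intervention scenario
#'
#' Returns the exact specification of one of the nine comparison scenarios:
#' no intervention (base case); medication odds multiplied by 2 or 3 in the
#' targeted groups; JRS hazard multiplied by 2 or 3 in persons with OA and
#' pain >= 2; or BMI reduced by 0.1/0.3/0.5/1.0 units per year while BMI >=
#' 25. Interventions start in 2020 unless `start_year` is overridden.
#'
#' @param name one of [scenario_names()].
#' @param start_year first year the intervention is active.
#' @return an `oa_scenario` object.
#' @export
build_scenario <- function(name, start_year = 2020) {
  if (!name %in% .scenario_names)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(.scenario_names, collapse = ", "), call. = FALSE)
  sc <- switch(
    name,
    "Base-case" = .new_scenario(name, "base"),
    "Medication x2" = .new_scenario(name, "medication",
                                    med_modifiers = .med_modifiers(2)),
    "Medication x3" = .new_scenario(name, "medication",
                                    med_modifiers = .med_modifiers(3)),
    "Surgery x2" = .new_scenario(name, "surgery", jrs_multiplier = 2),
    "Surgery x3" = .new_scenario(name, "surgery", jrs_multiplier = 3),
    "BMI-0.1" = .new_scenario(name, "bmi", bmi_reduction = 0.1),
    "BMI-0.3" = .new_scenario(name, "bmi", bmi_reduction = 0.3),
    "BMI-0.5" = .new_scenario(name, "bmi", bmi_reduction = 0.5),
    "BMI-1.0" = .new_scenario(name, "bmi", bmi_reduction = 1.0))
  sc$start_year <- start_year
  sc
}

#' The suppressed-treatment counterfactual
#'
#' A base-case-like run in which every effect of drugs and surgery is
#' suppressed (no pain relief, no side effects, no surgical improvement or
#' perioperative mortality). The person-time difference against the base
#' case yields OA-related years of life lost for the total-burden
#' denominator.
#' @return an `oa_scenario` object.
#' @export
suppressed_treatment_scenario <- function() {
  sc <- .new_scenario("Suppressed-treatment", "suppressed")
  sc$suppress_treatment <- TRUE
  sc
}

#' Run a set of scenarios under common random numbers
#'
#' All scenarios share one initial population and the same master seed;
#' counter-based substreams guarantee that an individual untouched by an
#' intervention has an identical trajectory in every scenario. The base
#' case is added automatically if absent.
#'
#' @param params an `oa_params` object.
#' @param scenarios character vector of scenario names and/or a list of
#'   `oa_scenario` objects.
#' @param n initial population size.
#' @param start_year first simulated year (default 2020).
#' @param end_year last simulated year.
#' @param seed master seed.
#' @param include_suppressed also run the suppressed-treatment
#'   counterfactual (needed for percentage-of-total-DALY reporting).
#' @param ... passed to [simulate_scenario()].
#' @return named list of per-scenario results (see [simulate_scenario()]),
#'   with attribute `n` and `seed`.
#' @export
run_scenarios <- function(params, scenarios = scenario_names(), n = 10000,
                          start_year = 2020, end_year = 2040, seed = 1L,
                          include_suppressed = FALSE, ...) {
  if (end_year < start_year) stop("horizon must be >= 1 year", call. = FALSE)
  scens <- lapply(scenarios, function(s)
    if (inherits(s, "oa_scenario")) s else build_scenario(s))
  names(scens) <- vapply(scens, `[[`, character(1), "name")
  if (!"Base-case" %in% names(scens))
    scens <- c(list("Base-case" = build_scenario("Base-case")), scens)
  if (include_suppressed &&
      !"Suppressed-treatment" %in% names(scens))
    scens <- c(scens,
               list("Suppressed-treatment" = suppressed_treatment_scenario()))
  pop <- initialize_population(params, n, start_year, seed)
  out <- lapply(scens, function(sc)
    simulate_scenario(params, sc, pop, end_year, ...))
  attr(out, "n") <- n
  attr(out, "seed") <- seed
  attr(out, "start_year") <- start_year
  attr(out, "end_year") <- end_year
  out
}

#' Preliminary subgroup analysis of candidate medication targets
#'
#' For each (drug, pain level, age group) cell, increases the odds of using
#' the drug (multiplier `m`) in that cell only and reports the difference in
#' total QALYs per 1000 initial persons against the base case, under common
#' random numbers. Used to identify the target groups in which pain-relief
#' benefits outweigh side-effect harms.
#'
#' @param params an `oa_params` object.
#' @param drugs drug names to assess.
#' @param multiplier odds multiplier for the candidate intervention.
#' @param pain_levels pain levels (or ranges) to assess: a vector of single
#'   levels, or a list whose elements are single levels or `c(lo, hi)`
#'   ranges (e.g. `list(2, c(3, 5))`).
#' @param n initial population size.
#' @param start_year,end_year horizon of the assessment.
#' @param seed master seed.
#' @return data frame with columns drug, multiplier, pain_level, age_group,
#'   d_qaly_per_1000.
#' @export
preliminary_subgroup_analysis <- function(params, drugs = .drugs,
                                          multiplier = 2, pain_levels = 2:5,
                                          n = 20000, start_year = 2020,
                                          end_year = 2040, seed = 1L) {
  if (!is.list(pain_levels)) pain_levels <- as.list(pain_levels)
  pop <- initialize_population(params, n, start_year, seed)
  base <- simulate_scenario(params, build_scenario("Base-case"), pop,
                            end_year, person_qaly = TRUE)
  res <- list()
  for (d in drugs) for (pl in pain_levels) {
    lo <- pl[1]; hi <- pl[length(pl)]
    mods <- data.frame(drug = d, multiplier = multiplier, pain_lo = lo,
                       pain_hi = hi, age_lo = 20, age_hi = Inf,
                       stringsAsFactors = FALSE)
    sc <- .new_scenario(paste0(d, " x", multiplier, " pain ", lo, "-", hi),
                        "medication", med_modifiers = mods,
                        start_year = start_year)
    r <- simulate_scenario(params, sc, pop, end_year, person_qaly = TRUE)
    m <- max(length(base$person_qaly), length(r$person_qaly))
    dq <- `length<-`(r$person_qaly, m)
    dq[is.na(dq)] <- 0
    bq <- `length<-`(base$person_qaly, m)
    bq[is.na(bq)] <- 0
    delta <- dq - bq
    old <- `length<-`(r$person_age0 >= 70, m)
    old[is.na(old)] <- FALSE
    for (ag in c("20-69", "70+")) {
      sel <- if (ag == "70+") old else !old
      res[[length(res) + 1L]] <- data.frame(
        drug = d, multiplier = multiplier,
        pain_level = if (lo == hi) as.character(lo) else paste0(lo, "-", hi),
        age_group = ag, d_qaly_per_1000 = 1000 * sum(delta[sel]) / n,
        mc_se_per_1000 = 1000 * stats::sd(delta[sel]) * sqrt(sum(sel)) / n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
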