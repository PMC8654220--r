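# The annual simulation engine. Within-year event order (fixed):
#   1. demographics: aging, background death, emigration, entry, immigration
#   2. autoregressive BMI update
#   3. preventive BMI reduction (scenario)
#   4. OA incidence
#   5. medication sampling (with scenario odds modifiers)
#   6. side effects, including overdose and case-fatality deaths
#   7. JRS sampling (with scenario hazard multiplier), perioperative death,
#      and HUI3 domain improvements
#   8. hierarchical HUI3 update (pain last), then same-year drug pain effects
#   9. accounting snapshot
# Decedents contribute 0.5 person-years in their death year at their
# pre-update utility; emigrants contribute none in the exit year.

.measures <- c("pt", "pt_oa", "pt_free", "uw_oa", "uw_non", "qaly",
               "deaths", "trt_deaths", "periop_deaths", "overdose_deaths",
               "gi_events", "cvd_events", "cvd_excess", "stroke_events",
               "stroke_excess", "dysp_events", "primary_jrs", "revision_jrs",
               "oa_incident", "n_alive", "n_oa",
               "users_acetaminophen", "users_nsaid", "users_coxib",
               "users_opioid")

.acc4 <- function(val, grp) {
  out <- numeric(4)
  if (!length(val)) return(out)
  s <- rowsum(as.numeric(val), grp)
  out[as.integer(rownames(s))] <- s
  out
}

# HUI3/medication/surgery-history burn-in: brings the joint (health state,
# medication, treated pain, OA stage) distribution near stationarity before
# the first accounted year. Demography, OA incidence and side effects are
# frozen; surgeries occur (without perioperative mortality) so that the
# post-JRS stage mix reaches its steady-state share.
.burnin_population <- function(P, params) {
  models <- .compile_hui_models(params)
  nb <- params$burnin_years
  start <- P$year - nb + 1L
  idx <- seq_along(P$id)
  for (year in seq.int(start, P$year)) {
    oa <- idx[P$has_oa]
    stage <- .oa_stage_code(P$has_oa[oa], P$oa_onset_year[oa],
                            P$last_jrs_year[oa], year)
    probs <- medication_probabilities(P$age[oa], P$sex[oa], stage,
                                      P$hui[oa, 8L], params$medications)
    Um <- substream_uniform_mat(P$seed, P$id[oa], .streams$med, year)
    P$med[] <- FALSE
    P$med[oa, ] <- sample_medications(probs, Um)

    up <- substream_uniform(P$seed, P$id[oa], .streams$jrs_primary, year)
    ur <- substream_uniform(P$seed, P$id[oa], .streams$jrs_revision, year)
    js <- sample_jrs(P$age[oa], P$sex[oa], P$hui[oa, 8L], year,
                     P$n_primary[oa], params$jrs, 1, up, ur)
    surg <- oa[js$primary | js$revision]
    P$n_primary[oa[js$primary]] <- P$n_primary[oa[js$primary]] + 1L
    if (length(surg)) {
      P$last_jrs_year[surg] <- year
      upain <- substream_uniform(P$seed, P$id[surg], .streams$jrs_pain, year)
      umob <- substream_uniform(P$seed, P$id[surg], .streams$jrs_mobility,
                                year)
      P$hui[surg, 8L] <- apply_pain_change(
        P$hui[surg, 8L], .sample_improvement(params$jrs$improve_pain, upain))
      P$hui[surg, 6L] <- pmax(
        P$hui[surg, 6L] - (umob >= params$jrs$improve_mobility[1]), 1L)
    }

    X <- .hui_design(P, idx, year)
    U <- substream_uniform_mat(P$seed, P$id, .streams$hui, year)
    P$hui <- update_hui3(X, P$hui, models, U)

    imp <- integer(length(oa))
    for (k in seq_along(.drugs)) {
      uk <- substream_uniform(P$seed, P$id[oa], .streams$painfx[k], year)
      eff <- params$medications[[.drugs[k]]]$effect
      imp <- imp + ifelse(P$med[oa, k], .sample_improvement(eff, uk), 0L)
    }
    P$hui[oa, 8L] <- apply_pain_change(P$hui[oa, 8L], imp)
  }
  P
}

# scenario medication probabilities with odds modifiers applied to matching
# target groups
.scenario_med_probs <- function(probs, scen, age, pain, active) {
  if (!active || is.null(scen$med_modifiers) || !nrow(scen$med_modifiers))
    return(probs)
  mm <- scen$med_modifiers
  for (r in seq_len(nrow(mm))) {
    d <- mm$drug[r]
    hit <- pain >= mm$pain_lo[r] & pain <= mm$pain_hi[r] &
      age >= mm$age_lo[r] & age <= mm$age_hi[r]
    probs[hit, d] <- apply_odds_multiplier(probs[hit, d], mm$multiplier[r])
  }
  probs
}

#' Simulate one scenario
#'
#' Runs the annual engine from `start_year` to `end_year` and returns the
#' stratified person-year table. All randomness comes from counter-based
#' substreams of `pop$seed`, so runs of different scenarios from the same
#' initial population are coupled by common random numbers.
#'
#' @param params an `oa_params` object.
#' @param scenario an `oa_scenario` (see [build_scenario()]).
#' @param pop initial population from [initialize_population()].
#' @param end_year last simulated calendar year.
#' @param trace optional `function(population, year)` called after each
#'   accounted year (for diagnostics).
#' @param person_qaly logical; also accumulate per-person QALY totals.
#' @param keep_population logical; return the final population.
#' @return list with `table` (person-year data frame: scenario, year, sex,
#'   agegrp, measures), `tally` (annual demographic-flow data frame), and
#'   optionally `person_qaly`, `person_age0`, `population`.
#' @export
simulate_scenario <- function(params, scenario, pop, end_year, trace = NULL,
                              person_qaly = FALSE, keep_population = FALSE) {
  P <- pop
  seed <- P$seed
  start_year <- P$year + 1L
  if (end_year < start_year) stop("horizon must be >= 1 year", call. = FALSE)
  years <- seq.int(start_year, end_year)
  ny <- length(years)
  acc <- array(0, dim = c(ny, 4L, length(.measures)),
               dimnames = list(NULL, NULL, .measures))
  tallies <- matrix(0L, ny, 4L,
                    dimnames = list(NULL, c("deaths", "emigrants",
                                            "entrants", "immigrants")))
  models <- .compile_hui_models(params)
  pq <- if (person_qaly) numeric(5L * length(P$id)) else NULL
  rev_mult <- isTRUE(scenario$revision_multiplier)
  supp <- isTRUE(scenario$suppress_treatment)

  for (yi in seq_len(ny)) {
    year <- years[yi]
    active <- year >= scenario$start_year

    # 1. demographics
    adv <- advance_demographics(P, params)
    P <- adv$population
    tallies[yi, ] <- adv$tally
    died <- adv$deaths # background deaths this year
    alive <- which(P$alive & P$in_pop)

    # 2-3. BMI
    noise <- substream_normal(seed, P$id[alive], .streams$bmi, year)
    P$bmi[alive] <- as.numeric(update_bmi(P$bmi[alive], P$age[alive],
                                          P$edu[alive], P$income[alive],
                                          P$region[alive], P$sex[alive],
                                          params$bmi_model, noise))
    if (active && scenario$bmi_reduction > 0)
      P$bmi[alive] <- apply_bmi_reduction(P$bmi[alive],
                                          scenario$bmi_reduction,
                                          scenario$bmi_threshold)

    # 4. OA incidence
    free <- alive[!P$has_oa[alive]]
    if (length(free)) {
      haz <- oa_hazard(P$age[free], P$sex[free], P$bmi[free],
                       params$oa_incidence)
      u_oa <- substream_uniform(seed, P$id[free], .streams$oa, year)
      onset <- sample_oa_onset(haz, u_oa)
      P$has_oa[free[onset]] <- TRUE
      P$oa_onset_year[free[onset]] <- year
      n_onset_idx <- free[onset]
    } else n_onset_idx <- integer(0)

    # 5. medication sampling (OA members only)
    oa <- alive[P$has_oa[alive]]
    P$med[] <- FALSE
    if (length(oa)) {
      stage <- .oa_stage_code(P$has_oa[oa], P$oa_onset_year[oa],
                              P$last_jrs_year[oa], year)
      probs <- medication_probabilities(P$age[oa], P$sex[oa], stage,
                                        P$hui[oa, 8L], params$medications)
      probs <- .scenario_med_probs(probs, scenario, P$age[oa], P$hui[oa, 8L],
                                   active)
      Um <- substream_uniform_mat(seed, P$id[oa], .streams$med, year)
      P$med[oa, ] <- sample_medications(probs, Um)
    }

    # 6. side effects
    se_death_idx <- integer(0); trt_death_idx <- integer(0)
    se <- NULL
    if (!supp && length(alive)) {
      Us <- substream_uniform_mat(
        seed, P$id[alive],
        c(.streams$gi, .streams$cvd, .streams$stroke, .streams$dyspepsia,
          .streams$overdose, .streams$gi_fatal, .streams$cvd_fatal,
          .streams$stroke_fatal), year)
      colnames(Us) <- c("gi", "cvd", "stroke", "dysp", "overdose",
                        "gi_fatal", "cvd_fatal", "stroke_fatal")
      se <- sample_side_effects(
        P$med[alive, , drop = FALSE], P$age[alive], P$sex[alive],
        P$cvd[alive], P$stroke[alive],
        .dysp_active(P$dysp_year[alive], year,
                     params$side_effects$dyspepsia_duration),
        params, Us)
      P$ulcer[alive[se$gi & !se$gi_death]] <- TRUE
      P$cvd[alive[se$cvd & !se$cvd_death]] <- TRUE
      P$stroke[alive[se$stroke & !se$stroke_death]] <- TRUE
      P$dysp_year[alive[se$dysp]] <- year
      se_death_idx <- alive[se$death]
      trt_death_idx <- alive[se$trt_death]
      P$alive[se_death_idx] <- FALSE
    }
    alive2 <- if (length(se_death_idx)) which(P$alive & P$in_pop) else alive

    # 7. joint replacement
    periop_idx <- integer(0); prim_idx <- integer(0); revi_idx <- integer(0)
    oa2 <- alive2[P$has_oa[alive2]]
    if (length(oa2)) {
      mult <- rep(1, length(oa2))
      if (active && scenario$jrs_multiplier != 1)
        mult[P$hui[oa2, 8L] >= scenario$jrs_min_pain] <-
          scenario$jrs_multiplier
      up <- substream_uniform(seed, P$id[oa2], .streams$jrs_primary, year)
      ur <- substream_uniform(seed, P$id[oa2], .streams$jrs_revision, year)
      js <- sample_jrs(P$age[oa2], P$sex[oa2], P$hui[oa2, 8L], year,
                       P$n_primary[oa2], params$jrs, mult, up, ur, rev_mult)
      prim_idx <- oa2[js$primary]
      revi_idx <- oa2[js$revision & !js$primary]
      surg_idx <- c(prim_idx, revi_idx)
      P$n_primary[prim_idx] <- P$n_primary[prim_idx] + 1L
      P$n_revision[revi_idx] <- P$n_revision[revi_idx] + 1L
      if (!supp && length(surg_idx)) {
        upo <- substream_uniform(seed, P$id[surg_idx], .streams$periop, year)
        periop_idx <- surg_idx[upo < params$treatment_mortality$jrs_periop]
        P$alive[periop_idx] <- FALSE
        surv <- setdiff(surg_idx, periop_idx)
        P$last_jrs_year[surv] <- year
        upain <- substream_uniform(seed, P$id[surv], .streams$jrs_pain, year)
        umob <- substream_uniform(seed, P$id[surv], .streams$jrs_mobility,
                                  year)
        P$hui[surv, 8L] <- apply_pain_change(
          P$hui[surv, 8L], .sample_improvement(params$jrs$improve_pain,
                                               upain))
        P$hui[surv, 6L] <- pmax(
          P$hui[surv, 6L] - (umob >= params$jrs$improve_mobility[1]), 1L)
      } else if (length(surg_idx)) {
        P$last_jrs_year[surg_idx] <- year
      }
    }
    alive3 <- which(P$alive & P$in_pop)

    # 8. HUI3 update, pain last; then same-year drug pain effects
    if (length(alive3)) {
      X <- .hui_design(P, alive3, year)
      U <- substream_uniform_mat(seed, P$id[alive3], .streams$hui, year)
      P$hui[alive3, ] <- update_hui3(X, P$hui[alive3, , drop = FALSE],
                                     models, U)
      if (!supp) {
        oa3 <- alive3[P$has_oa[alive3]]
        if (length(oa3)) {
          imp <- integer(length(oa3))
          for (k in seq_along(.drugs)) {
            uk <- substream_uniform(seed, P$id[oa3], .streams$painfx[k],
                                    year)
            eff <- params$medications[[.drugs[k]]]$effect
            imp <- imp + ifelse(P$med[oa3, k],
                                .sample_improvement(eff, uk), 0L)
          }
          P$hui[oa3, 8L] <- apply_pain_change(P$hui[oa3, 8L], imp)
        }
      }
    }

    # 9. accounting
    dead_now <- c(died, se_death_idx, periop_idx)
    contrib <- c(alive3, dead_now)
    ptw <- c(rep(1, length(alive3)), rep(0.5, length(dead_now)))
    grp <- P$sex[contrib] + 2L * (P$age[contrib] >= 70L)
    util <- hui3_utility(P$hui[contrib, , drop = FALSE], params$utility_map)
    is_oa <- P$has_oa[contrib]

    a <- function(m, v, g = grp) acc[yi, , m] <<- acc[yi, , m] + .acc4(v, g)
    a("pt", ptw)
    a("pt_oa", ptw * is_oa)
    a("pt_free", ptw * !is_oa)
    a("uw_oa", ptw * util * is_oa)
    a("uw_non", ptw * util * !is_oa)
    a("qaly", ptw * util)
    a("deaths", rep(1, length(dead_now)), grp[length(alive3) + seq_along(dead_now)])
    grp_of <- function(idx) P$sex[idx] + 2L * (P$age[idx] >= 70L)
    a("trt_deaths", rep(1, length(trt_death_idx)), grp_of(trt_death_idx))
    a("periop_deaths", rep(1, length(periop_idx)), grp_of(periop_idx))
    if (!is.null(se)) {
      a("overdose_deaths", as.numeric(se$overdose_death), grp_of(alive))
      a("gi_events", as.numeric(se$gi), grp_of(alive))
      a("cvd_events", as.numeric(se$cvd), grp_of(alive))
      a("cvd_excess", as.numeric(se$cvd_excess), grp_of(alive))
      a("stroke_events", as.numeric(se$stroke), grp_of(alive))
      a("stroke_excess", as.numeric(se$stroke_excess), grp_of(alive))
      a("dysp_events", as.numeric(se$dysp), grp_of(alive))
    }
    a("primary_jrs", rep(1, length(prim_idx)), grp_of(prim_idx))
    a("revision_jrs", rep(1, length(revi_idx)), grp_of(revi_idx))
    a("oa_incident", rep(1, length(n_onset_idx)), grp_of(n_onset_idx))
    a("n_alive", rep(1, length(alive3)), grp_of(alive3))
    a("n_oa", as.numeric(P$has_oa[alive3]), grp_of(alive3))
    oa_all <- contrib[is_oa]
    for (k in seq_along(.drugs))
      a(paste0("users_", .drugs[k]), as.numeric(P$med[oa_all, k]),
        grp_of(oa_all))

    if (person_qaly) {
      if (length(P$id) > length(pq)) pq <- c(pq, numeric(length(P$id)))
      pq[contrib] <- pq[contrib] + ptw * util
    }
    if (!is.null(trace)) trace(P, year)
  }

  tab <- do.call(rbind, lapply(1:4, function(g) {
    m <- acc[, g, , drop = FALSE]
    dim(m) <- c(ny, length(.measures))
    colnames(m) <- .measures
    data.frame(scenario = scenario$name, year = years,
               sex = c("male", "female")[1 + (g - 1) %% 2],
               agegrp = c("20-69", "70+")[1 + (g > 2)],
               m, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  rownames(tab) <- NULL
  out <- list(table = tab,
              tally = data.frame(year = years, tallies,
                                 check.names = FALSE))
  if (person_qaly) {
    out$person_qaly <- pq[seq_along(P$id)]
    out$person_age0 <- P$age0
    out$person_sex <- P$sex
  }
  if (keep_population) out$population <- P
  out
}
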