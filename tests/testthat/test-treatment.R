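test_that("odds multiplication matches the hand odds computation", {
  expect_equal(apply_odds_multiplier(0.5, 2), 2 / 3, tolerance = 1e-15)
  expect_equal(apply_odds_multiplier(0.3, 1), 0.3)
  expect_equal(apply_odds_multiplier(0.2, 3), 0.75 / 1.75, tolerance = 1e-15)
  expect_equal(apply_odds_multiplier(c(0, 1), 7), c(0, 1))
  expect_equal(apply_odds_multiplier(1, 0), 0)

  # strictly increasing in the multiplier on the open interval
  p <- 0.37
  ms <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(apply_odds_multiplier(p, ms)) > 0))
})

test_that("medication lookup reads the configured cells", {
  p <- default_params
  p$medications$nsaid$prevalence["50-54", "male", "oa_lt5", "3"] <- 0.377
  got <- medication_probabilities(52L, 1L, 1L, 3L, p$medications)
  expect_equal(unname(got[, "nsaid"]), 0.377)

  zero <- default_params
  for (d in names(zero$medications))
    zero$medications[[d]]$prevalence[, , , 1] <- 0
  got <- medication_probabilities(c(40L, 80L), c(1L, 2L), c(2L, 4L),
                                  c(1L, 1L), zero$medications)
  expect_true(all(got == 0))
})

test_that("drug use is sampled independently with co-use allowed", {
  n <- 1e5
  U <- oasim:::substream_uniform_mat(13, seq_len(n), 10:13, 2020)
  expect_false(any(sample_medications(matrix(0, n, 4), U)))
  expect_true(all(sample_medications(matrix(1, n, 4), U)))

  probs <- matrix(rep(c(0.4, 0.4, 0, 0), each = n), n)
  use <- sample_medications(probs, U)
  joint <- mean(use[, 1] & use[, 2])
  expect_lt(abs(joint - 0.16), 3 * sqrt(0.16 * 0.84 / n))
})

test_that("side effects honour linkage, attribution, and event scales", {
  p <- default_params
  n <- 1e5
  U <- oasim:::substream_uniform_mat(17, seq_len(n), 20:27, 2020)
  colnames(U) <- c("gi", "cvd", "stroke", "dysp", "overdose", "gi_fatal",
                   "cvd_fatal", "stroke_fatal")
  none <- matrix(FALSE, n, 4, dimnames = list(NULL, names(p$medications)))
  se0 <- sample_side_effects(none, rep(60L, n), rep(1L, n), rep(FALSE, n),
                             rep(FALSE, n), rep(FALSE, n), p, U)
  expect_false(any(se0$gi))
  expect_false(any(se0$dysp))
  expect_false(any(se0$overdose_death))
  expect_false(any(se0$cvd_excess))
  expect_false(any(se0$trt_death))
  expect_gt(sum(se0$cvd), 0) # background risk still applies

  # NSAID users: GI events at the configured age-specific excess rate
  nsaid <- none; nsaid[, "nsaid"] <- TRUE
  se1 <- sample_side_effects(nsaid, rep(50L, n), rep(1L, n), rep(FALSE, n),
                             rep(FALSE, n), rep(FALSE, n), p, U)
  rate <- p$side_effects$gi_excess50[["nsaid"]]
  expect_lt(abs(sum(se1$gi) - n * rate), 4 * sqrt(n * rate) + 1)
  # CVD attribution: excess events are exactly those between baseline and
  # user-level risk
  base_p <- pmin(p$side_effects$cvd_baseline50[["male"]],
                 p$side_effects$cvd_baseline_cap)
  user_p <- base_p * p$side_effects$cvd_rr[["nsaid"]]
  expect_identical(se1$cvd_excess,
                   se1$cvd & U[, "cvd"] >= base_p & U[, "cvd"] < user_p)

  # opioid non-users can never die of overdose
  expect_false(any(se1$overdose_death))
  opioid <- none; opioid[, "opioid"] <- TRUE
  se2 <- sample_side_effects(opioid, rep(50L, n), rep(1L, n), rep(FALSE, n),
                             rep(FALSE, n), rep(FALSE, n), p, U)
  expect_gt(sum(se2$overdose_death), 0)
})

test_that("no drugs and no surgery mean zero treatment-attributable deaths", {
  p <- untreated_params()
  pop <- initialize_population(p, 5000, 2020, 10)
  r <- simulate_scenario(p, build_scenario("Base-case"), pop, 2030)
  expect_identical(sum(r$table$trt_deaths), 0)
  expect_identical(sum(r$table$periop_deaths), 0)
  expect_identical(sum(r$table$overdose_deaths), 0)
  expect_identical(sum(r$table$primary_jrs), 0)
  expect_identical(sum(r$table$users_nsaid), 0)
})

test_that("the surgery hazard matches its log-linear form", {
  m <- default_params$jrs
  m$age_coef <- 0; m$female_coef <- 0; m$year_coef <- 0
  m$intercept <- log(0.045)
  m$pain_or <- rep(1, 5); m$or_norm <- 1
  expect_equal(jrs_rate(70L, 1L, 3L, 2020, m), 0.045, tolerance = 1e-12)

  # monotone pain modifier implies monotone hazard, all else equal
  d <- default_params$jrs
  h <- jrs_rate(rep(70L, 5), rep(1L, 5), 1:5, 2020, d)
  expect_true(all(diff(h) > 0))

  # hand-evaluated exponential
  expect_equal(jrs_rate(75L, 2L, 4L, 2026, d),
               exp(d$intercept + d$age_coef * 10 + d$female_coef +
                     d$year_coef * 6) * d$pain_or[4] / d$or_norm)
})

test_that("surgery sampling caps primaries and scales the hazard", {
  m <- default_params$jrs
  got <- sample_jrs(rep(70L, 3), rep(1L, 3), rep(4L, 3), 2020,
                    n_primary = c(4L, 4L, 0L), m, multiplier = 1,
                    u_primary = rep(1e-9, 3), u_revision = rep(1e-9, 3))
  expect_identical(got$primary, c(FALSE, FALSE, TRUE))
  expect_identical(got$revision, c(TRUE, TRUE, FALSE))

  # probability under a multiplier is 1 - exp(-m h): check both sides of the
  # threshold
  h <- jrs_rate(70L, 1L, 4L, 2020, m)
  thr <- 1 - exp(-2 * h)
  below <- sample_jrs(70L, 1L, 4L, 2020, 0L, m, 2, thr - 1e-9, 1)
  above <- sample_jrs(70L, 1L, 4L, 2020, 0L, m, 2, thr + 1e-9, 1)
  expect_true(below$primary)
  expect_false(above$primary)
})

test_that("medication scenarios raise year-one drug use monotonically", {
  res <- run_scenarios(default_params,
                       c("Medication x2", "Medication x3"),
                       n = 30000, end_year = 2021, seed = 12)
  use <- sapply(res[c("Base-case", "Medication x2", "Medication x3")],
                function(r) {
                  y <- r$table[r$table$year == 2020, ]
                  c(acet = sum(y$users_acetaminophen), nsaid = sum(y$users_nsaid),
                    coxib = sum(y$users_coxib), opioid = sum(y$users_opioid)) /
                    sum(y$pt_oa)
                })
  for (d in rownames(use)) {
    expect_gt(use[d, "Medication x2"], use[d, "Base-case"], label = d)
    expect_gt(use[d, "Medication x3"], use[d, "Medication x2"], label = d)
  }
})

test_that("surgical uptake peaks later than medication in OA quality of life", {
  res <- run_scenarios(default_params, c("Medication x2", "Surgery x2"),
                       n = 30000, end_year = 2034, seed = 12)
  mean_hui <- function(r) {
    y <- collapse_years(r$table)
    y$uw_oa / y$pt_oa
  }
  base <- mean_hui(res[["Base-case"]])
  dmed <- mean_hui(res[["Medication x2"]]) - base
  dsur <- mean_hui(res[["Surgery x2"]]) - base
  years <- sort(unique(res[["Base-case"]]$table$year))
  expect_gt(max(dmed), 0)
  expect_gt(max(dsur), 0)
  expect_lt(years[which.max(dmed)], years[which.max(dsur)])

  surg_extra <- sum(res[["Surgery x2"]]$table$primary_jrs) -
    sum(res[["Base-case"]]$table$primary_jrs)
  expect_gt(surg_extra, 0)
})
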