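test_that("counter-based substreams are reproducible and well separated", {
  u1 <- substream_uniform(1, 1:1000, 5, 2020)
  expect_identical(u1, substream_uniform(1, 1:1000, 5, 2020))
  expect_false(any(u1 == substream_uniform(1, 1:1000, 6, 2020)))
  expect_false(any(u1 == substream_uniform(1, 1:1000, 5, 2021)))
  expect_false(any(u1 == substream_uniform(2, 1:1000, 5, 2020)))
  expect_true(all(u1 > 0 & u1 < 1))
  expect_lt(abs(mean(u1) - 0.5), 0.05)
})

test_that("population initialization is deterministic and validates inputs", {
  expect_error(initialize_population(default_params, 0), "n must be > 0")
  p1 <- initialize_population(default_params, 1000, 2020, 7)
  p2 <- initialize_population(default_params, 1000, 2020, 7)
  expect_identical(unclass(p1), unclass(p2))
  expect_true(all(p1$age >= 20))
  expect_identical(anyDuplicated(p1$id), 0L)
})

test_that("initial age structure follows the configured pyramid", {
  pop <- initialize_population(default_params, 20000, 2020, 3,
                               burnin = FALSE)
  d <- default_params$demography
  expected <- (1 - d$sex_female) * sum(d$age_pyramid_male[d$ages >= 70]) +
    d$sex_female * sum(d$age_pyramid_female[d$ages >= 70])
  observed <- mean(pop$age >= 70)
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(observed - expected), 4 * se)
  # the configured default sits in the low-to-mid teens (percent)
  expect_gt(observed, 0.10)
  expect_lt(observed, 0.17)
})

test_that("zero configured prevalence yields an OA-free population", {
  p <- default_params
  p$oa_incidence$base_per_1000[] <- 0
  pop <- initialize_population(p, 2000, 2020, 1, burnin = FALSE)
  expect_false(any(pop$has_oa))
})

test_that("demographic advancement conserves the population identity", {
  # frozen demography: size constant, all ages +1
  pf <- frozen_demography()
  pop <- initialize_population(pf, 2000, 2020, 2, burnin = FALSE)
  adv <- advance_demographics(pop, pf)
  expect_identical(unname(adv$tally),
                   c(0L, 0L, 0L, 0L))
  expect_identical(adv$population$age, pop$age + 1L)
  expect_identical(sum(adv$population$alive & adv$population$in_pop), 2000L)

  # default dynamics: exact open-population balance over several years
  pop <- initialize_population(default_params, 5000, 2020, 2,
                               burnin = FALSE)
  for (i in 1:5) {
    before <- sum(pop$alive & pop$in_pop)
    adv <- advance_demographics(pop, default_params)
    pop <- adv$population
    after <- sum(pop$alive & pop$in_pop)
    t <- adv$tally
    expect_identical(after,
                     before - unname(t["deaths"]) - unname(t["emigrants"]) +
                       unname(t["entrants"]) + unname(t["immigrants"]))
  }
})

test_that("background mortality honours the probability scale", {
  p <- default_params
  p$demography$mortality$improvement <- 0
  # craft the Gompertz level so that q(60, male) is exactly 0.02
  p$demography$mortality$a_male <- 0.02 / exp(p$demography$mortality$b * 60)
  n <- 1e5
  u <- substream_uniform(9, seq_len(n), 1, 2020)
  died <- sample_background_death(rep(60L, n), rep(1L, n), 2020,
                                  rep(1, n), p, u)
  expect_lt(abs(mean(died) - 0.02), 3 * sqrt(0.02 * 0.98 / n))

  p$demography$mortality$a_male <- 0
  expect_false(any(sample_background_death(rep(60L, n), rep(1L, n), 2020,
                                           rep(1, n), p, u)))
  p$demography$mortality$a_male <- 10
  p$demography$mortality$cap <- 1
  expect_true(all(sample_background_death(rep(60L, n), rep(1L, n), 2020,
                                          rep(1, n), p, u)))
})

test_that("universal mortality still balances the person-time accounts", {
  p <- default_params
  p$demography$mortality$a_male <- 10
  p$demography$mortality$a_female <- 10
  p$demography$mortality$cap <- 1
  p$demography$entry_rate <- 0
  p$demography$immigration_rate <- 0
  pop <- initialize_population(p, 1000, 2020, 4, burnin = FALSE)
  r <- simulate_scenario(p, build_scenario("Base-case"), pop, 2021)
  y <- r$table[r$table$year == 2020, ]
  expect_equal(sum(y$deaths), 1000)
  # decedents contribute half a person-year each
  expect_equal(sum(y$pt), 500)
  expect_equal(sum(y$n_alive), 0)
})

test_that("the aging population raises the share aged 70 and over", {
  pop <- initialize_population(default_params, 20000, 2020, 5)
  share <- new.env()
  tr <- function(P, year) {
    ok <- P$alive & P$in_pop
    assign(as.character(year), mean(P$age[ok] >= 70), envir = share)
  }
  invisible(simulate_scenario(default_params, build_scenario("Base-case"),
                              pop, 2040, trace = tr))
  expect_gt(get("2040", envir = share), get("2020", envir = share))
})

test_that("person-time equals survivors plus half-weighted decedents", {
  pop <- initialize_population(default_params, 4000, 2020, 6)
  r <- simulate_scenario(default_params, build_scenario("Base-case"), pop,
                         2030)
  expect_equal(r$table$pt, r$table$n_alive + 0.5 * r$table$deaths,
               tolerance = 1e-12)
})

test_that("population snapshots expose the documented columns", {
  pop <- initialize_population(default_params, 500, 2020, 1)
  snap <- population_snapshot(pop)
  expect_identical(nrow(snap), 500L)
  expect_true(all(c("id", "year", "sex", "age", "bmi", "has_oa", "pain",
                    "nsaid", "n_primary_jrs", "alive") %in% names(snap)))
})
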