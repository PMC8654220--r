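test_that("the OA hazard is the base rate scaled by the BMI relative risk", {
  m <- default_params$oa_incidence
  m$base_per_1000[] <- 8.1
  m$rr_bmi[] <- 1
  expect_equal(oa_hazard(55L, 1L, 23, m), 0.0081)

  m$rr_bmi["obese", "male"] <- 2
  m$base_per_1000[] <- 10
  expect_equal(oa_hazard(55L, 1L, 33, m), 0.02)

  # hand product with the default table for an obese female
  d <- default_params$oa_incidence
  expect_equal(oa_hazard(62L, 2L, 31.5, d),
               unname(d$base_per_1000[age_band(62), "female"] / 1000 *
                        d$rr_bmi["obese", "female"]))
})

test_that("onset sampling follows 1 - exp(-hazard) and OA is absorbing", {
  expect_false(any(sample_oa_onset(rep(0, 1000),
                                   substream_uniform(1, 1:1000, 4, 2020))))
  n <- 1e5
  u <- substream_uniform(5, seq_len(n), 4, 2021)
  rate <- mean(sample_oa_onset(rep(0.01, n), u))
  p <- 1 - exp(-0.01)
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / n))

  # absorbing through the engine: onset years never change once set
  pop <- initialize_population(default_params, 3000, 2020, 9)
  seen <- new.env()
  tr <- function(P, year) {
    oa_now <- P$id[P$has_oa]
    prev <- get0("ids", envir = seen, ifnotfound = integer())
    expect_true(all(prev %in% oa_now))
    assign("ids", oa_now, envir = seen)
  }
  invisible(simulate_scenario(default_params, build_scenario("Base-case"),
                              pop, 2030, trace = tr))
})

test_that("OA staging respects duration and surgery precedence", {
  got <- oa_stage(has_oa = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                  oa_onset_year = c(2018, 2000, NA, 2010, 2019),
                  last_jrs_year = c(NA, 2019, NA, 2012, NA),
                  year = 2020)
  expect_identical(as.character(got),
                   c("oa_lt5", "postjrs_lt5", "none", "postjrs_ge5",
                     "oa_lt5"))
  # boundary: exactly 5 years since onset is the long-standing stage
  expect_identical(as.character(oa_stage(TRUE, 2015, NA, 2020)), "oa_ge5")
})

test_that("proportional-odds probabilities match the closed form", {
  expect_equal(ordinal_probs(0, 0), c(0.5, 0.5))
  expect_equal(sum(ordinal_probs(1.3, c(-1, 0, 1, 2))), 1, tolerance = 1e-12)
  expect_equal(ordinal_probs(50, c(-1, 0, 1, 2))[5], 1, tolerance = 1e-12)

  # hand-evaluated logistic differences
  lp <- 1
  cuts <- c(-1, 0, 1, 2)
  cum <- 1 / (1 + exp(-(cuts - lp)))
  expect_equal(ordinal_probs(lp, cuts), diff(c(0, cum, 1)), tolerance = 1e-15)

  for (i in 1:25) {
    lp <- rnorm(1, 0, 2)
    cuts <- sort(rnorm(4, 0, 2))
    pr <- ordinal_probs(lp, cuts)
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }
  expect_error(ordinal_probs(0, c(1, 0)), "strictly increasing")
})

test_that("the hierarchical update matches a sequential reference", {
  p <- default_params
  models <- oasim:::.compile_hui_models(p)
  n <- 200
  X <- matrix(rnorm(n * length(oasim:::.xcols), 0, 0.5), n,
              dimnames = list(NULL, oasim:::.xcols))
  lag <- cbind(matrix(sample(1:3, n * 7, TRUE), n), sample(1:5, n, TRUE))
  U <- matrix(runif(n * 8), n)

  # independent reference: plain R loop over persons and attributes
  ref <- matrix(0L, n, 8)
  for (i in seq_len(n)) {
    for (a in 1:8) {
      m <- models[[a]]
      lp <- sum(m$beta * X[i, ]) + m$lag_coef * (lag[i, a] - 1) +
        sum(m$conc[seq_len(a - 1)] * (ref[i, seq_len(a - 1)] - 1))
      cum <- plogis(m$cutpoints - lp)
      ref[i, a] <- 1L + sum(U[i, a] > cum)
    }
  }
  got <- update_hui3(X, lag, models, U)
  expect_identical(got, ref)
  expect_identical(update_hui3(X, lag, models, U), got)

  # extreme cutpoints pin every attribute at the best level
  pinned <- lapply(models, function(m) {
    m$cutpoints <- m$cutpoints + 100
    m
  })
  expect_true(all(update_hui3(X, lag, pinned, U) == 1L))
})

test_that("the utility map is anchored, floored, and monotone", {
  map <- default_params$utility_map
  best <- matrix(1L, 1, 8)
  expect_equal(hui3_utility(best, map), 1)

  worst <- matrix(c(rep(3L, 7), 5L), 1)
  expect_equal(hui3_utility(worst, map), map$floor)
  expect_equal(map$floor, -0.36)

  # single-deficit values come straight off the factor table
  one <- best
  one[1, 8] <- 3L
  expect_equal(hui3_utility(one, map),
               map$scale * map$factors$pain[3] - map$shift)

  expect_error(hui3_utility(matrix(c(rep(1L, 7), 6L), 1), map),
               "out of range")

  # worsening any one attribute never increases utility
  set.seed(42)
  base_levels <- cbind(matrix(sample(1:3, 400 * 7, TRUE), 400),
                       sample(1:5, 400, TRUE))
  u0 <- hui3_utility(base_levels, map)
  for (a in 1:8) {
    worse <- base_levels
    top <- if (a == 8) 5L else 3L
    worse[, a] <- pmin(worse[, a] + 1L, top)
    expect_true(all(hui3_utility(worse, map) <= u0 + 1e-12))
  }
})

test_that("pain changes clamp at the scale ends and convolve across drugs", {
  expect_identical(apply_pain_change(c(1L, 3L, 5L), 0L), c(1L, 3L, 5L))
  expect_identical(apply_pain_change(2L, 1L), 1L)
  expect_identical(apply_pain_change(1L, 1L), 1L)

  # two drugs with known improvement distributions acting on pain 5:
  # exhaustive enumeration of the outcome distribution
  effA <- c(0.5, 0.5, 0)    # one level with probability 1/2
  effB <- c(0.6, 0.2, 0.2)  # one or two levels
  exact <- numeric(5)
  for (ia in 0:2) for (ib in 0:2) {
    pr <- effA[ia + 1] * effB[ib + 1]
    out <- max(5 - ia - ib, 1)
    exact[out] <- exact[out] + pr
  }
  n <- 4e4
  uA <- substream_uniform(3, seq_len(n), 50, 2020)
  uB <- substream_uniform(3, seq_len(n), 51, 2020)
  got <- apply_pain_change(rep(5L, n),
                           oasim:::.sample_improvement(effA, uA) +
                             oasim:::.sample_improvement(effB, uB))
  freq <- tabulate(got, 5) / n
  for (k in 1:5)
    expect_lt(abs(freq[k] - exact[k]),
              4 * sqrt(max(exact[k], 1e-3) / n) + 1e-3)
})

test_that("OA raises pain relative to identical covariates", {
  p <- default_params
  models <- oasim:::.compile_hui_models(p)
  n <- 2e4
  X <- matrix(0, n, length(oasim:::.xcols),
              dimnames = list(NULL, oasim:::.xcols))
  X_oa <- X
  X_oa[, "oa_ge5"] <- 1
  lag <- cbind(matrix(1L, n, 7), sample(1:5, n, TRUE))
  U <- oasim:::substream_uniform_mat(8, seq_len(n), 40:47, 2020)
  pain_free <- update_hui3(X, lag, models, U)[, 8]
  pain_oa <- update_hui3(X_oa, lag, models, U)[, 8]
  d <- mean(pain_oa) - mean(pain_free)
  se <- sqrt(var(pain_oa - pain_free) / n)
  expect_gt(d, 3 * se)
})
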