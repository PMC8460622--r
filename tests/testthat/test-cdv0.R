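make_fit <- function(b, c, d, e) {
  structure(list(b = b, c = c, d = d, e = e, converged = TRUE,
                 n_free_params = 3L), class = "ll_fit")
}

test_that("model-based cDV0 closed form matches known crossings", {
  # symmetric curve crosses 0 exactly at e
  expect_equal(cdv0_from_model(make_fit(-1, -1, 1, 10), ci = FALSE)$value, 10)
  # asymmetric: x = 10 * ((1.5/1) - 1)^(-1/2) = 10 / sqrt(0.5)
  est <- cdv0_from_model(make_fit(-2, -1, 0.5, 10), ci = FALSE)
  expect_equal(est$value, 10 / sqrt(0.5), tolerance = 1e-12)
  # upper asymptote below the threshold: no crossing
  ns <- cdv0_from_model(make_fit(-1, -1, -0.2, 10), ci = FALSE)
  expect_identical(ns$censored, "NS")
  expect_true(is.na(ns$value))
  # control at/above threshold: degenerate
  dg <- cdv0_from_model(make_fit(-1, -0.5, 1, 10), threshold = -0.6, ci = FALSE)
  expect_identical(dg$censored, "NS")
  # non-converged fit: censored with a note, never an exception
  nc <- make_fit(-1, -1, 1, 10); nc$converged <- FALSE
  expect_identical(cdv0_from_model(nc, ci = FALSE)$censored, "NS")
})

test_that("closed form agrees with an independent bisection oracle", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:1000) {
    b <- runif(1, -4, -0.3)
    cc <- runif(1, -2, -0.1)
    d <- runif(1, 0.05, 2)
    e <- exp(runif(1, log(0.5), log(500)))
    est <- cdv0_from_model(make_fit(b, cc, d, e), ci = FALSE)
    expect_identical(est$censored, "none")
    oracle <- bisect_crossing(b, cc, d, e)
    expect_equal(est$value, oracle, tolerance = 1e-8)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 1000)
})

test_that("running median smooths with shrinking windows at the edges", {
  expect_equal(running_median(c(-1, 1, -0.5, 0.8, 0.9)),
               c(-1, -0.5, 0.8, 0.8, 0.9))
  mono <- c(-1, -0.5, 0, 0.5, 1)
  expect_equal(running_median(mono), mono)       # monotone: unchanged
  expect_equal(running_median(rep(0.3, 5)), rep(0.3, 5))  # constant
  expect_error(running_median(1:5, window = 4), "odd")
  expect_error(running_median(c(1, 2), window = 3), "long")
  # interior values agree with the standard running median
  x <- c(0.3, -1, 2, 0.5, -0.2, 1.4, 0.9)
  expect_equal(running_median(x)[2:6],
               as.numeric(stats::runmed(x, 3, endrule = "keep"))[2:6])
})

test_that("linear interpolation solves the bracket crossing exactly", {
  d <- quiet_dataset("a", c(1, 3), c(-1, 1), control_dv = -1)
  expect_equal(cdv0_linear_interpolation(d)$value, 2)
  d2 <- quiet_dataset("b", c(10, 20), c(-0.5, 0.5), control_dv = -1)
  expect_equal(cdv0_linear_interpolation(d2)$value, 15)

  # algebraic exactness on random brackets: the interpolated point lies on
  # the segment and maps back to the threshold
  set.seed(17)
  for (i in 1:500) {
    c_minus <- exp(runif(1, log(0.1), log(100)))
    c_plus <- c_minus * exp(runif(1, 0.05, 2))
    dv_minus <- runif(1, -2, -0.01)
    dv_plus <- runif(1, 0, 2)
    d <- quiet_dataset("r", c(c_minus, c_plus), c(dv_minus, dv_plus),
                       control_dv = -1)
    est <- cdv0_linear_interpolation(d)
    slope <- (dv_plus - dv_minus) / (c_plus - c_minus)
    expect_equal(dv_minus + slope * (est$value - c_minus), 0,
                 tolerance = 1e-10)
    expect_gte(est$value, c_minus)
    expect_lte(est$value, c_plus)
  }
})

test_that("interpolation censoring matches a brute-force scan of the data", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(5:12, 1)
    dv <- runif(n, -1.5, 1.5) - sample(c(0, 2), 1)  # sometimes all-negative
    d <- quiet_dataset("r", log_grid(n), dv, control_dv = -1)
    est <- cdv0_linear_interpolation(d)
    if (!any(dv >= 0)) {
      expect_identical(est$censored, "NS")
    } else if (dv[1] >= 0) {
      expect_identical(est$censored, "below_range")
    } else {
      expect_identical(est$censored, "none")
      j <- which(dv >= 0)[1]
      expect_gte(est$value, log_grid(n)[j - 1])
      expect_lte(est$value, log_grid(n)[j])
    }
  }
})

test_that("interpolation recovers the true crossing on the design ladder", {
  grid <- design_series(500)$concentration_uM
  d <- simulate_dataset(c(b = -1, c = -1, d = 1, e = 20),
                        concentrations = grid, noise_sd = 0)
  est <- cdv0_linear_interpolation(d)
  bracket <- grid[grid <= 20 * 5 / 3 & grid >= 20 * 3 / 5]
  expect_gte(est$value, min(bracket))
  expect_lte(est$value, max(bracket))
  expect_equal(est$value, 20, tolerance = 0.1 * 20)
})

test_that("both cDV0 estimators scale with the concentration axis", {
  k <- 7.3
  d <- simulate_dataset(c(b = -1.3, c = -1, d = 1, e = 20),
                        concentrations = log_grid(9), noise_sd = 0.1,
                        seed = 13)
  dk <- quiet_dataset("scaled", d$points$concentration * k, d$points$dv,
                      control_dv = d$control_dv)
  li <- cdv0_linear_interpolation(d)$value
  lik <- cdv0_linear_interpolation(dk)$value
  expect_equal(lik, k * li, tolerance = 1e-10)
  ll <- cdv0_from_model(fit_log_logistic(d), ci = FALSE)$value
  llk <- cdv0_from_model(fit_log_logistic(dk), ci = FALSE)$value
  expect_equal(llk, k * ll, tolerance = 1e-4)
})

test_that("dense noiseless sampling brings the two estimators within 2%", {
  d <- simulate_dataset(c(b = -1.2, c = -1, d = 1, e = 30),
                        concentrations = log_grid(24, 2, 500), noise_sd = 0)
  a <- cdv0_from_model(fit_log_logistic(d), ci = FALSE)$value
  b <- cdv0_linear_interpolation(d)$value
  expect_lt(abs(a - b) / a, 0.02)
})

test_that("confidence interval behaves at zero noise and brackets the estimate", {
  d0 <- simulate_dataset(c(b = -1.5, c = -1, d = 1, e = 20),
                         concentrations = log_grid(9), noise_sd = 0)
  est0 <- cdv0_from_model(fit_log_logistic(d0))
  expect_equal(est0$ci_low, est0$value, tolerance = 1e-3)
  expect_equal(est0$ci_high, est0$value, tolerance = 1e-3)

  for (s in 1:25) {
    d <- simulate_dataset(c(b = -1.5, c = -1, d = 1, e = 20),
                          concentrations = log_grid(9), noise_sd = 0.1,
                          seed = 800 + s)
    est <- cdv0_from_model(fit_log_logistic(d))
    if (est$censored == "none" && is.finite(est$ci_low) &&
        is.finite(est$ci_high)) {
      expect_lte(est$ci_low, est$value)
      expect_gte(est$ci_high, est$value)
      expect_gt(est$ci_low, 0)
    }
  }
})

test_that("estimator comparison flags discordant response shapes only", {
  # clean sigmoids: close agreement, no flag
  clean <- lapply(1:5, function(s) {
    simulate_dataset(c(b = -1.5, c = -1, d = 1, e = 30),
                     concentrations = log_grid(12), noise_sd = 0.05,
                     seed = 40 + s, chemical_id = paste0("clean", s))
  })
  cmp <- compare_estimators(clean)
  expect_false(any(cmp$flag))
  expect_true(all(cmp$ratio < 1.15))

  # flat data: both censored, no flag
  flat <- quiet_dataset("flat", log_grid(9), rep(-1, 9) + 0.01 * (1:9 %% 2),
                        control_dv = -1)
  cmp_flat <- compare_estimators(list(flat))
  expect_identical(cmp_flat$cdv0_ll_status, "NS")
  expect_identical(cmp_flat$cdv0_interp_status, "NS")
  expect_false(cmp_flat$flag)

  # two-phase curve: interpolation finds the lower crossing, the sigmoid a
  # higher one; discrepancy must be flagged
  two <- simulate_dataset(c(b = -3, c = -1, d = 2, e = 200),
                          concentrations = design_series(500)$concentration_uM,
                          noise_sd = 0.02, contamination = "two_phase",
                          seed = 3, chemical_id = "twophase")
  cmp2 <- suppressWarnings(compare_estimators(list(two)))
  expect_true(cmp2$flag)
  expect_lt(cmp2$cdv0_interp, cmp2$cdv0_ll)
})
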