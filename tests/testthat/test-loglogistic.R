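test_that("predicted response follows the four-parameter log-logistic form", {
  fit <- list(b = -1, c = -1, d = 1, e = 10)
  # at x = e the logistic term is 1/2: midpoint of (c, d)
  expect_equal(predict_response(fit, 10), 0)
  # lower-asymptote limit as x -> 0+
  expect_equal(predict_response(fit, 1e-9), -1, tolerance = 1e-6)
  # upper-asymptote limit
  expect_equal(predict_response(fit, 1e12), 1, tolerance = 1e-6)
  # hand evaluation: b=-2, c=-0.8, d=1.4, e=50, x=25:
  # exp(-2*(log 25 - log 50)) = exp(2 log 2) = 4, so f = -0.8 + 2.2/5 = -0.36
  expect_equal(predict_response(list(b = -2, c = -0.8, d = 1.4, e = 50), 25),
               -0.36)
  expect_error(predict_response(fit, 0), "> 0")
  expect_error(predict_response(fit, -5), "> 0")
})

test_that("noiseless data recover the generating parameters essentially exactly", {
  d <- simulate_dataset(c(b = -1.5, c = -1, d = 1, e = 20),
                        concentrations = log_grid(9), noise_sd = 0)
  fit <- fit_log_logistic(d)
  expect_true(fit$converged)
  expect_equal(fit$c, -1)  # fixed at control
  expect_equal(fit$b, -1.5, tolerance = 1e-4)
  expect_equal(fit$d, 1, tolerance = 1e-4)
  expect_equal(fit$e, 20, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)
  expect_identical(fit$n_free_params, 3L)
})

test_that("fit matches a twice-refined grid-search oracle on noisy data", {
  d <- simulate_dataset(c(b = -2, c = -1, d = 1.2, e = 50),
                        concentrations = log_grid(9), noise_sd = 0.1,
                        seed = 42)
  pts <- viable_points(d)
  fit <- fit_log_logistic(d)
  oracle <- grid_search_fit(pts$concentration, pts$dv, cc = -1)
  # the optimizer must do at least as well as the oracle's best grid cell
  expect_lte(fit$rss, oracle$rss * (1 + 1e-6))
  expect_equal(fit$b, oracle$b, tolerance = 0.15)
  expect_equal(fit$d, oracle$d, tolerance = 0.05)
  expect_equal(fit$e, oracle$e, tolerance = 0.15)
})

test_that("degenerate inputs are flagged, never thrown", {
  # all DVs identical
  d <- quiet_dataset("flat", log_grid(6), rep(-0.4, 6), control_dv = -1)
  fit <- fit_log_logistic(d)
  expect_false(fit$converged)
  expect_true(fit$degenerate)
  expect_equal(fit$rss, 0)
  # flat at the control value
  d2 <- quiet_dataset("flat2", log_grid(6), rep(-1, 6), control_dv = -1)
  fit2 <- fit_log_logistic(d2)
  expect_true(fit2$degenerate || abs(fit2$d - fit2$c) < 1e-6)
  # too few distinct concentrations
  d3 <- quiet_dataset("small", c(1, 1, 10), c(-1, -0.9, 0.5), control_dv = -1)
  expect_error(fit_log_logistic(d3), "3 distinct")
})

test_that("flat fit is the mean with its residual sum of squares", {
  d <- quiet_dataset("f", c(1, 10, 100), c(-1, 0, 1), control_dv = -1)
  flat <- fit_flat(d)
  expect_equal(flat$flat_value, 0)
  expect_equal(flat$rss, 2)
  d1 <- quiet_dataset("g", 5, 0.3, control_dv = -1)
  flat1 <- fit_flat(d1)
  expect_equal(flat1$flat_value, 0.3)
  expect_equal(flat1$rss, 0)
})

test_that("log-logistic fit never does worse than the horizontal line (nesting)", {
  set.seed(2024)
  for (i in 1:150) {
    n <- sample(5:12, 1)
    d <- quiet_dataset("r", log_grid(n),
                       runif(n, -1.5, 1.5), control_dv = runif(1, -1.5, -0.1))
    fit <- fit_log_logistic(d)
    flat <- fit_flat(d)
    expect_lte(fit$rss, flat$rss + 1e-8 * max(1, flat$rss))
  }
})

test_that("converged non-degenerate fits are monotone non-decreasing", {
  for (s in 1:20) {
    d <- simulate_dataset(c(b = -1.5, c = -1, d = 1, e = 20),
                          concentrations = log_grid(9), noise_sd = 0.1,
                          seed = s)
    fit <- fit_log_logistic(d)
    if (fit$converged && !fit$degenerate && fit$d >= fit$c) {
      grid <- exp(seq(log(0.01), log(1e5), length.out = 200))
      pred <- predict_response(fit, grid)
      expect_true(all(diff(pred) >= -1e-10))
    }
  }
})

test_that("midpoint recovery under noise stays within a 25% median error", {
  errs <- vapply(1:100, function(s) {
    d <- simulate_dataset(c(b = -1.5, c = -1, d = 1, e = 20),
                          concentrations = log_grid(9), noise_sd = 0.1,
                          seed = 10000 + s)
    fit <- fit_log_logistic(d)
    abs(fit$e - 20) / 20
  }, numeric(1))
  expect_lte(median(errs), 0.25)
})
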