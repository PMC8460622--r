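#' Four-parameter log-logistic response function
#'
#' The sigmoidal dose-response model used throughout the package,
#' \deqn{f(x) = c + \frac{d - c}{1 + \exp\{b(\log x - \log e)\}},}
#' where `c` and `d` are the lower and upper response limits, `b` the slope
#' and `e` the midpoint (ED50). With `b < 0` and `d >= c` the curve rises
#' monotonically from `c` (as x -> 0) to `d` (as x -> Inf).
#'
#' @param x concentration(s), µM, > 0; vectorized.
#' @param b slope parameter.
#' @param c lower asymptote.
#' @param d upper asymptote.
#' @param e midpoint concentration (ED50), > 0.
#' @return numeric vector of predicted decision values.
#' @examples
#' ll4(10, b = -1, c = -1, d = 1, e = 10)  # midpoint: 0
#' @export
ll4 <- function(x, b, c, d, e) {
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Predict decision values from a fitted log-logistic model
#'
#' @param fit an object of class `"ll_fit"` from [fit_log_logistic()], or any
#'   list with numeric elements `b`, `c`, `d`, `e`.
#' @param concentration numeric vector of concentrations, µM, all > 0.
#' @return predicted decision values.
#' @export
predict_response <- function(fit, concentration) {
  concentration <- as.numeric(concentration)
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("`concentration` must be finite and > 0", call. = FALSE)
  }
  ll4(concentration, fit$b, fit$c, fit$d, fit$e)
}

#' @export
predict.ll_fit <- function(object, newdata, ...) {
  predict_response(object, newdata)
}

# Gaussian maximum-likelihood log-likelihood implied by a residual sum of
# squares (variance profiled out as rss/n).
gauss_loglik <- function(rss, n) {
  if (rss <= 0) rss <- .Machine$double.xmin
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

#' Best-fitting horizontal line
#'
#' The least-squares horizontal fit -- the "no effect" reference model whose
#' value is the mean decision value -- used as the null model of the
#' likelihood-ratio no-effect test.
#'
#' @param data a [dose_response_dataset()]; only viable points are used.
#' @return list with `flat_value` (the mean DV) and `rss`.
#' @export
fit_flat <- function(data) {
  pts <- viable_points(data)
  if (nrow(pts) == 0L) stop("no viable points to fit", call. = FALSE)
  m <- mean(pts$dv)
  list(flat_value = m, rss = sum((pts$dv - m)^2))
}

# Deterministic start values for the constrained fit: midpoint from the
# geometric mean of the assayed concentrations, upper limit from the largest
# observed DV, slope from a logit-linearization of the centred responses.
ll_start_grid <- function(x, y, cc) {
  gm <- exp(mean(log(x)))
  d0 <- max(y)
  span <- max(d0 - cc, 0.1)
  z <- (y - cc) / (d0 - cc + 0.05 * span)
  z <- pmin(pmax(z, 0.02), 0.98)
  w <- log(z / (1 - z))
  b0 <- -1
  loge0 <- log(gm)
  if (length(unique(x)) >= 2) {
    co <- tryCatch(stats::coef(stats::lm(w ~ log(x))), error = function(e) NULL)
    if (!is.null(co) && all(is.finite(co)) && co[2] > 1e-8) {
      b0 <- max(-30, min(-0.05, -co[2]))
      le <- co[1] / (-b0)
      if (is.finite(le)) loge0 <- le
    }
  }
  loge_lo <- log(min(x)) - 23
  loge_hi <- log(max(x)) + 23
  loge0 <- max(loge_lo + 1, min(loge_hi - 1, loge0))
  starts <- rbind(
    c(b0, d0, loge0),
    c(-0.3, d0, log(gm)),
    c(-1,   d0, log(gm)),
    c(-3,   d0, log(gm)),
    c(-1,   d0, log(min(x))),
    c(-1,   d0, log(max(x))),
    # a start in the flat limit (e far below the assayed range, d at the mean)
    # guarantees the fit can never do worse than the horizontal line
    c(-1, mean(y), loge_lo + 1)
  )
  list(starts = starts, loge_lo = loge_lo, loge_hi = loge_hi)
}

#' Fit the constrained log-logistic dose-response model
#'
#' Least-squares fit of [ll4()] to a chemical's decision values over
#' log-concentration, with the lower asymptote `c` held fixed at the
#' dataset's unstimulated-control DV and the slope constrained negative
#' (`b <= -1e-6`), so that fitted curves are monotonically non-decreasing in
#' concentration. Under i.i.d. Gaussian errors the least-squares optimum is
#' the maximum-likelihood fit; the Gaussian log-likelihood (error variance
#' profiled out as rss/n) is attached for likelihood-ratio testing.
#'
#' Optimization is multi-start box-constrained quasi-Newton (`L-BFGS-B`) over
#' (b, d, log e) from a deterministic grid of seven start points, so results
#' do not depend on the random-number state. The midpoint is optimized on the
#' log scale and bounded well outside the assayed concentration range, which
#' lets the model collapse toward a horizontal line (e below the range) when
#' the data carry no dose signal; such collapsed fits (d <= c, or no spread)
#' are flagged `degenerate`. Optimizer failure never raises an error: the
#' best parameters found are returned with `converged = FALSE`.
#'
#' @param data a [dose_response_dataset()]; non-viable points are excluded
#'   before fitting.
#' @return An object of class `"ll_fit"`: list with elements `b`, `c`, `d`,
#'   `e`, `rss`, `log_likelihood`, `n_points`, `n_free_params` (3: b, d, e),
#'   `converged`, `degenerate`, `chemical_id`, and the fitted `x`/`y` data.
#' @seealso [no_effect_test()], [cdv0_from_model()]
#' @examples
#' d <- simulate_dataset(c(b = -1.5, c = -1, d = 1, e = 20), noise_sd = 0)
#' fit <- fit_log_logistic(d)
#' fit
#' @export
fit_log_logistic <- function(data) {
  stopifnot(inherits(data, "dr_dataset"))
  pts <- viable_points(data)
  x <- pts$concentration
  y <- pts$dv
  cc <- data$control_dv
  if (length(unique(x)) < 3L) {
    stop(sprintf("dataset '%s': at least 3 distinct viable concentrations are required to fit 3 free parameters",
                 data$chemical_id), call. = FALSE)
  }
  n <- length(y)

  if (stats::sd(y) < 1e-12) {
    # all DVs identical: every parameterization with d = y is equivalent
    fit <- new_ll_fit(b = -1, c = cc, d = y[1], e = exp(mean(log(x))),
                      rss = 0, n = n, converged = FALSE, degenerate = TRUE,
                      chemical_id = data$chemical_id, x = x, y = y)
    return(fit)
  }

  sg <- ll_start_grid(x, y, cc)
  obj <- function(par) {
    r <- y - ll4(x, par[1], cc, par[2], exp(par[3]))
    v <- sum(r * r)
    if (!is.finite(v)) 1e10 else v
  }
  lower <- c(-50, -Inf, sg$loge_lo)
  upper <- c(-1e-6, Inf, sg$loge_hi)
  results <- list()
  for (i in seq_len(nrow(sg$starts))) {
    p0 <- sg$starts[i, ]
    p0[1] <- min(max(p0[1], lower[1]), upper[1])
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    results[[length(results) + 1L]] <- res
  }
  best <- NULL
  for (res in results) {
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    # optimizer failed everywhere; report the best start evaluation
    vals <- apply(sg$starts, 1, obj)
    p <- sg$starts[which.min(vals), ]
    return(new_ll_fit(b = p[1], c = cc, d = p[2], e = exp(p[3]),
                      rss = min(vals), n = n, converged = FALSE,
                      degenerate = FALSE, chemical_id = data$chemical_id,
                      x = x, y = y))
  }
  # a cleanly-terminated start that ties the optimum (to relative 1e-8)
  # counts as convergence: the line search can report an abnormal code at a
  # point another start reached with a clean code
  tie_tol <- best$value * 1e-8 + 1e-14
  converged <- any(vapply(results, function(res) {
    res$convergence == 0 && res$value <= best$value + tie_tol
  }, logical(1)))
  b <- best$par[1]; d <- best$par[2]; e <- exp(best$par[3])
  degenerate <- (d <= cc + 1e-8 * max(1, abs(cc)))
  new_ll_fit(b = b, c = cc, d = d, e = e, rss = best$value, n = n,
             converged = converged, degenerate = degenerate,
             chemical_id = data$chemical_id, x = x, y = y)
}

new_ll_fit <- function(b, c, d, e, rss, n, converged, degenerate,
                       chemical_id, x, y) {
  structure(
    list(b = b, c = c, d = d, e = e,
         rss = rss,
         log_likelihood = gauss_loglik(rss, n),
         n_points = n,
         n_free_params = 3L,
         converged = converged,
         degenerate = degenerate,
         chemical_id = chemical_id,
         x = x, y = y),
    class = "ll_fit"
  )
}

#' @export
print.ll_fit <- function(x, ...) {
  cat(sprintf("Constrained log-logistic fit: %s\n", x$chemical_id))
  cat(sprintf("  b = %.4g, c = %.4g (fixed), d = %.4g, e = %.4g uM\n",
              x$b, x$c, x$d, x$e))
  cat(sprintf("  rss = %.4g on %d points; logLik = %.4g; converged: %s%s\n",
              x$rss, x$n_points, x$log_likelihood, x$converged,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' @export
logLik.ll_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_free_params + 1L,
            nobs = object$n_points, class = "logLik")
}

#' Likelihood-ratio no-effect test
#'
#' Tests for a concentration-dependent increase in decision values by
#' comparing the constrained log-logistic fit against the best-fitting
#' horizontal line. Under the Gaussian error model the likelihood-ratio
#' statistic is `n * log(rss_flat / rss_loglogistic)`; it is referred to the
#' upper tail of a chi-square distribution with 2 degrees of freedom (the
#' horizontal line has 1 free mean parameter, the constrained log-logistic
#' 3). Because the slope constraint puts the null on the parameter-space
#' boundary, the chi-square reference is an approximation; it is slightly
#' conservative in practice (see the methods vignette). A significant result
#' indicates that the decision values depend on concentration.
#'
#' @param data a [dose_response_dataset()].
#' @param fit optionally, an `"ll_fit"` already computed for `data` (avoids
#'   refitting).
#' @return An object of class `"no_effect_test"`: list with `lr_statistic`,
#'   `df`, `p_value`, `flat_fit_value`, `flat_rss`, `ll_rss`, `converged`.
#'   When the constrained fit fails to converge the test reports
#'   `p_value = 1` with `converged = FALSE`.
#' @examples
#' d <- simulate_dataset(c(b = -2, c = -1, d = 1, e = 30), noise_sd = 0.05,
#'                       seed = 1)
#' no_effect_test(d)
#' @export
no_effect_test <- function(data, fit = NULL) {
  flat <- fit_flat(data)
  if (is.null(fit)) fit <- fit_log_logistic(data)
  n <- fit$n_points
  if (!fit$converged && !fit$degenerate) {
    return(structure(list(lr_statistic = 0, df = 2L, p_value = 1,
                          flat_fit_value = flat$flat_value,
                          flat_rss = flat$rss, ll_rss = fit$rss,
                          converged = FALSE),
                     class = "no_effect_test"))
  }
  tol <- 1e-12 * max(1, flat$rss)
  if (flat$rss <= tol) {
    lr <- 0
  } else {
    # floor the alternative rss so a numerically perfect fit yields a large
    # finite statistic rather than Inf
    rss1 <- max(fit$rss, flat$rss * 1e-15)
    lr <- n * log(flat$rss / rss1)
  }
  lr <- max(lr, 0)  # clip tiny negatives from optimizer slack
  p <- stats::pchisq(lr, df = 2, lower.tail = FALSE)
  structure(list(lr_statistic = lr, df = 2L, p_value = min(p, 1),
                 flat_fit_value = flat$flat_value, flat_rss = flat$rss,
                 ll_rss = fit$rss, converged = fit$converged),
            class = "no_effect_test")
}

#' @export
print.no_effect_test <- function(x, ...) {
  cat("No-effect likelihood-ratio test (log-logistic vs horizontal line)\n")
  cat(sprintf("  LR = %.4g on %d df, p = %.3g\n", x$lr_statistic, x$df, x$p_value))
  cat(sprintf("  flat fit: value %.4g, rss %.4g; log-logistic rss %.4g\n",
              x$flat_fit_value, x$flat_rss, x$ll_rss))
  invisible(x)
}
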