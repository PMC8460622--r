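#' Construct a cDV0 estimate
#'
#' Container for a possibly-censored threshold-crossing concentration.
#' `censored` is `"none"` for a defined value, `"NS"` when no crossing exists
#' (non-sensitizing outcome), and `"below_range"` when the lowest assayed
#' concentration is already positive so the true crossing lies below the
#' assayed range. A censored estimate may still carry a finite lower
#' confidence bound with an undefined upper bound.
#'
#' @param value crossing concentration, µM, or `NA` when censored.
#' @param method `"log_logistic"` or `"linear_interpolation"`.
#' @param censored `"none"`, `"NS"` or `"below_range"`.
#' @param ci_low,ci_high confidence bounds, µM, or `NA`.
#' @param threshold the DV threshold that was crossed (default 0).
#' @param notes free-text annotations (e.g. "running median applied").
#' @return object of class `"cdv0_estimate"`.
#' @export
cdv0_estimate <- function(value = NA_real_,
                          method = c("log_logistic", "linear_interpolation"),
                          censored = c("none", "NS", "below_range"),
                          ci_low = NA_real_, ci_high = NA_real_,
                          threshold = 0, notes = character()) {
  method <- match.arg(method)
  censored <- match.arg(censored)
  value <- as.numeric(value)
  if (censored != "none" && is.finite(value)) {
    stop("a censored estimate must not carry a numeric value", call. = FALSE)
  }
  if (censored == "none") {
    if (!is.finite(value) || value <= 0) {
      stop("a defined cDV0 must be a positive concentration", call. = FALSE)
    }
    if (is.finite(ci_low) && is.finite(ci_high) &&
        !(ci_low <= value && value <= ci_high)) {
      stop("confidence bounds must bracket the estimate", call. = FALSE)
    }
  }
  if ((is.finite(ci_low) && ci_low <= 0) || (is.finite(ci_high) && ci_high <= 0)) {
    stop("confidence bounds must be positive when defined", call. = FALSE)
  }
  structure(list(value = value, method = method, censored = censored,
                 ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
                 threshold = threshold, notes = notes),
            class = "cdv0_estimate")
}

#' @export
print.cdv0_estimate <- function(x, ...) {
  lab <- switch(x$censored,
                none = sprintf("%.4g uM", x$value),
                NS = "NS (no crossing)",
                below_range = "< lowest assayed concentration")
  ci <- sprintf("(%s, %s)",
                if (is.finite(x$ci_low)) sprintf("%.4g", x$ci_low) else "NA",
                if (is.finite(x$ci_high)) sprintf("%.4g", x$ci_high) else "NA")
  cat(sprintf("cDV0 [%s, threshold DV >= %g]: %s %s\n",
              x$method, x$threshold, lab,
              if (is.finite(x$ci_low) || is.finite(x$ci_high)) ci else ""))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' cDV0 from the fitted log-logistic curve
#'
#' Solves `predict_response(x) = threshold` for the fitted model, i.e. the
#' curve's intercept with the classification threshold, in closed form:
#' \deqn{x_0 = e\,\Big(\frac{d-c}{t-c} - 1\Big)^{1/b}.}
#' The crossing exists only when the fixed lower asymptote lies below the
#' threshold (`c < t`) and the upper asymptote above it (`d > t`); otherwise
#' the estimate is censored as `NS` (upper asymptote never reaches the
#' threshold) or annotated as degenerate (control already at/above
#' threshold). A 95% inverse-regression confidence interval from
#' [cdv0_confidence_interval()] is attached when the fit converged and
#' carries its data.
#'
#' @param fit an `"ll_fit"` from [fit_log_logistic()].
#' @param threshold DV threshold, default 0 (the classification border).
#' @param level confidence level for the attached interval.
#' @param ci compute the confidence interval (default `TRUE`).
#' @return a [cdv0_estimate()] with `method = "log_logistic"`.
#' @examples
#' fit <- list(b = -1, c = -1, d = 1, e = 10)
#' class(fit) <- "ll_fit"
#' fit$converged <- TRUE
#' cdv0_from_model(fit, ci = FALSE)  # symmetric curve crosses 0 at e = 10
#' @export
cdv0_from_model <- function(fit, threshold = 0, level = 0.95, ci = TRUE) {
  stopifnot(inherits(fit, "ll_fit"))
  if (!isTRUE(fit$converged)) {
    return(cdv0_estimate(method = "log_logistic", censored = "NS",
                         threshold = threshold,
                         notes = "model fit did not converge"))
  }
  if (fit$c >= threshold) {
    return(cdv0_estimate(method = "log_logistic", censored = "NS",
                         threshold = threshold,
                         notes = "degenerate: control DV at or above threshold"))
  }
  if (fit$d <= threshold) {
    return(cdv0_estimate(method = "log_logistic", censored = "NS",
                         threshold = threshold,
                         notes = "upper asymptote below threshold"))
  }
  ratio <- (fit$d - fit$c) / (threshold - fit$c)  # > 1 here
  x0 <- fit$e * (ratio - 1)^(1 / fit$b)
  if (!is.finite(x0) || x0 <= 0) {
    return(cdv0_estimate(method = "log_logistic", censored = "NS",
                         threshold = threshold,
                         notes = "crossing not numerically defined"))
  }
  lo <- hi <- NA_real_
  if (isTRUE(ci) && !is.null(fit$x)) {
    bounds <- cdv0_confidence_interval(fit, threshold = threshold, level = level)
    lo <- bounds[1]; hi <- bounds[2]
  }
  cdv0_estimate(value = x0, method = "log_logistic",
                ci_low = lo, ci_high = hi, threshold = threshold)
}

#' Inverse-regression confidence interval for the model-based cDV0
#'
#' Approximate confidence bounds for the threshold-crossing concentration of
#' a converged log-logistic fit, by the delta method on the
#' log-concentration scale: the variance of
#' `log x0 = log e + log((d-c)/(t-c) - 1)/b` is propagated from the
#' Gauss-Newton approximation to the covariance of (b, d, e) at the optimum
#' (`sigma^2 (J'J)^{-1}` with `sigma^2 = rss/(n - 3)`), and the symmetric
#' log-scale interval is exponentiated, giving positive, asymmetric bounds.
#' A bound is reported `NA` when the propagated variance is not finite or the
#' endpoint under- or overflows; a singular Jacobian cross-product yields
#' `(NA, NA)` with a warning.
#'
#' @param fit a converged `"ll_fit"` carrying its fitted data.
#' @param data optional [dose_response_dataset()]; defaults to the data
#'   stored in the fit.
#' @param threshold DV threshold, default 0.
#' @param level confidence level, default 0.95.
#' @return numeric vector `c(ci_low, ci_high)` in µM.
#' @export
cdv0_confidence_interval <- function(fit, data = NULL, threshold = 0,
                                     level = 0.95) {
  stopifnot(inherits(fit, "ll_fit"))
  if (!is.null(data)) {
    pts <- viable_points(data)
    x <- pts$concentration; y <- pts$dv
  } else {
    x <- fit$x; y <- fit$y
  }
  if (is.null(x) || length(x) <= fit$n_free_params) {
    return(c(NA_real_, NA_real_))
  }
  b <- fit$b; cc <- fit$c; d <- fit$d; e <- fit$e
  if (!(cc < threshold && d > threshold)) return(c(NA_real_, NA_real_))
  n <- length(x)
  sigma2 <- fit$rss / (n - fit$n_free_params)

  u <- log(x) - log(e)
  E <- exp(b * u)
  denom <- (1 + E)^2
  J <- cbind(
    b = -(d - cc) * E * u / denom,
    d = 1 / (1 + E),
    e = (d - cc) * E * b / (e * denom)
  )
  JtJ <- crossprod(J)
  V <- tryCatch(sigma2 * solve(JtJ), error = function(err) NULL)
  if (is.null(V)) {
    warning("singular parameter covariance; confidence bounds undefined",
            call. = FALSE)
    return(c(NA_real_, NA_real_))
  }
  R <- (d - cc) / (threshold - cc)
  logx0 <- log(e) + log(R - 1) / b
  grad <- c(
    b = -log(R - 1) / b^2,
    d = 1 / (b * (R - 1) * (threshold - cc)),
    e = 1 / e
  )
  var_log <- drop(t(grad) %*% V %*% grad)
  if (!is.finite(var_log) || var_log < 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- exp(logx0 - z * sqrt(var_log))
  hi <- exp(logx0 + z * sqrt(var_log))
  if (!is.finite(lo) || lo <= 0) lo <- NA_real_
  if (!is.finite(hi)) hi <- NA_real_
  c(lo, hi)
}

#' Centered running median with shrinking windows at the edges
#'
#' Smooths a decision-value sequence with a centered running median; near the
#' sequence ends the window shrinks symmetrically to what is available, so
#' the output has the same length as the input and the first and last values
#' are preserved for window 3.
#'
#' @param dvs numeric vector, ordered by concentration.
#' @param window odd integer window width, >= 3.
#' @return smoothed numeric vector, same length as `dvs`.
#' @examples
#' running_median(c(-1, 1, -0.5, 0.8, 0.9))
#' @export
running_median <- function(dvs, window = 3) {
  if (length(window) != 1L || !is.finite(window) || window < 3 ||
      window %% 2 != 1) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  n <- length(dvs)
  if (n < window) {
    stop("sequence must be at least as long as the window", call. = FALSE)
  }
  k <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    ki <- min(k, i - 1, n - i)  # symmetric shrink at the edges
    stats::median(dvs[(i - ki):(i + ki)])
  }, numeric(1))
}

#' cDV0 by linear interpolation across the decision border
#'
#' Estimates the lowest concentration with a non-negative decision value by
#' linear interpolation between the two assayed points on adjacent sides of
#' the decision border,
#' \deqn{cDV_0 = c_- - \frac{DV_-\,(c_+ - c_-)}{DV_+ - DV_-},}
#' where the minus/plus points are the lowest-concentration adjacent pair
#' with `DV- < t <= DV+` (DVs shifted by the threshold when `t != 0`).
#' Optionally the DV sequence is first smoothed with a window-3 running
#' median ([running_median()]) to reduce the impact of noise on the choice
#' of positive interpolation point; `smooth = "auto"` applies the smoothing
#' only when the sign pattern of `dv - threshold` changes more than once
#' (a noise indication).
#'
#' Censoring: when no (smoothed) DV reaches the threshold the outcome is
#' `NS`; when the lowest assayed concentration is already at/above the
#' threshold the true crossing is unobserved and the estimate is censored
#' `below_range`.
#'
#' @param data a [dose_response_dataset()]; non-viable points are excluded.
#' @param threshold DV threshold, default 0.
#' @param smooth `FALSE` (default), `TRUE`, or `"auto"`.
#' @param window running-median window (odd, default 3).
#' @return a [cdv0_estimate()] with `method = "linear_interpolation"`.
#' @examples
#' d <- dose_response_dataset("ex", c(1, 3), c(-1, 1), control_dv = -1)
#' cdv0_linear_interpolation(d)  # crossing at 2
#' @export
cdv0_linear_interpolation <- function(data, threshold = 0, smooth = FALSE,
                                      window = 3) {
  stopifnot(inherits(data, "dr_dataset"))
  pts <- viable_points(data)
  if (nrow(pts) == 0L) stop("no viable points", call. = FALSE)
  conc <- pts$concentration
  dv <- pts$dv
  notes <- character()

  apply_smooth <- isTRUE(smooth)
  if (identical(smooth, "auto") && length(dv) >= window) {
    signs <- sign(dv - threshold)
    signs[signs == 0] <- 1  # at-threshold counts as positive (DV >= 0 rule)
    changes <- sum(diff(signs) != 0)
    apply_smooth <- changes > 1
  }
  if (apply_smooth && length(dv) >= window) {
    dv <- running_median(dv, window = window)
    notes <- c(notes, "running median applied")
  }

  pos <- which(dv >= threshold)
  if (length(pos) == 0L) {
    return(cdv0_estimate(method = "linear_interpolation", censored = "NS",
                         threshold = threshold, notes = notes))
  }
  j <- pos[1]
  if (j == 1L) {
    return(cdv0_estimate(method = "linear_interpolation",
                         censored = "below_range", threshold = threshold,
                         ci_low = NA_real_, ci_high = NA_real_,
                         notes = c(notes, sprintf(
                           "lowest assayed concentration (%g uM) already positive",
                           conc[1]))))
  }
  c_minus <- conc[j - 1]; c_plus <- conc[j]
  dv_minus <- dv[j - 1] - threshold; dv_plus <- dv[j] - threshold
  if (c_plus <= c_minus) {
    # replicate concentrations straddling the border: the crossing is at
    # that concentration itself
    value <- c_plus
  } else {
    value <- c_minus - dv_minus * (c_plus - c_minus) / (dv_plus - dv_minus)
  }
  cdv0_estimate(value = value, method = "linear_interpolation",
                threshold = threshold, notes = notes)
}

#' Compare the two cDV0 estimators across chemicals
#'
#' Runs both the model-based and the interpolation estimator on each dataset
#' and flags chemicals where the two disagree: one method censored while the
#' other yields a value, or a ratio between the two estimates exceeding
#' `ratio_flag`. Such discordance typically indicates departures from the
#' sigmoidal model (two-phase or U-shaped responses) that warrant analyst
#' review rather than automatic exclusion.
#'
#' @param datasets a list of [dose_response_dataset()] objects.
#' @param threshold DV threshold, default 0.
#' @param smooth smoothing policy passed to [cdv0_linear_interpolation()]
#'   (default `"auto"`).
#' @param ratio_flag flag when max/min of the two estimates exceeds this
#'   factor (default 2).
#' @return data frame with one row per chemical: `chemical_id`, `cdv0_ll`,
#'   `cdv0_interp`, censoring statuses, `ratio`, `flag`.
#' @export
compare_estimators <- function(datasets, threshold = 0, smooth = "auto",
                               ratio_flag = 2) {
  if (inherits(datasets, "dr_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    ll <- tryCatch({
      fit <- fit_log_logistic(d)
      cdv0_from_model(fit, threshold = threshold, ci = FALSE)
    }, error = function(e) {
      cdv0_estimate(method = "log_logistic", censored = "NS",
                    threshold = threshold, notes = conditionMessage(e))
    })
    li <- tryCatch(
      cdv0_linear_interpolation(d, threshold = threshold, smooth = smooth),
      error = function(e) cdv0_estimate(method = "linear_interpolation",
                                        censored = "NS", threshold = threshold,
                                        notes = conditionMessage(e))
    )
    defined_ll <- ll$censored == "none"
    defined_li <- li$censored == "none"
    ratio <- if (defined_ll && defined_li) {
      max(ll$value, li$value) / min(ll$value, li$value)
    } else NA_real_
    flag <- xor(defined_ll, defined_li) ||
      (is.finite(ratio) && ratio > ratio_flag)
    data.frame(chemical_id = d$chemical_id,
               cdv0_ll = ll$value, cdv0_ll_status = ll$censored,
               cdv0_interp = li$value, cdv0_interp_status = li$censored,
               ratio = ratio, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
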