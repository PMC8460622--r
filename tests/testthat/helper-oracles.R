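# Shared fixtures and independent oracles used across the test files.

# 9-point log-spaced grid spanning the assay's working range
log_grid <- function(n = 9, lo = 1, hi = 500) {
  exp(seq(log(lo), log(hi), length.out = n))
}

quiet_dataset <- function(...) suppressWarnings(dose_response_dataset(...))

# Independent oracle for the threshold crossing of the log-logistic curve:
# bisection root finding on f(x) - threshold over log-concentration, ignorant
# of the closed form used by cdv0_from_model().
bisect_crossing <- function(b, c, d, e, threshold = 0,
                            lower = 1e-12, upper = 1e12) {
  g <- function(lx) ll4(exp(lx), b, c, d, e) - threshold
  exp(stats::uniroot(g, c(log(lower), log(upper)), tol = 1e-14)$root)
}

# Independent oracle for the least-squares fit: exhaustive grid search over
# (b, d, e) refined twice around the best cell. Slow but has no shared code
# with the package optimizer.
grid_search_fit <- function(x, y, cc,
                            b_range = c(-6, -0.2),
                            d_range = NULL,
                            e_range = NULL,
                            n_grid = 12, refinements = 2) {
  if (is.null(d_range)) d_range <- c(max(y) - 0.5, max(y) + 0.5)
  if (is.null(e_range)) e_range <- range(x)
  rss_of <- function(b, d, e) sum((y - ll4(x, b, cc, d, e))^2)
  best <- NULL
  for (r in 0:refinements) {
    bs <- seq(b_range[1], b_range[2], length.out = n_grid)
    ds <- seq(d_range[1], d_range[2], length.out = n_grid)
    les <- seq(log(e_range[1]), log(e_range[2]), length.out = n_grid)
    for (b in bs) for (d in ds) for (le in les) {
      v <- rss_of(b, d, exp(le))
      if (is.null(best) || v < best$rss) {
        best <- list(b = b, d = d, e = exp(le), rss = v)
      }
    }
    # shrink each range around the current best
    shrink <- function(rng, center, factor = 0.35) {
      w <- diff(rng) * factor
      c(center - w / 2, center + w / 2)
    }
    b_range <- shrink(b_range, best$b)
    d_range <- shrink(d_range, best$d)
    le_rng <- shrink(log(e_range), log(best$e))
    e_range <- exp(le_rng)
  }
  best
}
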