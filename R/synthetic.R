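#' Simulate one dose-response dataset
#'
#' Generates a synthetic chemical with decision values drawn from the
#' four-parameter log-logistic model plus i.i.d. Gaussian noise on the DV
#' scale: `DV_i = f(c_i; b, c, d, e) + eps_i`. The control DV equals the
#' model's lower asymptote `c`, matching the assay's anchoring of the fixed
#' lower limit at unstimulated controls. Optional deterministic
#' contamination (added to the mean before noise) mimics response shapes
#' observed in real data that violate the sigmoid assumption:
#' * `"u_shape"` adds a positive component at the lowest concentrations
#'   (apparent U-shape);
#' * `"two_phase"` adds an early secondary rise to a moderate positive
#'   plateau well below the main transition, so the true lowest crossing
#'   sits far below the sigmoid midpoint.
#'
#' The default grid is the first nine steps of the standard Eq.-style ladder
#' anchored at the 500 µM cap (see [design_series()]), one replicate per
#' concentration.
#'
#' @param true_params named numeric vector/list with elements `b` (< 0),
#'   `c` (< 0), `d`, `e` (> 0).
#' @param concentrations assay grid, µM; default first 9 ladder steps from
#'   500 µM.
#' @param noise_sd Gaussian noise standard deviation on the DV scale
#'   (default 0.1); 0 gives exact model evaluations.
#' @param contamination `"none"` (default), `"u_shape"`, or `"two_phase"`.
#' @param seed optional integer; identical seeds give identical datasets.
#' @param chemical_id label, default `"synthetic"`.
#' @return a [dose_response_dataset()].
#' @examples
#' d <- simulate_dataset(c(b = -1.5, c = -1, d = 1, e = 20), seed = 1)
#' d
#' @export
simulate_dataset <- function(true_params, concentrations = NULL,
                             noise_sd = 0.1,
                             contamination = c("none", "u_shape", "two_phase"),
                             seed = NULL, chemical_id = "synthetic") {
  contamination <- match.arg(contamination)
  p <- as.list(true_params)
  for (nm in c("b", "c", "d", "e")) {
    if (is.null(p[[nm]]) || !is.finite(p[[nm]])) {
      stop(sprintf("`true_params` must supply finite '%s'", nm), call. = FALSE)
    }
  }
  if (p$b >= 0) stop("slope `b` must be negative", call. = FALSE)
  if (p$c >= 0) stop("lower asymptote `c` must be negative (control DV)",
                     call. = FALSE)
  if (p$e <= 0) stop("midpoint `e` must be positive", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  if (is.null(concentrations)) {
    concentrations <- design_series(500, cap = 500)$concentration_uM[1:9]
  }
  x <- sort(as.numeric(concentrations))
  mu <- ll4(x, p$b, p$c, p$d, p$e)
  if (contamination == "u_shape") {
    # positive limb at the lowest concentrations, decaying over ~1 decade
    amp <- (0 - p$c) + 0.3
    mu <- mu + amp / (1 + exp(3 * (log(x) - log(min(x) * 3))))
  } else if (contamination == "two_phase") {
    # early secondary transition to a moderate positive plateau
    amp <- (0 - p$c) + 0.3
    mu <- mu + amp / (1 + exp(-3 * (log(x) - log(p$e / 25))))
  }
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise_sd > 0) stats::rnorm(length(x), 0, noise_sd) else 0
  dose_response_dataset(chemical_id, x, mu + eps,
                        control_dv = p$c,
                        input_concentration = max(x) * (3 / 5)^2)
}

#' Simulate a chemical panel with known ground truth
#'
#' Emulates a study panel of sensitizers and non-sensitizers. Sensitizers
#' get sigmoidal curves with lower asymptote −1 and upper asymptote +1, so
#' the true threshold crossing (true cDV0 at DV = 0) equals the midpoint
#' `e`, drawn log-uniformly over `potency_range`; slopes are drawn uniformly
#' from (−2.5, −0.8). Non-sensitizers are flat at the control DV plus noise.
#' All chemicals are assayed on the full 12-step ladder anchored at the
#' 500 µM cap, one replicate per concentration.
#'
#' @param n_sensitizers,n_nonsensitizers panel composition (defaults 22 / 7,
#'   the study regime).
#' @param potency_range range of true crossing concentrations, µM
#'   (default `c(1, 500)`).
#' @param noise_sd DV-scale noise (default 0.1).
#' @param seed integer seed; all randomness is funneled through it.
#' @param control_dv control decision value (default −1).
#' @return list with `datasets` (named list of [dose_response_dataset()])
#'   and `truth` (data frame: `chemical_id`, `sensitizer`, `true_cdv0`,
#'   `b`, `d`, `e`).
#' @examples
#' panel <- simulate_panel(3, 2, seed = 1)
#' panel$truth
#' @export
simulate_panel <- function(n_sensitizers = 22L, n_nonsensitizers = 7L,
                           potency_range = c(1, 500), noise_sd = 0.1,
                           seed = NULL, control_dv = -1) {
  stopifnot(n_sensitizers >= 0, n_nonsensitizers >= 0,
            length(potency_range) == 2L, all(potency_range > 0),
            control_dv < 0)
  if (!is.null(seed)) set.seed(seed)
  grid <- design_series(500, cap = 500)$concentration_uM
  datasets <- list()
  truth <- list()

  if (n_sensitizers > 0) {
    e_true <- exp(stats::runif(n_sensitizers,
                               log(potency_range[1]), log(potency_range[2])))
    b_true <- stats::runif(n_sensitizers, -2.5, -0.8)
    sub_seeds <- sample.int(.Machine$integer.max, n_sensitizers)
    for (k in seq_len(n_sensitizers)) {
      id <- sprintf("S%02d", k)
      datasets[[id]] <- simulate_dataset(
        c(b = b_true[k], c = control_dv, d = -control_dv, e = e_true[k]),
        concentrations = grid, noise_sd = noise_sd,
        seed = sub_seeds[k], chemical_id = id)
      truth[[id]] <- data.frame(chemical_id = id, sensitizer = TRUE,
                                true_cdv0 = e_true[k], b = b_true[k],
                                d = -control_dv, e = e_true[k])
    }
  }
  if (n_nonsensitizers > 0) {
    sub_seeds <- sample.int(.Machine$integer.max, n_nonsensitizers)
    for (k in seq_len(n_nonsensitizers)) {
      id <- sprintf("N%02d", k)
      if (!is.null(sub_seeds[k])) set.seed(sub_seeds[k])
      dv <- control_dv + stats::rnorm(length(grid), 0, max(noise_sd, 0))
      datasets[[id]] <- dose_response_dataset(id, grid, dv,
                                              control_dv = control_dv,
                                              input_concentration = 500)
      truth[[id]] <- data.frame(chemical_id = id, sensitizer = FALSE,
                                true_cdv0 = NA_real_, b = NA_real_,
                                d = NA_real_, e = NA_real_)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chemical_id = character(), sensitizer = logical(),
               true_cdv0 = numeric(), b = numeric(), d = numeric(),
               e = numeric())
  rownames(truth) <- NULL
  list(datasets = datasets, truth = truth)
}
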