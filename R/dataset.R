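#' Construct a dose-response dataset for one chemical
#'
#' The unit of analysis for GARDskin dose-response work: one chemical's
#' assayed concentrations (in micromolar) paired with the decision values
#' (DVs) produced by the frozen GARDskin classifier, plus the decision value
#' of unstimulated controls. The control DV anchors the fixed lower asymptote
#' of the log-logistic model and must therefore classify negative (be < 0).
#'
#' Points are stored sorted by ascending concentration. Duplicate
#' concentrations (replicates) are permitted and retained. Points flagged
#' non-viable (failed the cytotoxicity screen) are kept in the object but
#' excluded by the fitting and estimation routines.
#'
#' @param chemical_id character scalar naming the chemical.
#' @param concentration numeric vector of assayed concentrations, µM, all > 0.
#' @param dv numeric vector of decision values, same length as
#'   `concentration`; must be finite.
#' @param viable logical vector (recycled) marking concentrations that passed
#'   the cytotoxicity screen. Default all `TRUE`.
#' @param is_input logical vector (recycled) marking the GARD input
#'   concentration. Default all `FALSE`.
#' @param control_dv decision value of unstimulated controls; must be < 0.
#' @param input_concentration optional GARD input concentration, µM.
#'
#' @return An object of class `"dr_dataset"`: a list with elements
#'   `chemical_id`, `points` (data frame with columns `concentration`, `dv`,
#'   `viable`, `is_input`), `control_dv` and `input_concentration`.
#' @examples
#' d <- dose_response_dataset("example",
#'   concentration = c(1, 3, 10, 30, 100),
#'   dv = c(-0.9, -0.7, 0.1, 0.8, 1.0),
#'   control_dv = -1)
#' d
#' @export
dose_response_dataset <- function(chemical_id, concentration, dv,
                                  viable = TRUE, is_input = FALSE,
                                  control_dv = -1,
                                  input_concentration = NA_real_) {
  stopifnot(is.character(chemical_id), length(chemical_id) == 1L)
  concentration <- as.numeric(concentration)
  dv <- as.numeric(dv)
  if (length(concentration) != length(dv)) {
    stop("`concentration` and `dv` must have the same length", call. = FALSE)
  }
  if (length(concentration) == 0L) {
    stop("dataset must contain at least one point", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("all concentrations must be finite and > 0 (log-concentration must be defined)",
         call. = FALSE)
  }
  if (any(!is.finite(dv))) {
    stop("all decision values must be finite", call. = FALSE)
  }
  if (!is.finite(control_dv) || control_dv >= 0) {
    stop("`control_dv` must be < 0: an unstimulated control must classify negative",
         call. = FALSE)
  }
  viable <- rep_len(as.logical(viable), length(concentration))
  is_input <- rep_len(as.logical(is_input), length(concentration))
  ord <- order(concentration)
  pts <- data.frame(
    concentration = concentration[ord],
    dv = dv[ord],
    viable = viable[ord],
    is_input = is_input[ord]
  )
  n_distinct <- length(unique(pts$concentration[pts$viable]))
  if (n_distinct < 4L) {
    warning(sprintf("dataset '%s' has only %d distinct viable concentration(s); >= 4 recommended",
                    chemical_id, n_distinct), call. = FALSE)
  }
  structure(
    list(chemical_id = chemical_id, points = pts,
         control_dv = control_dv,
         input_concentration = as.numeric(input_concentration)),
    class = "dr_dataset"
  )
}

#' @export
print.dr_dataset <- function(x, ...) {
  pts <- x$points
  cat(sprintf("GARDskin dose-response dataset: %s\n", x$chemical_id))
  cat(sprintf("  %d points, %d distinct concentrations (%g - %g uM), %d non-viable\n",
              nrow(pts), length(unique(pts$concentration)),
              min(pts$concentration), max(pts$concentration),
              sum(!pts$viable)))
  cat(sprintf("  control DV: %g", x$control_dv))
  if (is.finite(x$input_concentration)) {
    cat(sprintf(", input concentration: %g uM", x$input_concentration))
  }
  cat("\n")
  invisible(x)
}

#' Viable points of a dataset
#'
#' Returns the subset of points that passed the cytotoxicity screen, the
#' points the fitting and estimation routines operate on.
#'
#' @param data a [dose_response_dataset()].
#' @return data frame of viable points, sorted by concentration.
#' @export
viable_points <- function(data) {
  stopifnot(inherits(data, "dr_dataset"))
  data$points[data$points$viable, , drop = FALSE]
}
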