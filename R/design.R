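#' Design the geometric concentration series for a chemical
#'
#' Generates the assay's standard concentration ladder: a descending
#' geometric sequence with scaling factor 3/5 whose third step equals the
#' GARD input concentration, i.e. `c_i = c_input * (3/5)^(i - 3)` for
#' `i = 1..n_steps`. The highest concentration is thus two steps above the
#' input concentration, unless that exceeds the assay's upper concentration
#' limit (`cap`, default 500 µM), in which case the whole ladder is
#' re-anchored to descend from the cap. (A `cap_mode = "truncate"`
#' alternative instead drops the over-cap steps of the uncapped ladder.)
#'
#' @param c_input GARD input concentration, µM, > 0.
#' @param cap upper concentration limit, µM (default 500).
#' @param n_steps number of steps (default 12).
#' @param cap_mode `"reanchor"` (default) or `"truncate"`.
#' @param chemical_id optional label.
#' @return An object of class `"concentration_series"`: a data frame with
#'   columns `i`, `concentration_uM`, `selected`, and attributes `c_input`,
#'   `cap`, `chemical_id`, `exclusions`.
#' @examples
#' design_series(100)      # steps 277.8, 166.7, 100, 60, ...
#' design_series(500)      # anchored at the 500 uM cap
#' @export
design_series <- function(c_input, cap = 500, n_steps = 12L,
                          cap_mode = c("reanchor", "truncate"),
                          chemical_id = NA_character_) {
  cap_mode <- match.arg(cap_mode)
  if (length(c_input) != 1L || !is.finite(c_input) || c_input <= 0) {
    stop("`c_input` must be a single positive concentration", call. = FALSE)
  }
  stopifnot(is.finite(cap), cap > 0, n_steps >= 1)
  ratio <- 3 / 5
  anchor <- c_input * ratio^(-2)  # two steps above the input concentration
  i <- seq_len(n_steps)
  if (anchor > cap && cap_mode == "reanchor") {
    conc <- cap * ratio^(i - 1)
  } else {
    conc <- c_input * ratio^(i - 3)
    if (cap_mode == "truncate") conc <- conc[conc <= cap]
  }
  out <- data.frame(i = seq_along(conc), concentration_uM = conc,
                    selected = TRUE)
  structure(out, class = c("concentration_series", "data.frame"),
            c_input = c_input, cap = cap, chemical_id = chemical_id,
            exclusions = data.frame(concentration_uM = numeric(),
                                    reason = character()))
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("Concentration series (input %g uM, cap %g uM): %d steps, %d selected\n",
              attr(x, "c_input"), attr(x, "cap"), nrow(x), sum(x$selected)))
  print.data.frame(x, row.names = FALSE, digits = 6)
  ex <- attr(x, "exclusions")
  if (nrow(ex)) {
    cat("Exclusions:\n")
    print.data.frame(ex, row.names = FALSE, digits = 6)
  }
  invisible(x)
}

#' Select the concentrations carried into the assay
#'
#' Deselects ladder steps that failed the cytotoxicity screen and,
#' optionally, the lowest evaluated concentration, mirroring the assay
#' practice of carrying eight to nine of the twelve designed concentrations
#' into quantification. Every exclusion is logged with its reason in the
#' series' `exclusions` attribute.
#'
#' @param series a [design_series()] result.
#' @param viability viability map: a named logical vector (names are
#'   concentrations) or a data frame with columns `concentration_uM` and
#'   `viable`. Concentrations absent from the map are assumed viable.
#' @param drop_lowest drop the smallest still-selected concentration
#'   (default `TRUE`).
#' @return the series with updated `selected` column and exclusion log;
#'   warns when the selected count falls outside 8-9.
#' @export
select_for_assay <- function(series, viability = NULL, drop_lowest = TRUE) {
  stopifnot(inherits(series, "concentration_series"))
  conc <- series$concentration_uM
  selected <- series$selected
  exclusions <- attr(series, "exclusions")

  if (!is.null(viability)) {
    if (is.data.frame(viability)) {
      vmap <- stats::setNames(as.logical(viability$viable),
                              format(viability$concentration_uM, digits = 15))
    } else {
      vmap <- stats::setNames(as.logical(viability), names(viability))
    }
    keys <- format(conc, digits = 15)
    alt_keys <- as.character(conc)
    for (idx in seq_along(conc)) {
      v <- vmap[keys[idx]]
      if (is.na(v)) v <- vmap[alt_keys[idx]]
      if (!is.na(v) && !v && selected[idx]) {
        selected[idx] <- FALSE
        exclusions <- rbind(exclusions, data.frame(
          concentration_uM = conc[idx], reason = "excessive cytotoxicity"))
      }
    }
  }
  if (isTRUE(drop_lowest) && any(selected)) {
    low <- which(selected)[which.min(conc[selected])]
    selected[low] <- FALSE
    exclusions <- rbind(exclusions, data.frame(
      concentration_uM = conc[low], reason = "lowest evaluated concentration"))
  }
  n_sel <- sum(selected)
  if (n_sel < 8 || n_sel > 9) {
    warning(sprintf("%d concentrations selected; the assay typically carries 8-9",
                    n_sel), call. = FALSE)
  }
  series$selected <- selected
  attr(series, "exclusions") <- exclusions
  series
}
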