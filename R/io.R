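#' Analysis configuration
#'
#' Bundles the tunable constants of the workflow with their standard
#' defaults: classification threshold DV >= 0, window-3 running median,
#' 95% confidence level, 2% EC3 cutoff for GHS sub-categorization, 500 µM
#' assay concentration cap, and the linear-interpolation estimator for
#' benchmarking (the less constrained of the two estimators).
#'
#' @param threshold DV threshold (default 0).
#' @param smoothing_window odd running-median window (default 3).
#' @param smooth smoothing policy for interpolation: `FALSE`, `TRUE` or
#'   `"auto"` (default).
#' @param ci_level confidence level (default 0.95).
#' @param ghs_cutoff EC3 sub-categorization cutoff, % (default 2).
#' @param cap concentration cap, µM (default 500).
#' @param estimator estimator used for benchmarking:
#'   `"linear_interpolation"` (default) or `"log_logistic"`.
#' @param seed integer seed for any simulation steps (default 1).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(threshold = 0, smoothing_window = 3, smooth = "auto",
                       ci_level = 0.95, ghs_cutoff = 2, cap = 500,
                       estimator = c("linear_interpolation", "log_logistic"),
                       seed = 1L) {
  estimator <- match.arg(estimator)
  if (smoothing_window %% 2 != 1) {
    stop("`smoothing_window` must be odd", call. = FALSE)
  }
  structure(list(threshold = threshold,
                 smoothing_window = as.integer(smoothing_window),
                 smooth = smooth, ci_level = ci_level,
                 ghs_cutoff = ghs_cutoff, cap = cap,
                 estimator = estimator, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a configuration as a flat key=value file
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_config()` returns a `"run_config"`; writing returns the
#'   path invisibly. A written configuration reads back identically.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(k) {
    paste0(k, "=", format(config[[k]], digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  cfg <- stats::setNames(as.list(vals), keys)
  num <- function(x) as.numeric(x)
  run_config(
    threshold = num(cfg$threshold),
    smoothing_window = num(cfg$smoothing_window),
    smooth = if (cfg$smooth %in% c("TRUE", "FALSE")) as.logical(cfg$smooth)
             else cfg$smooth,
    ci_level = num(cfg$ci_level),
    ghs_cutoff = num(cfg$ghs_cutoff),
    cap = num(cfg$cap),
    estimator = cfg$estimator,
    seed = as.integer(cfg$seed)
  )
}

#' Read dose-response datasets from a delimited file
#'
#' Expects a header row and columns `chemical_id`, `concentration_uM`, `dv`;
#' optional columns `viable` (0/1, default 1), `is_input` (0/1, default 0)
#' and `control_dv` (constant per chemical; falls back to the `control_dv`
#' argument when absent). Comma- and tab-delimited files are both accepted
#' (sniffed from the header). Malformed rows are reported with their line
#' numbers; an empty file yields an empty collection with a warning.
#'
#' @param path file path.
#' @param control_dv default control decision value used when the file has
#'   no `control_dv` column (default −1).
#' @return named list of [dose_response_dataset()] objects, one per
#'   chemical.
#' @export
read_dose_response <- function(path, control_dv = -1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("no data rows in ", path, call. = FALSE)
    return(list())
  }
  need <- c("chemical_id", "concentration_uM", "dv")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"viable" %in% names(df)) df$viable <- 1L
  if (!"is_input" %in% names(df)) df$is_input <- 0L
  has_control_col <- "control_dv" %in% names(df)

  conc <- suppressWarnings(as.numeric(df$concentration_uM))
  dv <- suppressWarnings(as.numeric(df$dv))
  bad <- which(!is.finite(conc) | conc <= 0 | !is.finite(dv))
  if (length(bad)) {
    stop(sprintf("malformed row(s) at line(s) %s: concentration must be a positive number and dv finite",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  out <- list()
  for (id in unique(df$chemical_id)) {
    sub <- df[df$chemical_id == id, , drop = FALSE]
    cdv <- if (has_control_col) as.numeric(sub$control_dv[1]) else control_dv
    inp <- sub$concentration_uM[as.logical(as.integer(sub$is_input))]
    out[[as.character(id)]] <- dose_response_dataset(
      chemical_id = as.character(id),
      concentration = as.numeric(sub$concentration_uM),
      dv = as.numeric(sub$dv),
      viable = as.logical(as.integer(sub$viable)),
      is_input = as.logical(as.integer(sub$is_input)),
      control_dv = cdv,
      input_concentration = if (length(inp)) as.numeric(inp[1]) else NA_real_)
  }
  out
}

#' Write dose-response datasets to the standard CSV layout
#'
#' Inverse of [read_dose_response()]; numeric columns are written with 6
#' significant digits so repeated runs are byte-identical.
#'
#' @param datasets a dataset or list of datasets.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_dose_response <- function(datasets, path) {
  if (inherits(datasets, "dr_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    data.frame(chemical_id = d$chemical_id,
               concentration_uM = fmt_num(d$points$concentration),
               dv = fmt_num(d$points$dv),
               viable = as.integer(d$points$viable),
               is_input = as.integer(d$points$is_input),
               control_dv = fmt_num(d$control_dv),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# fixed 6-significant-digit text rendering for deterministic CSV output
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}
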