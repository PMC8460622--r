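#' Run the full dose-response workflow
#'
#' Orchestrates the analysis end to end for a collection of chemicals:
#' constrained log-logistic fit, no-effect likelihood-ratio test, cDV0 by
#' both estimators (model-based with confidence interval, linear
#' interpolation with the configured smoothing policy), estimator
#' comparison, and -- when a reference table is supplied -- weight-based
#' unit conversion, GHS sub-categorization, log-scale Pearson correlations
#' against LLNA EC3 and human NOEL, and the class-separation report.
#' Per-chemical failures are recorded as censored outcomes, never abort the
#' batch, and every exclusion or censoring emits one structured audit line.
#'
#' @param input a named list of [dose_response_dataset()] objects, or a path
#'   readable by [read_dose_response()].
#' @param reference optional [read_reference_table()]-style data frame (or
#'   path) keyed by `chemical` matching the dataset names.
#' @param config a [run_config()].
#' @param output_dir optional directory; when given, writes `fits.csv`,
#'   `cdv0.csv`, `comparison.csv`, `correlations.json` and `audit.log`.
#' @return list with elements `fits` (per-chemical fit + test table),
#'   `cdv0` (per-chemical estimate table), `comparison`
#'   ([compare_estimators()] output), `correlations` (list of
#'   `correlation_result`, when a reference was given), `separation`
#'   (class-separation report, when a reference was given), `audit`
#'   (character vector).
#' @examples
#' panel <- simulate_panel(4, 2, seed = 7)
#' res <- run_pipeline(panel$datasets)
#' res$cdv0
#' @export
run_pipeline <- function(input, reference = NULL, config = run_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  datasets <- if (is.character(input)) read_dose_response(input) else input
  if (inherits(datasets, "dr_dataset")) datasets <- list(datasets)
  if (is.character(reference)) reference <- read_reference_table(reference)

  audit <- character()
  log_line <- function(...) {
    audit[[length(audit) + 1L]] <<- sprintf(...)
  }

  fit_rows <- list()
  cdv0_rows <- list()
  for (d in datasets) {
    id <- d$chemical_id
    n_excl <- sum(!d$points$viable)
    if (n_excl > 0) {
      log_line("exclude\t%s\t%d non-viable concentration(s) removed before fitting",
               id, n_excl)
    }
    fit <- tryCatch(suppressWarnings(fit_log_logistic(d)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      log_line("error\t%s\tfit failed: %s", id, conditionMessage(fit))
      fit_rows[[id]] <- data.frame(
        chemical_id = id, b = NA_real_, c = d$control_dv, d = NA_real_,
        e = NA_real_, rss = NA_real_, loglik = NA_real_, converged = FALSE,
        lr_stat = NA_real_, df = NA_integer_, p_no_effect = NA_real_,
        stringsAsFactors = FALSE)
      est_ll <- cdv0_estimate(method = "log_logistic", censored = "NS",
                              threshold = config$threshold,
                              notes = "model fit failed")
    } else {
      net <- no_effect_test(d, fit)
      fit_rows[[id]] <- data.frame(
        chemical_id = id, b = fit$b, c = fit$c, d = fit$d, e = fit$e,
        rss = fit$rss, loglik = fit$log_likelihood, converged = fit$converged,
        lr_stat = net$lr_statistic, df = net$df, p_no_effect = net$p_value,
        stringsAsFactors = FALSE)
      est_ll <- cdv0_from_model(fit, threshold = config$threshold,
                                level = config$ci_level)
    }
    est_li <- tryCatch(
      cdv0_linear_interpolation(d, threshold = config$threshold,
                                smooth = config$smooth,
                                window = config$smoothing_window),
      error = function(e) cdv0_estimate(method = "linear_interpolation",
                                        censored = "NS",
                                        threshold = config$threshold,
                                        notes = conditionMessage(e)))
    if (est_li$censored != "none") {
      log_line("censor\t%s\tinterpolation cDV0: %s", id, est_li$censored)
    }
    if (est_ll$censored != "none") {
      log_line("censor\t%s\tmodel cDV0: %s (%s)", id, est_ll$censored,
               paste(est_ll$notes, collapse = "; "))
    }
    cdv0_rows[[id]] <- data.frame(
      chemical_id = id,
      cdv0_interp_uM = est_li$value,
      cdv0_ll_uM = est_ll$value,
      ci_low_uM = est_ll$ci_low,
      ci_high_uM = est_ll$ci_high,
      censored_interp = est_li$censored,
      censored_ll = est_ll$censored,
      smoothed = "running median applied" %in% est_li$notes,
      p_no_effect = fit_rows[[id]]$p_no_effect,
      stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, fit_rows); rownames(fits) <- NULL
  cdv0_tab <- do.call(rbind, cdv0_rows); rownames(cdv0_tab) <- NULL
  comparison <- compare_estimators(datasets, threshold = config$threshold,
                                   smooth = config$smooth)
  for (i in which(comparison$flag)) {
    log_line("flag\t%s\testimator discrepancy (ll=%s, interp=%s, ratio=%s)",
             comparison$chemical_id[i],
             fmt_num(comparison$cdv0_ll[i]), fmt_num(comparison$cdv0_interp[i]),
             fmt_num(comparison$ratio[i]))
  }

  correlations <- NULL
  separation <- NULL
  if (!is.null(reference)) {
    merged <- merge(reference,
                    cdv0_tab[, c("chemical_id", "cdv0_interp_uM", "cdv0_ll_uM",
                                 "censored_interp", "censored_ll")],
                    by.x = "chemical", by.y = "chemical_id", all.x = TRUE)
    est_col <- if (config$estimator == "linear_interpolation")
      "cdv0_interp_uM" else "cdv0_ll_uM"
    merged$cdv0_est_uM <- merged[[est_col]]
    merged$cdv0_est_mgL <- um_to_mg_per_l(merged$cdv0_est_uM,
                                          merged$molecular_weight)
    merged$cdv0_est_mgL_status <- ifelse(is.na(merged$cdv0_est_mgL), "NS",
                                         "value")
    correlations <- list()
    for (metric in c("llna_ec3", "human_noel")) {
      res <- tryCatch(correlate_potency(merged, metric,
                                        cdv0_col = "cdv0_est_mgL"),
                      error = function(e) e)
      if (inherits(res, "error")) {
        log_line("error\tbenchmark\t%s correlation failed: %s", metric,
                 conditionMessage(res))
      } else {
        correlations[[metric]] <- res
        log_line("benchmark\t%s\tr=%.3f p=%.3g n=%d", metric, res$r,
                 res$p_value, res$n)
      }
    }
    separation <- class_separation_report(merged, cdv0_col = "cdv0_est_uM")
  }

  out <- list(fits = fits, cdv0 = cdv0_tab, comparison = comparison,
              correlations = correlations, separation = separation,
              audit = audit)
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

# serialize the pipeline outputs with fixed 6-significant-digit numbers so
# reruns are byte-identical
write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt_num)
    utils::write.csv(df, file.path(output_dir, file), row.names = FALSE,
                     quote = TRUE)
  }
  wr(result$fits, "fits.csv")
  wr(result$cdv0, "cdv0.csv")
  wr(result$comparison, "comparison.csv")
  if (!is.null(result$correlations)) {
    cj <- lapply(result$correlations, function(cr) {
      list(r = signif(cr$r, 6), p_value = signif(cr$p_value, 6), n = cr$n)
    })
    jsonlite::write_json(cj, file.path(output_dir, "correlations.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  writeLines(result$audit, file.path(output_dir, "audit.log"))
  invisible(output_dir)
}
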