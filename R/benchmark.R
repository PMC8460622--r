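#' Convert a molar concentration to a weight-based concentration
#'
#' `mg/L = µM * MW / 1000`. Weight-based cDV0 values are what the potency
#' correlations use, since the reference metrics (LLNA EC3 in %, human NOEL
#' in µg/cm²) are weight-based.
#'
#' @param concentration_um concentration in µM, > 0 (vectorized; `NA`
#'   propagates).
#' @param molecular_weight molecular weight in g/mol, > 0.
#' @return concentration in mg/L.
#' @examples
#' um_to_mg_per_l(1000, 1000)  # 1000 mg/L
#' @export
um_to_mg_per_l <- function(concentration_um, molecular_weight) {
  ok <- is.na(concentration_um) | concentration_um > 0
  if (any(!ok) || any(!is.na(molecular_weight) & molecular_weight <= 0)) {
    stop("concentration and molecular weight must be positive", call. = FALSE)
  }
  concentration_um * molecular_weight / 1000
}

#' @rdname um_to_mg_per_l
#' @param concentration_mgL concentration in mg/L, > 0.
#' @export
mg_per_l_to_um <- function(concentration_mgL, molecular_weight) {
  ok <- is.na(concentration_mgL) | concentration_mgL > 0
  if (any(!ok) || any(!is.na(molecular_weight) & molecular_weight <= 0)) {
    stop("concentration and molecular weight must be positive", call. = FALSE)
  }
  concentration_mgL / molecular_weight * 1000
}

#' GHS skin-sensitizer sub-category from an LLNA EC3 value
#'
#' Applies the standard 2% EC3 cutoff: `EC3 <= 2` is sub-category 1A
#' (strong), `EC3 > 2` is 1B, and a non-sensitizing LLNA outcome (`NA` or
#' the token `"NS"`) is No Cat.
#'
#' @param ec3 numeric EC3 (%) vector; `NA` or `"NS"` means LLNA
#'   non-sensitizer.
#' @param cutoff sub-categorization threshold, % (default 2).
#' @return character vector with levels `"1A"`, `"1B"`, `"NoCat"`.
#' @examples
#' ghs_subcategory(c(0.06, 2, 2.1, NA))
#' @export
ghs_subcategory <- function(ec3, cutoff = 2) {
  if (is.character(ec3)) {
    ec3[toupper(ec3) %in% c("NS", "NA", "")] <- NA
    ec3 <- as.numeric(ec3)
  }
  out <- ifelse(is.na(ec3), "NoCat", ifelse(ec3 <= cutoff, "1A", "1B"))
  out
}

# Parse a fixture column carrying numeric values and censoring tokens
# (NS/ND/NA/NM) into a numeric vector plus a status vector.
parse_censored <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == ""] <- "NA"
  status <- rep("value", length(x))
  tok <- toupper(x) %in% c("NS", "ND", "NA", "NM")
  status[tok] <- toupper(x)[tok]
  num <- suppressWarnings(as.numeric(x))
  num[tok] <- NA_real_
  list(value = num, status = status)
}

#' Load a chemical reference potency table
#'
#' Reads the bundled reference table (or a user-supplied file in the same
#' layout): one row per chemical with CAS, molecular weight, sensitizer
#' status, LLNA EC3 (%), human NOEL (µg/cm²), GARD input concentration, the
#' study's cDV0 estimates in µM (both estimators, with the model-based 95%
#' CI), cDV0 in mg/L, and the no-effect p-value. Censored entries use the
#' literal uppercase tokens `NS` (non-sensitizer), `ND` (no NOEL
#' definable), `NA` (value not definable) and `NM` (not meaningful).
#'
#' The loader parses tokens into numeric columns plus `_status` columns,
#' assigns GHS sub-categories from EC3, and checks each row's unit
#' consistency `cdv0_mgL ~= cdv0_uM * MW / 1000` (warning beyond 2%
#' relative, which absorbs the table's printed rounding).
#'
#' @param path CSV path; default the table bundled with the package.
#' @return data frame of class `"chemical_reference"`.
#' @examples
#' ref <- read_reference_table()
#' head(ref[, c("chemical", "llna_ec3", "cdv0_mgL", "ghs")])
#' @export
read_reference_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_reference.csv", package = "cdv0",
                        mustWork = TRUE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("chemical", "cas", "molecular_weight", "sensitizer", "llna_ec3",
            "noel_ug_cm2", "gard_input_uM", "cdv0_uM", "cdv0_mgL")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("reference table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ec3 <- parse_censored(raw$llna_ec3)
  noel <- parse_censored(raw$noel_ug_cm2)
  cdv0u <- parse_censored(raw$cdv0_uM)
  cdv0m <- parse_censored(raw$cdv0_mgL)
  ll <- if ("cdv0_ll_uM" %in% names(raw)) parse_censored(raw$cdv0_ll_uM) else
    list(value = rep(NA_real_, nrow(raw)), status = rep("NA", nrow(raw)))
  out <- data.frame(
    chemical = raw$chemical,
    cas = raw$cas,
    molecular_weight = as.numeric(raw$molecular_weight),
    sensitizer = tolower(raw$sensitizer) %in% c("yes", "true", "1"),
    llna_ec3 = ec3$value, llna_ec3_status = ec3$status,
    noel_ug_cm2 = noel$value, noel_status = noel$status,
    gard_input_uM = as.numeric(raw$gard_input_uM),
    cdv0_uM = cdv0u$value, cdv0_status = cdv0u$status,
    cdv0_ll_uM = ll$value, cdv0_ll_status = ll$status,
    cdv0_ll_ci_low = if ("cdv0_ll_ci_low" %in% names(raw))
      suppressWarnings(as.numeric(raw$cdv0_ll_ci_low)) else NA_real_,
    cdv0_ll_ci_high = if ("cdv0_ll_ci_high" %in% names(raw))
      suppressWarnings(as.numeric(raw$cdv0_ll_ci_high)) else NA_real_,
    cdv0_mgL = cdv0m$value, cdv0_mgL_status = cdv0m$status,
    p_no_effect = if ("p_no_effect" %in% names(raw))
      suppressWarnings(as.numeric(raw$p_no_effect)) else NA_real_,
    stringsAsFactors = FALSE
  )
  out$ghs <- ghs_subcategory(out$llna_ec3)
  both <- !is.na(out$cdv0_uM) & !is.na(out$cdv0_mgL) &
    !is.na(out$molecular_weight)
  if (any(both)) {
    implied <- um_to_mg_per_l(out$cdv0_uM[both], out$molecular_weight[both])
    rel <- abs(implied - out$cdv0_mgL[both]) / out$cdv0_mgL[both]
    bad <- rel > 0.02
    if (any(bad)) {
      warning("cdv0_uM * MW / 1000 deviates from cdv0_mgL by more than 2% for: ",
              paste(out$chemical[both][bad], collapse = ", "), call. = FALSE)
    }
  }
  class(out) <- c("chemical_reference", "data.frame")
  out
}

#' Log-scale Pearson correlation of cDV0 against a reference potency metric
#'
#' Pairs each chemical's weight-based cDV0 (mg/L by default) with LLNA EC3
#' (%) or human NOEL (µg/cm²), drops censored entries on either side
#' (NS/ND/NA/NM), log-transforms both variables and computes Pearson's
#' correlation coefficient with a two-sided t-test p-value (n − 2 df).
#' Pearson's r on log scales is invariant to the log base and to
#' multiplicative rescaling of either variable, so the choice of units does
#' not affect it.
#'
#' @param records a [read_reference_table()]-style data frame; needs the
#'   chosen metric column, its status column, and the cDV0 column with its
#'   status column.
#' @param metric `"llna_ec3"` or `"human_noel"`.
#' @param cdv0_col cDV0 column to correlate (default `"cdv0_mgL"`, the
#'   weight-based interpolation estimate).
#' @return object of class `"correlation_result"`: list with `r`,
#'   `p_value`, `n`, `metric`, `chemicals`.
#' @examples
#' ref <- read_reference_table()
#' correlate_potency(ref, "llna_ec3")
#' @export
correlate_potency <- function(records, metric = c("llna_ec3", "human_noel"),
                              cdv0_col = "cdv0_mgL") {
  metric <- match.arg(metric)
  mcol <- if (metric == "llna_ec3") "llna_ec3" else "noel_ug_cm2"
  scol <- if (metric == "llna_ec3") "llna_ec3_status" else "noel_status"
  stat_col <- paste0(cdv0_col, "_status")
  x <- records[[cdv0_col]]
  xs <- if (stat_col %in% names(records)) records[[stat_col]] else
    ifelse(is.na(x), "NA", "value")
  y <- records[[mcol]]
  ys <- if (scol %in% names(records)) records[[scol]] else
    ifelse(is.na(y), "NA", "value")
  keep <- xs == "value" & ys == "value" & !is.na(x) & !is.na(y) &
    x > 0 & y > 0
  n <- sum(keep)
  if (n < 3) {
    stop(sprintf("only %d complete pairs for metric '%s'; at least 3 required",
                 n, metric), call. = FALSE)
  }
  ct <- stats::cor.test(log(x[keep]), log(y[keep]), method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = n,
                 metric = metric,
                 chemicals = if ("chemical" %in% names(records))
                   records$chemical[keep] else NULL),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation (log scale), cDV0 vs %s:\n", x$metric))
  cat(sprintf("  r = %.3f, p = %.3g, n = %d\n", x$r, x$p_value, x$n))
  invisible(x)
}

#' GHS 1A/1B ordering of chemicals by cDV0
#'
#' Sorts chemicals with a defined cDV0 by potency and counts 1A/1B ordering
#' violations: pairs where a 1B chemical (weaker by LLNA) has a lower cDV0
#' than a 1A chemical (stronger). The summary flags 1B chemicals that rank
#' below any 1A chemical; complete class resolution corresponds to zero
#' flagged chemicals.
#'
#' @param records reference-style data frame with `ghs` and a cDV0 column.
#' @param cdv0_col column to rank on (default `"cdv0_uM"`).
#' @return list with `ordering` (chemicals sorted by cDV0 with class),
#'   `violations` (per-chemical violating-pair counts for flagged 1B
#'   chemicals) and `n_flagged`.
#' @examples
#' ref <- read_reference_table()
#' class_separation_report(ref)$violations
#' @export
class_separation_report <- function(records, cdv0_col = "cdv0_uM") {
  val <- records[[cdv0_col]]
  keep <- !is.na(val) & records$ghs %in% c("1A", "1B")
  chem <- if ("chemical" %in% names(records)) records$chemical[keep] else
    as.character(seq_len(sum(keep)))
  val <- val[keep]
  ghs <- records$ghs[keep]
  ord <- order(val)
  ordering <- data.frame(chemical = chem[ord], ghs = ghs[ord],
                         cdv0 = val[ord], stringsAsFactors = FALSE)
  a_vals <- val[ghs == "1A"]
  viol <- lapply(which(ghs == "1B"), function(i) {
    n_above <- sum(a_vals > val[i])
    if (n_above > 0) data.frame(chemical = chem[i], cdv0 = val[i],
                                violating_pairs = n_above,
                                stringsAsFactors = FALSE) else NULL
  })
  viol <- do.call(rbind, viol)
  if (is.null(viol)) viol <- data.frame(chemical = character(),
                                        cdv0 = numeric(),
                                        violating_pairs = integer())
  rownames(viol) <- NULL
  list(ordering = ordering, violations = viol, n_flagged = nrow(viol))
}
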