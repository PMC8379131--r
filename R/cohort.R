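# Longitudinal cohort statistics: annualized follow-up/baseline ratios,
# Pearson correlations of baseline functional means against reference
# values and their annualized change, NAA-vs-HAA paired tests.

#' Annualize a follow-up/baseline ratio
#'
#' Linear-change normalization to a 1-year interval:
#' `1 + (followup/baseline - 1) * (365.25 / interval_days)`. Identity at
#' exactly one year and linear in `(ratio - 1)`.
#'
#' @param baseline,followup scalar measurements (baseline must be nonzero).
#' @param interval_days days between the scans (> 0).
#' @param year_days length of the normalization year, default 365.25.
#' @return annualized ratio.
#' @export
annualize_ratio <- function(baseline, followup, interval_days,
                            year_days = 365.25) {
  if (any(interval_days <= 0)) stop("interval_days must be positive", call. = FALSE)
  if (any(baseline == 0)) stop("baseline must be nonzero", call. = FALSE)
  1 + (followup / baseline - 1) * (year_days / interval_days)
}

#' Pearson correlation with two-sided t-based p value
#'
#' Sample Pearson R computed from the covariance formula with the p value
#' from `t = R * sqrt((n - 2) / (1 - R^2))` against a t(n-2) reference.
#' Pairs with a missing value in either vector are deleted.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `R`, `p`, `n` (a `correlation_result`).
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) stop("zero variance input", call. = FALSE)
  R <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  R <- min(max(R, -1), 1)
  if (abs(R) >= 1) {
    p <- 0
  } else {
    tstat <- R * sqrt((n - 2) / (1 - R^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(R = R, p = p, n = n), class = "correlation_result")
}

#' Paired t test (two-sided)
#'
#' @param a,b numeric vectors of equal length (pairwise complete cases used).
#' @return list with `t`, `p`, `n`, `mean_difference`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length",
                                   call. = FALSE)
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  s <- sd(d)
  if (s == 0) {
    # identical vectors: no effect, t = 0 by convention; a constant nonzero
    # shift with zero spread is genuinely degenerate
    if (all(d == 0)) return(list(t = 0, p = 1, n = n, mean_difference = 0))
    stop("zero variance of paired differences", call. = FALSE)
  }
  tstat <- mean(d) / (s / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  list(t = tstat, p = p, n = n, mean_difference = mean(d))
}

COHORT_REFERENCES <- c("fvc_pct", "dlco_pct", "lung_volume_ml", "lung_density_hu")
COHORT_FUNCTIONALS <- c("ventilation", "perfusion", "late_enhancement")

#' Correlation table of baseline functional means vs cohort references
#'
#' For each of the three baseline functional parameters and each of the
#' four reference quantities (FVC%, DLCO%, lung volume, mean lung density)
#' computes the Pearson correlation against (a) the baseline value and
#' (b) the annualized follow-up/baseline ratio — a 3 x 8 matrix of cells.
#' Missing values are handled by pairwise deletion (each cell reports its
#' own n); cells with fewer than `min_n` complete pairs or zero variance
#' are marked unavailable rather than aborting. No multiple-testing
#' correction is applied by default.
#'
#' @param cohort data.frame as produced by [generate_cohort()] or read from
#'   a cohort TSV (see README for the column contract).
#' @param year_days year length for annualization.
#' @param min_n minimum complete pairs per cell, default 4.
#' @param p_adjust optional p-value adjustment method passed to
#'   [stats::p.adjust()] ("none" keeps the per-cell p values).
#' @return data.frame with one row per cell: `parameter`, `reference`,
#'   `timepoint` ("baseline" or "annual_ratio"), `R`, `p`, `n`,
#'   `available`, `sig_05`, `sig_01`.
#' @export
correlation_table <- function(cohort, year_days = 365.25, min_n = 4L,
                              p_adjust = "none") {
  cohort <- as.data.frame(cohort)
  need <- c("interval_days",
            paste0(COHORT_FUNCTIONALS, "_baseline"),
            paste0(rep(COHORT_REFERENCES, each = 2), c("_baseline", "_followup")))
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (fp in COHORT_FUNCTIONALS) {
    fvals <- cohort[[paste0(fp, "_baseline")]]
    for (ref in COHORT_REFERENCES) {
      base <- cohort[[paste0(ref, "_baseline")]]
      fup <- cohort[[paste0(ref, "_followup")]]
      ratio <- rep(NA_real_, nrow(cohort))
      ok <- is.finite(base) & is.finite(fup) & base != 0 &
        is.finite(cohort$interval_days) & cohort$interval_days > 0
      ratio[ok] <- annualize_ratio(base[ok], fup[ok], cohort$interval_days[ok],
                                   year_days)
      for (tp in c("baseline", "annual_ratio")) {
        yv <- if (tp == "baseline") base else ratio
        cell <- tryCatch(pearson_cor(fvals, yv), error = function(e) NULL)
        avail <- !is.null(cell) &&
          sum(is.finite(fvals) & is.finite(yv)) >= min_n
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = fp, reference = ref, timepoint = tp,
          R = if (avail) cell$R else NA_real_,
          p = if (avail) cell$p else NA_real_,
          n = sum(is.finite(fvals) & is.finite(yv)),
          available = avail, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none")
    out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$sig_05 <- !is.na(out$p) & out$p <= 0.05
  out$sig_01 <- !is.na(out$p) & out$p <= 0.01
  out
}

#' Read a cohort table from TSV
#'
#' One row per patient; empty cells are missing values. Reports malformed
#' rows (non-numeric entries in numeric columns) with their line numbers.
#'
#' @param path path to a tab-separated cohort file with a header row.
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort file not found: '%s'", path),
                               call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  if (nrow(df) == 0L) stop("cohort table is empty", call. = FALSE)
  num_cols <- setdiff(names(df), "patient_id")
  for (cn in num_cols) {
    raw <- df[[cn]]
    conv <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(conv))
    if (length(bad))
      stop(sprintf("cohort column '%s' has non-numeric entries at data row(s) %s",
                   cn, paste(bad, collapse = ", ")), call. = FALSE)
    df[[cn]] <- conv
  }
  df
}
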