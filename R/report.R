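#' Reference-value summary statistics per sample set
#'
#' Per analyte and per set (total, and calibration/prediction when a split
#' is supplied): n, range, mean and sample SD of the reference
#' concentrations.
#'
#' @param reference reference `data.frame` (see [read_reference_csv()]).
#' @param split optional `split_result` whose indices refer to the rows of
#'   `reference`.
#' @return `data.frame`: `analyte`, `set`, `n`, `min`, `max`, `mean`, `sd`.
#' @export
summarize_reference <- function(reference, split = NULL) {
  reference <- validate_reference(reference)
  analytes <- setdiff(names(reference), c("sample_id", "origin"))
  sets <- list(total = seq_len(nrow(reference)))
  if (!is.null(split)) {
    stopifnot(inherits(split, "split_result"))
    if (split$n != nrow(reference))
      stop_invalid("split covers %d samples but reference has %d rows",
                   split$n, nrow(reference))
    sets$calibration <- split$calibration
    sets$prediction <- split$prediction
  }
  rows <- list()
  for (a in analytes) for (s in names(sets)) {
    v <- reference[[a]][sets[[s]]]
    if (length(v) == 0) stop_invalid("empty %s set", s)
    if (length(v) < 2) stop_invalid("SD undefined for single-sample %s set", s)
    rows[[length(rows) + 1L]] <- data.frame(
      analyte = a, set = s, n = length(v), min = min(v), max = max(v),
      mean = mean(v), sd = sd(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pooled mean of disjoint sample sets
#'
#' `sum(n * means) / sum(n)`; with exact inputs this reproduces the total
#' mean from the per-set means to machine precision, which is also the
#' consistency check tying a printed total mean to its printed subset
#' means and sizes.
#'
#' @param n set sizes.
#' @param means set means.
#' @return the pooled mean.
#' @export
pooled_mean <- function(n, means) {
  if (length(n) != length(means) || length(n) == 0)
    stop_invalid("n and means must be equal-length, nonempty")
  sum(n * means) / sum(n)
}

fmt4 <- function(x) formatC(x, format = "f", digits = 4)
fmt_pct <- function(x) formatC(x, format = "f", digits = 2)

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_invalid("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  df
}

#' Write the workflow summary tables
#'
#' Emits the four TSV tables of the workflow (display rounding only:
#' 4 decimals for metrics, 2 for percentages; computations elsewhere always
#' use unrounded values):
#' `table1_classification.tsv` (pretreatment, C, g, calibration %,
#' prediction %), `table3_reference.tsv` (reference summary statistics),
#' `table4_pretreatments.tsv` (PLS figures of merit per pretreatment and
#' analyte) and `table5_sipls.tsv` (interval-selected models).
#'
#' @param dir output directory (created if needed).
#' @param classification `data.frame` with columns `pretreatment`, `C`, `g`,
#'   `cal_accuracy`, `pred_accuracy`; or `NULL` to skip.
#' @param reference_summary output of [summarize_reference()]; or `NULL`.
#' @param pretreatments `data.frame` with columns `analyte`, `pretreatment`,
#'   `n_lv`, `r2c`, `rmsee`, `rmsecv`, `r2p`, `rmsep`, `rpd`; or `NULL`.
#' @param sipls like `pretreatments` plus `intervals` and
#'   `wavenumber_ranges` columns; or `NULL`.
#' @return invisible character vector of the files written.
#' @export
write_report_tables <- function(dir, classification = NULL,
                                reference_summary = NULL,
                                pretreatments = NULL, sipls = NULL) {
  if (is.null(classification) && is.null(reference_summary) &&
      is.null(pretreatments) && is.null(sipls))
    stop_invalid("nothing to write: all table inputs are NULL")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(classification)) {
    classification <- require_columns(classification,
      c("pretreatment", "C", "g", "cal_accuracy", "pred_accuracy"),
      "classification table")
    out <- data.frame(
      Pretreatment = classification$pretreatment,
      C = formatC(classification$C, format = "g", digits = 6),
      g = formatC(classification$g, format = "g", digits = 6),
      `Accuracy of calibration (%)` = fmt_pct(classification$cal_accuracy),
      `Accuracy of prediction (%)` = fmt_pct(classification$pred_accuracy),
      check.names = FALSE)
    tsv(out, "table1_classification.tsv")
  }
  if (!is.null(reference_summary)) {
    reference_summary <- require_columns(reference_summary,
      c("analyte", "set", "n", "min", "max", "mean", "sd"), "reference summary")
    out <- data.frame(
      Analyte = reference_summary$analyte, Set = reference_summary$set,
      n = reference_summary$n,
      `Range (mg/g)` = paste(fmt4(reference_summary$min),
                             fmt4(reference_summary$max), sep = "-"),
      Mean = fmt4(reference_summary$mean), SD = fmt4(reference_summary$sd),
      check.names = FALSE)
    tsv(out, "table3_reference.tsv")
  }
  metric_cols <- c("analyte", "pretreatment", "n_lv", "r2c", "rmsee",
                   "rmsecv", "r2p", "rmsep", "rpd")
  fmt_metrics <- function(df) data.frame(
    Compound = df$analyte, Pretreatment = df$pretreatment, LV = df$n_lv,
    R2C = fmt4(df$r2c), RMSEE = fmt4(df$rmsee), RMSECV = fmt4(df$rmsecv),
    R2P = fmt4(df$r2p), RMSEP = fmt4(df$rmsep), RPD = fmt4(df$rpd),
    check.names = FALSE)
  if (!is.null(pretreatments)) {
    pretreatments <- require_columns(pretreatments, metric_cols,
                                     "pretreatment metrics table")
    tsv(fmt_metrics(pretreatments), "table4_pretreatments.tsv")
  }
  if (!is.null(sipls)) {
    sipls <- require_columns(sipls,
      c(metric_cols, "intervals", "wavenumber_ranges"), "siPLS table")
    out <- fmt_metrics(sipls)
    out <- cbind(out[, 1:2],
                 `Spectral interval` = sipls$intervals,
                 `Wavenumber range/cm-1` = sipls$wavenumber_ranges,
                 out[, -(1:2)])
    tsv(out, "table5_sipls.tsv")
  }
  invisible(written)
}
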