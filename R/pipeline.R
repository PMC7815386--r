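#' Default configuration of the end-to-end workflow
#'
#' Collects every tunable of the pipeline in one list. The defaults are the
#' workflow's reference settings: 2:1 SPXY split, the eight standard
#' pretreatments compared for quantification, RBF-SVM grid search over
#' log2 C in [-5, 20] x log2 g in [-20, -5] at step 0.5 with 10-fold CV,
#' PLS latent-variable cap 15 selected by 7-fold RMSECV, and siPLS with 20
#' intervals, combination sizes {2, 3, 4}, 5 CV segments and LV cap 15.
#' One global seed fans out to per-stage seeds by fixed offsets, so stages
#' are individually reproducible.
#'
#' @param seed global integer seed.
#' @return nested config list.
#' @export
default_pipeline_config <- function(seed = 20210112) {
  list(
    seed = seed,
    synth = synth_config(seed = seed + 1L),
    split_ratio = 2 / 3,
    pretreatments = c("raw", "msc", "snv", "1d", "2d",
                      "msc+1d", "msc+2d", "snv+1d", "snv+2d"),
    classify = list(pretreatment = "msc+1d",
                    grid = svm_param_grid(), folds = 10, seed = seed + 3L),
    pls = list(max_lv = 15, folds = 7, seed = seed + 4L),
    sipls = list(pretreatment = "msc+1d", n_intervals = 20, k = c(2, 3, 4),
                 max_lv = 15, folds = 5, seed = seed + 5L)
  )
}

#' Run the full FT-NIR chemometrics workflow
#'
#' Chains the pipeline stages in their natural order: simulate (or accept)
#' a dataset, average replicate scans, split calibration/prediction
#' (stratified Kennard-Stone for the classification arm, SPXY on each
#' analyte for the quantification arm), compare pretreatments, grid-search
#' and evaluate the SVM origin classifier, fit and evaluate full-spectrum
#' PLS models per pretreatment and analyte, run the siPLS interval search
#' on the configured pretreatment, and assemble the summary tables.
#'
#' @param config a config list, see [default_pipeline_config()].
#' @param dataset optional list with `spectra` and `reference` (as from
#'   [generate_nir_dataset()]); by default a dataset is simulated from
#'   `config$synth`.
#' @param output_dir optional directory; when given, the summary TSV tables
#'   are written there via [write_report_tables()].
#' @param verbose print stage progress.
#' @return list with elements `dataset`, `splits`, `classification`,
#'   `pretreatment_metrics`, `sipls`, `reference_summary`, `tables`
#'   (file paths or `NULL`).
#' @export
run_nir_pipeline <- function(config = default_pipeline_config(),
                             dataset = NULL, output_dir = NULL,
                             verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(dataset)) {
    say("stage simulate: seed %d", config$synth$seed)
    dataset <- generate_nir_dataset(config$synth)
  }
  spectra <- average_replicates(dataset$spectra)
  joined <- align_spectra(spectra, dataset$reference)
  X <- joined$X
  analytes <- colnames(joined$Y)
  n <- nrow(X)
  n_cal <- round(config$split_ratio * n)

  ## classification arm -----------------------------------------------------
  say("stage split (classification): stratified KS, %d/%d", n_cal, n - n_cal)
  cls_split <- stratified_split(joined$labels, X, n_cal)
  pp <- apply_pretreatment(X[cls_split$calibration, , drop = FALSE],
                           X[cls_split$prediction, , drop = FALSE],
                           config$classify$pretreatment)
  say("stage classify: grid search, %d candidates, %d-fold CV",
      nrow(config$classify$grid), config$classify$folds)
  gs <- svm_grid_search(pp$cal, joined$labels[cls_split$calibration],
                        grid = config$classify$grid,
                        k = config$classify$folds, seed = config$classify$seed)
  model <- svm_train(pp$cal, joined$labels[cls_split$calibration],
                     gs$best$C, gs$best$g)
  classification <- data.frame(
    pretreatment = config$classify$pretreatment,
    C = gs$best$C, g = gs$best$g,
    cv_accuracy = gs$best_accuracy,
    cal_accuracy = recognition_rate(svm_predict(model, pp$cal),
                                    joined$labels[cls_split$calibration]),
    pred_accuracy = recognition_rate(svm_predict(model, pp$pred),
                                     joined$labels[cls_split$prediction]))

  ## quantification arm -----------------------------------------------------
  splits <- list(classification = cls_split)
  metrics_rows <- list()
  sipls_rows <- list()
  sipls_results <- list()
  for (a in analytes) {
    y <- joined$Y[, a]
    say("stage split (%s): SPXY, %d/%d", a, n_cal, n - n_cal)
    sp <- spxy_split(X, y, n_cal)
    splits[[a]] <- sp
    ical <- sp$calibration; ipred <- sp$prediction
    sd_all <- sd(y)
    for (pt in config$pretreatments) {
      q <- apply_pretreatment(X[ical, , drop = FALSE],
                              X[ipred, , drop = FALSE], pt)
      lv <- pls_select_lv(q$cal, y[ical], max_lv = config$pls$max_lv,
                          folds = config$pls$folds, seed = config$pls$seed)
      m <- pls_nipals(q$cal, y[ical], lv)
      em <- pls_evaluate(m, q$cal, y[ical], q$pred, y[ipred], sd_all = sd_all,
                         rmsecv = attr(lv, "rmsecv")[lv])
      metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
        analyte = a, pretreatment = pt, n_lv = em$n_lv, r2c = em$r2c,
        rmsee = em$rmsee, rmsecv = em$rmsecv, r2p = em$r2p,
        rmsep = em$rmsep, rpd = em$rpd, stringsAsFactors = FALSE)
    }
    say("stage sipls (%s): %d intervals, k in {%s}", a,
        config$sipls$n_intervals, paste(config$sipls$k, collapse = ","))
    q <- apply_pretreatment(X[ical, , drop = FALSE],
                            X[ipred, , drop = FALSE],
                            config$sipls$pretreatment)
    sr <- sipls_search(q$cal, y[ical], n_intervals = config$sipls$n_intervals,
                       k = config$sipls$k, max_lv = config$sipls$max_lv,
                       folds = config$sipls$folds, seed = config$sipls$seed,
                       wavenumbers = spectra$wavenumbers)
    rf <- sipls_refit(q$cal, y[ical], q$pred, y[ipred], sr, sd_all = sd_all)
    sipls_results[[a]] <- list(search = sr, refit = rf)
    em <- rf$metrics
    sipls_rows[[length(sipls_rows) + 1L]] <- data.frame(
      analyte = a, pretreatment = config$sipls$pretreatment,
      intervals = paste(sr$best$intervals, collapse = ", "),
      wavenumber_ranges = paste(sprintf("%.2f-%.2f", rf$intervals$wn_high,
                                        rf$intervals$wn_low), collapse = ", "),
      n_lv = em$n_lv, r2c = em$r2c, rmsee = em$rmsee, rmsecv = em$rmsecv,
      r2p = em$r2p, rmsep = em$rmsep, rpd = em$rpd, stringsAsFactors = FALSE)
  }
  pretreatment_metrics <- do.call(rbind, metrics_rows)
  sipls_table <- do.call(rbind, sipls_rows)
  reference_summary <- summarize_reference(joined$reference,
                                           splits[[analytes[1]]])
  tables <- NULL
  if (!is.null(output_dir)) {
    say("stage report: writing tables to %s", output_dir)
    tables <- write_report_tables(output_dir,
                                  classification = classification,
                                  reference_summary = reference_summary,
                                  pretreatments = pretreatment_metrics,
                                  sipls = sipls_table)
  }
  list(dataset = dataset, splits = splits, classification = classification,
       grid_search = gs, pretreatment_metrics = pretreatment_metrics,
       sipls = sipls_results, sipls_table = sipls_table,
       reference_summary = reference_summary, tables = tables)
}
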