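# ---- end-to-end orchestrated workflow -------------------------------------

#' Workflow configuration
#'
#' Bundles everything a full run needs; a run is reproducible from the config
#' plus its seed alone.
#'
#' @param sim A [sim_config()] used to generate the dataset (or NULL when
#'   `spectra_path`/`weights_path` are given).
#' @param spectra_path,weights_path Optional wide-CSV spectra and weighing
#'   record files to load instead of simulating.
#' @param preprocessing_grid Named list of preprocessor specs screened for
#'   RMSECV; `list()` skips the comparison.
#' @param max_lv Latent-variable scan range for cross validation.
#' @param raw_n_lv,emsc_n_lv,subset_n_lv Latent variables of the three PLS
#'   model configurations (NULL for `raw_n_lv` means choose by parsimony).
#' @param k_wavelengths,min_separation Wavelength-selection parameters.
#' @param outlier_alpha Hotelling screening level.
#' @param seed Integer seed.
#' @param outdir Output directory for report CSVs (NULL: nothing written).
#' @return A list of class `"workflow_config"`.
#' @export
workflow_config <- function(sim = sim_config(),
                            spectra_path = NULL, weights_path = NULL,
                            preprocessing_grid = list(),
                            max_lv = 8,
                            raw_n_lv = 3, emsc_n_lv = 4, subset_n_lv = 3,
                            k_wavelengths = 7, min_separation = 20,
                            outlier_alpha = 0.05,
                            seed = 1, outdir = NULL) {
  structure(
    list(sim = sim, spectra_path = spectra_path, weights_path = weights_path,
         preprocessing_grid = preprocessing_grid, max_lv = max_lv,
         raw_n_lv = raw_n_lv, emsc_n_lv = emsc_n_lv, subset_n_lv = subset_n_lv,
         k_wavelengths = k_wavelengths, min_separation = min_separation,
         outlier_alpha = outlier_alpha, seed = seed, outdir = outdir),
    class = "workflow_config"
  )
}

#' Run the full calibration workflow
#'
#' Orchestrates the whole pipeline deterministically from the config seed:
#' simulate (or load) spectra and weighing records; average replicates;
#' screen spectral outliers with PCA + Hotelling's T-squared and record the
#' keep/drop comparison; optionally screen a grid of pre-treatments by
#' RMSECV; fit the four model configurations (raw full-spectrum PLSR,
#' EMSC-corrected PLSR, selected-wavelength MLR, selected-wavelength PLS);
#' validate each on the held-out origins; and emit the comparison table and
#' paired prediction-error tests. All validation-set preprocessing reuses
#' calibration-fitted state.
#'
#' @param config A [workflow_config()].
#' @return A list: `data` (averaged spectra), `outliers`, `keep_drop`,
#'   `preprocessing` (NULL if the grid was empty), `selected_wavelengths`,
#'   `models`, `calibration_stats`, `reports`, `table`, `comparisons`,
#'   `log` (character vector of stage records). Written as CSVs under
#'   `config$outdir` when set.
#' @export
run_workflow <- function(config = workflow_config()) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  # ---- data ---------------------------------------------------------------
  if (!is.null(config$spectra_path)) {
    spectra <- read_spectra(config$spectra_path)
    moisture <- if (!is.null(config$weights_path)) {
      read_weighing_records(config$weights_path)
    } else NULL
    note("loaded spectra from %s (%d rows)", config$spectra_path, nrow(spectra))
  } else {
    ds <- simulate_dataset(config$sim, seed = config$seed)
    spectra <- ds$spectra
    moisture <- ds$moisture
    note("simulated dataset with seed %d (%d replicate spectra)",
         config$seed, nrow(spectra))
  }
  if (!is.null(moisture)) {
    ref <- summarize_duplicates(moisture)
    spectra$mc <- ref$mc[match(spectra$sample_id, ref$sample_id)]
  }
  avg <- average_replicates(spectra)
  note("averaged replicates: %d samples", nrow(avg))

  # ---- outlier screening on all samples -----------------------------------
  pca <- fit_pca(avg, n_pc = 2)
  outliers <- flag_outliers(pca, alpha = config$outlier_alpha)
  flagged <- outliers$sample_id[outliers$flagged]
  cal <- calibration(avg)
  val <- validation(avg)
  keep_drop <- keep_or_drop(cal, intersect(flagged, cal$sample_id),
                            n_lv = config$raw_n_lv %||% 3)
  note("outlier screening: %d flagged, recommendation %s",
       length(flagged), keep_drop$recommendation)
  # (flagged samples are retained unless the comparison recommends dropping)
  if (keep_drop$recommendation == "drop") {
    cal <- dplyr::filter(cal, !.data$sample_id %in% flagged)
    note("dropped %d flagged calibration samples", length(flagged))
  }
  y_cal <- cal$mc
  y_val <- val$mc

  # ---- pre-treatment screening --------------------------------------------
  prep <- NULL
  if (length(config$preprocessing_grid)) {
    prep <- compare_preprocessing(cal, y_cal, config$preprocessing_grid,
                                  max_lv = config$max_lv)
    note("preprocessing screen: best %s (RMSECV %.3f)",
         prep$treatment[1], prep$rmsecv[1])
  }

  # ---- model configurations -----------------------------------------------
  cv_raw <- full_cross_validation(cal, y_cal, max_lv = config$max_lv)
  n_lv_raw <- config$raw_n_lv %||% choose_n_lv(cv_raw)
  raw_pls <- fit_plsr(cal, y_cal, n_lv = n_lv_raw)

  emsc <- fit_scatter(cal, "emsc", poly_order = 2)
  cal_emsc <- predict(emsc, cal)
  val_emsc <- predict(emsc, val)
  cv_emsc <- full_cross_validation(cal_emsc, y_cal, max_lv = config$max_lv)
  emsc_pls <- fit_plsr(cal_emsc, y_cal, n_lv = config$emsc_n_lv)

  wl_sel <- select_wavelengths(raw_pls$b, spectra_wavelengths(cal),
                               k = config$k_wavelengths,
                               min_separation = config$min_separation)
  note("selected wavelengths: %s", paste(round(wl_sel), collapse = ", "))
  sub_mlr <- refit_subset(cal, y_cal, wl_sel, "mlr", tolerance = Inf)
  sub_pls <- refit_subset(cal, y_cal, wl_sel, "pls",
                          n_lv = config$subset_n_lv, tolerance = Inf)
  cal_sub <- subset_wavelengths(cal, wl_sel, tolerance = Inf)
  val_sub <- subset_wavelengths(val, wl_sel, tolerance = Inf)
  cv_sub <- full_cross_validation(cal_sub, y_cal, max_lv = config$subset_n_lv)

  models <- list(raw_plsr = raw_pls, emsc_plsr = emsc_pls,
                 subset_mlr = sub_mlr, subset_pls = sub_pls)

  cal_stats <- list(
    raw_plsr = tibble::tibble(
      n_lv = n_lv_raw, r2_cal = 1 - sum(raw_pls$residuals^2) /
        sum((y_cal - mean(y_cal))^2),
      rmsec = sqrt(mean(raw_pls$residuals^2)),
      r2_cv = cv_raw$r2_cv[n_lv_raw], rmsecv = cv_raw$rmsecv[n_lv_raw]),
    emsc_plsr = tibble::tibble(
      n_lv = config$emsc_n_lv, r2_cal = 1 - sum(emsc_pls$residuals^2) /
        sum((y_cal - mean(y_cal))^2),
      rmsec = sqrt(mean(emsc_pls$residuals^2)),
      r2_cv = cv_emsc$r2_cv[config$emsc_n_lv],
      rmsecv = cv_emsc$rmsecv[config$emsc_n_lv]),
    subset_mlr = tibble::tibble(
      n_lv = NA_integer_, r2_cal = 1 - sum(sub_mlr$residuals^2) /
        sum((y_cal - mean(y_cal))^2),
      rmsec = sqrt(mean(sub_mlr$residuals^2)),
      r2_cv = NA_real_, rmsecv = leverage_corrected_rmse(sub_mlr)),
    subset_pls = tibble::tibble(
      n_lv = config$subset_n_lv, r2_cal = 1 - sum(sub_pls$residuals^2) /
        sum((y_cal - mean(y_cal))^2),
      rmsec = sqrt(mean(sub_pls$residuals^2)),
      r2_cv = cv_sub$r2_cv[config$subset_n_lv],
      rmsecv = cv_sub$rmsecv[config$subset_n_lv])
  )

  # ---- validation ---------------------------------------------------------
  preds <- list(
    raw_plsr = predict(raw_pls, val),
    emsc_plsr = predict(emsc_pls, val_emsc),
    subset_mlr = predict(sub_mlr, val_sub),
    subset_pls = predict(sub_pls, val_sub)
  )
  reports <- purrr::map(preds, evaluate_predictions, y_ref = y_val)
  tbl <- report_table(purrr::imap(models, function(m, nm) {
    list(calibration = cal_stats[[nm]], prediction = reports[[nm]])
  }))
  resid <- purrr::map(preds, ~ .x - y_val)
  pairs <- utils::combn(names(resid), 2, simplify = FALSE)
  comparisons <- purrr::map_dfr(pairs, function(pr) {
    dplyr::mutate(compare_prediction_errors(resid[[pr[1]]], resid[[pr[2]]]),
                  model_a = pr[1], model_b = pr[2], .before = 1)
  })
  note("validation: RMSEP %s",
       paste(sprintf("%s=%.3f", names(reports),
                     purrr::map_dbl(reports, "rmsep")), collapse = ", "))

  out <- list(data = avg, outliers = outliers, keep_drop = keep_drop,
              preprocessing = prep, selected_wavelengths = wl_sel,
              models = models, calibration_stats = cal_stats,
              reports = reports, table = tbl, comparisons = comparisons,
              log = log)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(outliers, file.path(config$outdir, "outliers.csv"))
    if (!is.null(prep)) {
      readr::write_csv(prep, file.path(config$outdir, "preprocessing.csv"))
    }
    readr::write_csv(tbl, file.path(config$outdir, "model_table.csv"))
    readr::write_csv(comparisons, file.path(config$outdir, "comparisons.csv"))
    readr::write_lines(log, file.path(config$outdir, "workflow_log.txt"))
  }
  out
}
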