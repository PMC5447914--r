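# ---- uniform fit/apply interface over all pre-treatments ------------------

#' Preprocessor specifications
#'
#' A preprocessor spec is a plain named list (`method` plus method-specific
#' parameters) and therefore serialises directly to JSON/YAML config blocks.
#' `default_preprocessing_grid()` returns the full screening catalogue:
#' 3 smoothers x 5 windows, 3 Savitzky-Golay derivative configurations x 5
#' windows, 2 normalisations, 2 baseline corrections, SNV, MSC, EMSC, and
#' OSC(1).
#'
#' @return A named list of preprocessor specs.
#' @export
default_preprocessing_grid <- function() {
  grid <- list()
  for (sm in c("moving_average", "gaussian", "median")) {
    for (w in c(3, 7, 11, 15, 19)) {
      grid[[paste0(sm, "_w", w)]] <- list(method = "smooth", smoother = sm,
                                          window = w)
    }
  }
  for (dp in list(c(1, 2), c(2, 2), c(3, 3))) {
    for (w in c(3, 7, 11, 15, 19)) {
      if (w < dp[2] + 2) next  # window too small for the polynomial order
      grid[[sprintf("sg_d%dp%d_w%d", dp[1], dp[2], w)]] <-
        list(method = "sg_derivative", deriv = dp[1], poly = dp[2], window = w)
    }
  }
  grid$normalize_area <- list(method = "normalize", mode = "area")
  grid$normalize_mean <- list(method = "normalize", mode = "mean")
  grid$baseline_offset <- list(method = "baseline", mode = "offset")
  grid$baseline_linear <- list(method = "baseline", mode = "linear")
  grid$snv <- list(method = "snv")
  grid$msc <- list(method = "msc")
  grid$emsc <- list(method = "emsc", poly_order = 2)
  grid$osc <- list(method = "osc", n_components = 1)
  grid
}

#' Fit a preprocessor on calibration data
#'
#' Stateless treatments (smoothing, derivatives, normalisation, baseline,
#' SNV) have no fitted state; MSC/EMSC store the calibration reference
#' spectrum and OSC its weights/loadings. Applying a fitted preprocessor to
#' validation data therefore reuses calibration state only, which makes
#' train/validation leakage structurally impossible.
#'
#' @param spec A preprocessor spec (see [default_preprocessing_grid()]).
#' @param cal Calibration spectra tibble.
#' @param y Response vector (required for `method = "osc"`).
#' @return An object of class `"fitted_preprocessor"`.
#' @export
fit_preprocessor <- function(spec, cal, y = NULL) {
  state <- switch(spec$method,
    msc = fit_scatter(cal, "msc"),
    emsc = fit_scatter(cal, "emsc",
                       poly_order = spec$poly_order %||% 2),
    osc = {
      if (is.null(y)) abort("OSC needs the calibration response",
                            class = "nirmc_argument_error")
      fit_osc(cal, y, n_components = spec$n_components %||% 1)
    },
    NULL
  )
  structure(list(spec = spec, state = state), class = "fitted_preprocessor")
}

#' Apply a fitted preprocessor
#'
#' @param object A `"fitted_preprocessor"`.
#' @param newdata A spectra tibble.
#' @param ... Unused.
#' @return The transformed spectra tibble.
#' @export
predict.fitted_preprocessor <- function(object, newdata, ...) {
  spec <- object$spec
  switch(spec$method,
    smooth = smooth_spectra(newdata, spec$smoother, spec$window),
    sg_derivative = sg_derivative(newdata, spec$deriv, spec$poly, spec$window),
    normalize = normalize_spectra(newdata, spec$mode),
    baseline = baseline_correct(newdata, spec$mode),
    snv = snv(newdata),
    msc = ,
    emsc = ,
    osc = predict(object$state, newdata),
    abort(paste0("unknown preprocessing method: ", spec$method),
          class = "nirmc_argument_error")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen pre-treatments by cross-validated error
#'
#' Applies each preprocessor in the grid to the calibration set (fitting any
#' state on calibration data), runs leave-one-out cross validation of PLSR on
#' the treated spectra, and reports the best latent-variable count and its
#' RMSECV per treatment, plus the untreated ("raw") baseline. This reproduces
#' the screening procedure by which a pre-treatment is chosen (or, as often
#' happens, raw spectra are retained).
#'
#' @param cal Calibration spectra tibble.
#' @param y Response vector, % MC.
#' @param grid Named list of preprocessor specs; default the full catalogue.
#' @param max_lv Largest latent-variable count scanned.
#' @param lv_tolerance Parsimony tolerance passed to [choose_n_lv()].
#' @return A tibble sorted by RMSECV: `treatment`, `n_lv`, `rmsecv`, `r2_cv`.
#' @export
compare_preprocessing <- function(cal, y, grid = default_preprocessing_grid(),
                                  max_lv = 8, lv_tolerance = 0.05) {
  eval_one <- function(set) {
    curve <- full_cross_validation(set, y, max_lv = max_lv)
    L <- choose_n_lv(curve, lv_tolerance)
    tibble::tibble(n_lv = L, rmsecv = curve$rmsecv[L], r2_cv = curve$r2_cv[L])
  }
  rows <- c(list(raw = eval_one(cal)),
            purrr::imap(grid, function(spec, nm) {
              fp <- fit_preprocessor(spec, cal, y)
              eval_one(predict(fp, cal))
            }))
  dplyr::bind_rows(rows, .id = "treatment") |>
    dplyr::arrange(.data$rmsecv)
}
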