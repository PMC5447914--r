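# ---- broom-style tidiers --------------------------------------------------

#' Tidy a PLS model
#'
#' @param x A `"pls_model"`.
#' @param ... Unused.
#' @return A tibble with one row per wavelength: `wavelength`, `coefficient`.
#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(wavelength = x$wavelengths, coefficient = x$b)
}

#' @rdname tidy.pls_model
#' @export
glance.pls_model <- function(x, ...) {
  y <- x$fitted + x$residuals
  tibble::tibble(
    n = x$n, n_lv = x$n_lv,
    r2_cal = 1 - sum(x$residuals^2) / sum((y - mean(y))^2),
    rmsec = sqrt(mean(x$residuals^2))
  )
}

#' Tidy an MLR model
#'
#' @param x A `"mlr_model"`.
#' @param ... Unused.
#' @return A tibble with the intercept row followed by one row per
#'   wavelength: `term`, `wavelength`, `estimate`.
#' @export
tidy.mlr_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", paste0("wl_", x$wavelengths)),
    wavelength = c(NA_real_, x$wavelengths),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @rdname tidy.mlr_model
#' @export
glance.mlr_model <- function(x, ...) {
  y <- x$fitted + x$residuals
  tibble::tibble(
    n = x$n, n_predictors = length(x$coefficients),
    r2_cal = 1 - sum(x$residuals^2) / sum((y - mean(y))^2),
    rmsec = sqrt(mean(x$residuals^2)),
    rmse_leverage = leverage_corrected_rmse(x)
  )
}

#' Tidy a PCA model
#'
#' @param x A `"nir_pca"`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `eigenvalue`,
#'   `var_fraction`.
#' @export
tidy.nir_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 var_fraction = x$var_fraction)
}
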