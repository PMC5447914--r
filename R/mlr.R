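# ---- full-rank MLR on selected wavelengths --------------------------------

#' Fit a multiple linear regression on selected wavelengths
#'
#' Ordinary least squares with intercept on a small set of wavelength
#' intensities (the "full rank MLR" step after wavelength selection). The
#' design must be full rank; aliased columns are reported by name.
#'
#' @param x Spectra tibble or numeric matrix of predictor intensities.
#' @param y Response vector, % MC.
#' @return An object of class `"mlr_model"`: `intercept`, `coefficients`
#'   (one per predictor), `wavelengths`, `fitted`, `residuals`, `leverage`
#'   (hat-matrix diagonals), `n`.
#' @export
fit_mlr <- function(x, y) {
  X <- as_x_matrix(x)
  n <- nrow(X)
  p <- ncol(X)
  if (n != length(y)) abort("rows of x must match length of y",
                            class = "nirmc_shape_error")
  if (n < p + 1) abort("need more samples than predictors (plus intercept)",
                       class = "nirmc_argument_error")
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort(paste0("rank-deficient design; dependent column(s): ",
                 paste(aliased, collapse = ", ")),
          class = "nirmc_collinearity_error")
  }
  coefs <- qr.coef(qrd, y)
  fitted <- as.numeric(design %*% coefs)
  Q <- qr.Q(qrd)
  leverage <- rowSums(Q^2)
  structure(
    list(intercept = unname(coefs[1]), coefficients = coefs[-1],
         wavelengths = suppressWarnings(as.numeric(colnames(X))),
         fitted = fitted, residuals = y - fitted,
         leverage = leverage, n = n),
    class = "mlr_model"
  )
}

#' Predict from a fitted MLR model
#'
#' @param object A `"mlr_model"`.
#' @param newdata Spectra tibble or matrix with the fitted predictors.
#' @param ... Unused.
#' @return Numeric vector of predicted MC, % wet basis.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  X <- as_x_matrix(newdata)
  if (ncol(X) != length(object$coefficients)) {
    abort("column count does not match the fitted model",
          class = "nirmc_shape_error")
  }
  object$intercept + as.numeric(X %*% object$coefficients)
}

#' Leverage-corrected calibration error
#'
#' Estimates a validation-like error from calibration residuals alone:
#' `sqrt(mean((e_i / (1 - h_i))^2))`, with `h_i` the hat-matrix diagonals.
#' For OLS, `e_i / (1 - h_i)` is exactly the leave-one-out residual (the
#' PRESS identity), so this equals the LOO RMSECV without refitting.
#'
#' @param model A fitted `"mlr_model"`.
#' @return The leverage-corrected RMSE, % MC.
#' @export
leverage_corrected_rmse <- function(model) {
  h <- model$leverage
  if (any(h >= 1 - 1e-12)) {
    abort("leverage of 1: saturated fit, corrected error undefined",
          class = "nirmc_leverage_error")
  }
  sqrt(mean((model$residuals / (1 - h))^2))
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("MLR (OLS with intercept):", x$n, "samples,",
      length(x$coefficients), "predictors\n")
  cat("RMSEC:", sprintf("%.4f", sqrt(mean(x$residuals^2))), "% MC\n")
  invisible(x)
}
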