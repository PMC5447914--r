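# ---- wavelength selection and the published 7-wavelength model ------------

#' Select informative wavelengths from PLS regression coefficients
#'
#' Operationalises coefficient-based selection: find local maxima of `|b|`
#' and greedily keep the `k` largest subject to a minimum pairwise wavelength
#' separation. Ties are broken toward the lower wavelength, which makes the
#' selection a deterministic surrogate for visual peak picking on the
#' coefficient trace.
#'
#' @param b Regression coefficient vector (one per grid point).
#' @param wavelengths The wavelength grid, nm (same length as `b`).
#' @param k Number of wavelengths to select (default 7).
#' @param min_separation Minimum pairwise separation between selected
#'   wavelengths, nm (default 20).
#' @return Numeric vector of `k` selected wavelengths, sorted ascending.
#' @export
select_wavelengths <- function(b, wavelengths, k = 7, min_separation = 20) {
  if (length(b) != length(wavelengths)) {
    abort("b and wavelengths must have equal length", class = "nirmc_shape_error")
  }
  if (k < 1) abort("k must be >= 1", class = "nirmc_argument_error")
  ab <- abs(b)
  p <- length(ab)
  left <- c(-Inf, ab[-p])
  right <- c(ab[-1], -Inf)
  is_peak <- ab >= left & ab >= right & ab > 0
  cand <- which(is_peak)
  # largest |b| first; ties toward lower wavelength
  cand <- cand[order(-ab[cand], wavelengths[cand])]
  kept <- numeric(0)
  for (i in cand) {
    if (all(abs(wavelengths[i] - kept) >= min_separation)) {
      kept <- c(kept, wavelengths[i])
      if (length(kept) == k) break
    }
  }
  if (length(kept) < k) {
    abort(sprintf("only %d admissible peak(s) found, %d requested",
                  length(kept), k),
          class = "nirmc_selection_error")
  }
  sort(kept)
}

#' The published seven-wavelength moisture model
#'
#' The moisture predictor reported for intact green coffee beans: an affine
#' model in the log(1/R) intensities at seven selected wavelengths. Constants
#' are immutable, exactly as printed.
#'
#' @return A tibble with columns `wavelength` (nm) and `coefficient`
#'   (% MC per absorbance unit), with attribute `intercept` (-4.20 % MC).
#' @export
#' @examples
#' published_moisture_model()
published_moisture_model <- function() {
  out <- tibble::tibble(
    wavelength = c(1155, 1212, 1340, 1409, 1724, 1908, 2249),
    coefficient = c(115.02, 0.40, -116.18, 76.16, -97.72, 63.76, -17.59)
  )
  attr(out, "intercept") <- -4.20
  out
}

#' Predict moisture with the published model
#'
#' Evaluates the published affine predictor at seven log(1/R) intensities
#' given in wavelength order (1155, 1212, 1340, 1409, 1724, 1908, 2249 nm).
#' No clipping is applied.
#'
#' @param v Numeric vector of exactly 7 finite intensities, or a matrix with
#'   7 columns (one prediction per row).
#' @return Predicted MC, % wet basis.
#' @export
#' @examples
#' published_predict(rep(0, 7))   # the intercept, -4.20
published_predict <- function(v) {
  pm <- published_moisture_model()
  m <- rbind(v)
  if (ncol(m) != 7 || !all(is.finite(m))) {
    abort("need exactly 7 finite intensities per prediction",
          class = "nirmc_argument_error")
  }
  out <- attr(pm, "intercept") + as.numeric(m %*% pm$coefficient)
  if (is.null(dim(v)) && length(v) == 7) out[1] else out
}

#' Refit a calibration model on a wavelength subset
#'
#' Extracts the nearest grid columns to the requested wavelengths (see
#' [subset_wavelengths()]) and fits either a full-rank MLR or a PLS model on
#' them, recording the wavelength list in the model.
#'
#' @param cal Calibration spectra tibble.
#' @param y Response vector, % MC.
#' @param wavelengths Target wavelengths, nm.
#' @param method `"mlr"` or `"pls"`.
#' @param n_lv Latent variables for `method = "pls"` (<= number of
#'   wavelengths); default 3.
#' @param tolerance Wavelength matching tolerance, nm.
#' @return A `"mlr_model"` or `"pls_model"` fitted on the subset.
#' @export
refit_subset <- function(cal, y, wavelengths, method = c("mlr", "pls"),
                         n_lv = 3, tolerance = 2) {
  method <- match.arg(method)
  if (length(wavelengths) == 0) {
    abort("empty wavelength list", class = "nirmc_argument_error")
  }
  sub <- subset_wavelengths(cal, wavelengths, tolerance = tolerance)
  if (method == "pls" && n_lv > length(wavelengths)) {
    abort("n_lv cannot exceed the number of selected wavelengths",
          class = "nirmc_argument_error")
  }
  fit <- switch(method,
    mlr = fit_mlr(sub, y),
    pls = fit_plsr(sub, y, n_lv = n_lv)
  )
  fit$wavelengths <- spectra_wavelengths(sub)
  fit
}
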