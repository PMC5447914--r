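# ---- stateless spectral pre-treatments ------------------------------------
# All operate row-wise on a spectra tibble and return one of the same shape.
# Windowed filters use reflection padding so output length equals input
# length without edge bias.

reflect_pad <- function(v, k) {
  p <- length(v)
  if (k == 0) return(v)
  c(v[(k + 1):2], v, v[(p - 1):(p - k)])
}

check_window <- function(window, p) {
  if (window %% 2 == 0 || window < 3) {
    abort("window must be an odd integer >= 3", class = "nirmc_argument_error")
  }
  if (window > p) {
    abort("window exceeds spectrum length", class = "nirmc_argument_error")
  }
}

#' Smooth spectra
#'
#' Moving-average, Gaussian, or running-median smoothing with reflection
#' padding at the edges. The Gaussian kernel uses `sigma = window / 4`,
#' truncated to the window.
#'
#' @param x A spectra tibble.
#' @param method `"moving_average"`, `"gaussian"`, or `"median"`.
#' @param window Odd window size >= 3 (the screening grid uses
#'   3, 7, 11, 15, 19).
#' @return A spectra tibble on the same grid.
#' @export
smooth_spectra <- function(x, method = c("moving_average", "gaussian", "median"),
                           window = 7) {
  method <- match.arg(method)
  m <- spectra_matrix(x)
  check_window(window, ncol(m))
  k <- (window - 1) / 2
  kern <- switch(method,
    moving_average = rep(1 / window, window),
    gaussian = {
      w <- dnorm(seq(-k, k), sd = window / 4)
      w / sum(w)
    },
    median = NULL
  )
  out <- t(apply(m, 1, function(v) {
    vp <- reflect_pad(v, k)
    if (is.null(kern)) {
      vapply(seq_along(v), function(i) median(vp[i:(i + window - 1)]), 0)
    } else {
      as.numeric(stats::filter(vp, kern, sides = 2))[(k + 1):(k + length(v))]
    }
  }))
  set_spectra_matrix(x, out)
}

#' Savitzky-Golay derivative
#'
#' Least-squares polynomial convolution filter; the derivative is taken with
#' respect to grid index (unit spacing), since the default grid is non-uniform
#' in nm. Edges are handled by reflection padding. The screening grid uses the
#' (derivative, polynomial) pairs (1,2), (2,2), (3,3) at windows 3, 7, 11,
#' 15, 19.
#'
#' @param x A spectra tibble.
#' @param deriv Derivative order (<= `poly`).
#' @param poly Polynomial order of the local fit.
#' @param window Odd window size >= `poly + 2`.
#' @return A spectra tibble on the same grid.
#' @export
sg_derivative <- function(x, deriv = 1, poly = 2, window = 11) {
  if (deriv > poly) {
    abort("derivative order cannot exceed polynomial order",
          class = "nirmc_argument_error")
  }
  m <- spectra_matrix(x)
  check_window(window, ncol(m))
  if (window < poly + 2) {
    abort("window must be at least poly + 2", class = "nirmc_argument_error")
  }
  k <- (window - 1) / 2
  # central-row filter coefficients of the least-squares polynomial fit
  F <- signal::sgolay(p = poly, n = window, m = deriv)
  kern <- F[k + 1, ]
  out <- t(apply(m, 1, function(v) {
    vp <- reflect_pad(v, k)
    vapply(seq_along(v), function(i) sum(kern * vp[i:(i + window - 1)]), 0)
  }))
  set_spectra_matrix(x, out)
}

#' Normalise spectra
#'
#' `mean` mode divides each spectrum by its mean (output mean 1). `area` mode
#' divides by the total absolute area, computed as `sum(|v_i| * delta_i)` with
#' `delta_i` the local grid spacing (endpoint spacings at the edges); on a
#' unit-spaced grid this is the sum of absolute values.
#'
#' @param x A spectra tibble.
#' @param mode `"area"` or `"mean"`.
#' @return A spectra tibble on the same grid.
#' @export
normalize_spectra <- function(x, mode = c("area", "mean")) {
  mode <- match.arg(mode)
  m <- spectra_matrix(x)
  wl <- spectra_wavelengths(x)
  p <- length(wl)
  delta <- c(wl[2] - wl[1],
             if (p > 2) (wl[3:p] - wl[1:(p - 2)]) / 2,
             wl[p] - wl[p - 1])
  denom <- switch(mode,
    mean = rowMeans(m),
    area = as.numeric(abs(m) %*% delta)
  )
  if (any(abs(denom) < 1e-12)) {
    abort("degenerate spectrum: zero normalisation denominator",
          class = "nirmc_degenerate_error")
  }
  set_spectra_matrix(x, m / denom)
}

#' Baseline correction
#'
#' `offset` subtracts each spectrum's minimum (new minimum 0); `linear`
#' subtracts the least-squares straight line in wavelength fitted over the
#' full spectrum.
#'
#' @param x A spectra tibble.
#' @param mode `"offset"` or `"linear"`.
#' @return A spectra tibble on the same grid.
#' @export
baseline_correct <- function(x, mode = c("offset", "linear")) {
  mode <- match.arg(mode)
  m <- spectra_matrix(x)
  if (mode == "offset") {
    return(set_spectra_matrix(x, m - apply(m, 1, min)))
  }
  if (ncol(m) < 2) {
    abort("linear baseline needs at least 2 points",
          class = "nirmc_argument_error")
  }
  wl <- spectra_wavelengths(x)
  Z <- cbind(1, wl)
  # residual-maker applied to each row: v - Z (Z'Z)^-1 Z' v
  coefs <- solve(crossprod(Z), crossprod(Z, t(m)))
  set_spectra_matrix(x, m - t(Z %*% coefs))
}

#' Standard normal variate
#'
#' Per-spectrum centering and scaling to unit SD (n-1 denominator); a
#' standard scatter treatment that removes per-spectrum offset and
#' multiplicative effects.
#'
#' @param x A spectra tibble.
#' @return A spectra tibble; each row has mean 0 and SD 1.
#' @export
snv <- function(x) {
  m <- spectra_matrix(x)
  s <- apply(m, 1, sd)
  if (any(s < 1e-12)) {
    abort("degenerate (constant) spectrum: SNV undefined",
          class = "nirmc_degenerate_error")
  }
  set_spectra_matrix(x, (m - rowMeans(m)) / s)
}
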