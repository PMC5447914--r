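# ---- fitted scatter corrections (MSC / EMSC) and OSC ----------------------
# These are fit-on-calibration / apply-to-any-set transformers: the fitted
# state (reference spectrum, OSC weights) comes from calibration data only
# and is reused unchanged on validation data.

# wavelengths affinely mapped to [-1, 1] for a well-conditioned polynomial basis
lambda_tilde <- function(wl) {
  2 * (wl - min(wl)) / (max(wl) - min(wl)) - 1
}

poly_basis <- function(wl, order) {
  lt <- lambda_tilde(wl)
  if (order == 0) return(NULL)
  vapply(seq_len(order), function(j) lt^j, numeric(length(wl)))
}

#' Fit a multiplicative scatter correction (MSC / EMSC)
#'
#' Fits the correction on calibration spectra and stores the reference
#' spectrum (by default their mean). Applying the correction regresses each
#' spectrum `x` on `a*1 + b*ref + c_1*lt + ... + c_p*lt^p` (with `lt` the
#' wavelength mapped affinely to `[-1, 1]`) by least squares and returns
#' `(x - a - sum_i c_i lt^i) / b`. `poly_order = 0` is classical MSC;
#' EMSC adds the polynomial baseline terms (default order 2).
#'
#' @param cal Calibration spectra tibble (>= 2 rows).
#' @param method `"msc"` or `"emsc"`.
#' @param poly_order Baseline polynomial order: 0 for MSC, 1 or 2 for EMSC.
#' @param reference Optional explicit reference spectrum (numeric vector on
#'   the same grid); defaults to the calibration mean spectrum.
#' @return An object of class `"scatter_correction"`; apply it with
#'   [predict.scatter_correction()].
#' @export
fit_scatter <- function(cal, method = c("msc", "emsc"), poly_order = NULL,
                        reference = NULL) {
  method <- match.arg(method)
  if (is.null(poly_order)) poly_order <- if (method == "msc") 0L else 2L
  if (method == "msc" && poly_order != 0) {
    abort("MSC has no polynomial terms; use method = 'emsc'",
          class = "nirmc_argument_error")
  }
  if (!poly_order %in% 0:2) {
    abort("poly_order must be 0, 1, or 2", class = "nirmc_argument_error")
  }
  m <- spectra_matrix(cal)
  if (nrow(m) < 2 && is.null(reference)) {
    abort("need >= 2 calibration spectra to form a reference",
          class = "nirmc_argument_error")
  }
  wl <- spectra_wavelengths(cal)
  ref <- if (is.null(reference)) colMeans(m) else as.numeric(reference)
  if (length(ref) != length(wl)) {
    abort("reference length must match the grid", class = "nirmc_shape_error")
  }
  structure(
    list(method = method, poly_order = poly_order,
         reference = ref, wavelengths = wl),
    class = "scatter_correction"
  )
}

#' Apply a fitted scatter correction
#'
#' @param object A fitted `"scatter_correction"`.
#' @param newdata A spectra tibble on the same grid.
#' @param ... Unused.
#' @return The corrected spectra tibble.
#' @export
predict.scatter_correction <- function(object, newdata, ...) {
  m <- spectra_matrix(newdata)
  wl <- spectra_wavelengths(newdata)
  if (!isTRUE(all.equal(wl, object$wavelengths))) {
    abort("new data is not on the grid the correction was fitted on",
          class = "nirmc_grid_error")
  }
  Z <- cbind(`(offset)` = 1, ref = object$reference,
             poly_basis(wl, object$poly_order))
  ZtZ <- crossprod(Z)
  coefs <- solve(ZtZ, crossprod(Z, t(m)))  # (2 + order) x n
  b <- coefs["ref", ]
  if (any(abs(b) < 1e-8)) {
    abort("degenerate scatter fit: multiplicative coefficient ~ 0",
          class = "nirmc_degenerate_error")
  }
  baseline <- Z[, -2, drop = FALSE] %*% coefs[-2, , drop = FALSE]
  corrected <- (t(m) - baseline) / rep(b, each = length(wl))
  set_spectra_matrix(newdata, t(corrected))
}

#' Fit orthogonal signal correction (OSC)
#'
#' Removes from the spectra, before calibration, the dominant variation that
#' is orthogonal to the response. Per component, a NIPALS-style iteration
#' finds a score vector orthogonalised against `y`, a weight vector `w` that
#' reproduces it from the spectra, and a loading `p`; `t p'` is subtracted
#' from the centered spectra. The stored weights reproduce the deflation on
#' new data.
#'
#' @param cal Calibration spectra tibble (>= 3 rows).
#' @param y Response vector (moisture content, % MC), one value per row.
#' @param n_components Number of OSC components to remove (0 = identity;
#'   the screening grid uses 1).
#' @param max_iter,tol NIPALS iteration controls.
#' @return An object of class `"osc_correction"`; apply it with
#'   [predict.osc_correction()].
#' @export
fit_osc <- function(cal, y, n_components = 1, max_iter = 500, tol = 1e-10) {
  m <- spectra_matrix(cal)
  if (nrow(m) != length(y) || nrow(m) < 3) {
    abort("need >= 3 rows and one y per row", class = "nirmc_argument_error")
  }
  if (n_components < 0) {
    abort("n_components must be >= 0", class = "nirmc_argument_error")
  }
  if (n_components >= min(dim(m)) ) {
    abort("n_components must be below the rank of the spectra matrix",
          class = "nirmc_rank_error")
  }
  x_mean <- colMeans(m)
  X <- sweep(m, 2, x_mean)
  y0 <- y - mean(y)
  W <- P <- NULL
  for (k in seq_len(n_components)) {
    # minimum-norm pseudoinverse of the (deflated) spectra matrix
    sv <- svd(X)
    keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    if (!any(keep)) {
      abort("spectra matrix has no remaining variation",
            class = "nirmc_rank_error")
    }
    pinv <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
    # start from the first principal component score of the deflated X
    t_vec <- X %*% sv$v[, 1]
    w <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # orthogonalise the score against the response
      t_orth <- t_vec - y0 * as.numeric(crossprod(y0, t_vec) / crossprod(y0))
      # weights whose score Xw best reproduces the orthogonalised score;
      # with more wavelengths than samples the reproduction is exact, so the
      # removed score is exactly orthogonal to y
      w_new <- pinv %*% t_orth
      t_new <- X %*% w_new
      delta <- if (is.null(w)) Inf else {
        sqrt(sum((w_new - w)^2)) / max(sqrt(sum(w_new^2)), 1e-300)
      }
      w <- w_new
      t_vec <- t_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      abort("OSC NIPALS iteration did not converge", class = "nirmc_numeric_error")
    }
    # final orthogonalisation: the removed score is exactly orthogonal to y
    # (a no-op when there are more wavelengths than samples, since Xw then
    # reproduces the orthogonalised score exactly)
    t_vec <- t_vec - y0 * as.numeric(crossprod(y0, t_vec) / crossprod(y0))
    p <- crossprod(X, t_vec) / as.numeric(crossprod(t_vec))
    X <- X - t_vec %*% t(p)
    W <- cbind(W, w)
    P <- cbind(P, p)
  }
  structure(
    list(x_mean = x_mean, weights = W, loadings = P,
         n_components = n_components, wavelengths = spectra_wavelengths(cal)),
    class = "osc_correction"
  )
}

#' Apply a fitted OSC correction
#'
#' @param object A fitted `"osc_correction"`.
#' @param newdata A spectra tibble on the same grid.
#' @param ... Unused.
#' @return The deflated spectra tibble (centering is restored, so downstream
#'   mean-centered models see the correction only through the removed
#'   structure).
#' @export
predict.osc_correction <- function(object, newdata, ...) {
  m <- spectra_matrix(newdata)
  if (!isTRUE(all.equal(spectra_wavelengths(newdata), object$wavelengths))) {
    abort("new data is not on the grid the correction was fitted on",
          class = "nirmc_grid_error")
  }
  X <- sweep(m, 2, object$x_mean)
  if (object$n_components > 0) {
    scores <- X %*% object$weights
    X <- X - scores %*% t(object$loadings)
  }
  set_spectra_matrix(newdata, sweep(X, 2, object$x_mean, `+`))
}
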