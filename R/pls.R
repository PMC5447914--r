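# ---- NIPALS PLSR and leave-one-out cross validation -----------------------

# accept either a spectra tibble or a bare numeric matrix
as_x_matrix <- function(x) {
  if (is.data.frame(x) && all(META_COLS %in% names(x))) return(spectra_matrix(x))
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Fit a PLS regression by NIPALS
#'
#' Univariate partial least squares regression on mean-centered spectra:
#' each latent variable's weight vector maximises covariance between the
#' (deflated) spectra and the response, scores and loadings are extracted and
#' both blocks deflated. With a single response the NIPALS weight step is
#' closed-form, so no inner iteration is needed. No variable scaling is
#' applied anywhere: spectra are mean-centered only, so raw and "weighted"
#' regression coefficients coincide.
#'
#' @param x Calibration spectra (spectra tibble or numeric matrix).
#' @param y Response (moisture content, % MC), one value per row.
#' @param n_lv Number of latent variables (>= 1).
#' @return An object of class `"pls_model"`: centering vectors, weights `W`,
#'   x-loadings `P`, y-loadings `q`, scores `T`, the regression coefficient
#'   vector `b` on the centered scale, `fitted`, and bookkeeping fields.
#' @export
fit_plsr <- function(x, y, n_lv = 3) {
  X <- as_x_matrix(x)
  wl <- suppressWarnings(as.numeric(colnames(X)))
  n <- nrow(X)
  p <- ncol(X)
  if (n != length(y)) abort("rows of x must match length of y",
                            class = "nirmc_shape_error")
  if (n_lv < 1) abort("n_lv must be >= 1", class = "nirmc_argument_error")
  if (n < n_lv + 2) abort("need at least n_lv + 2 samples",
                          class = "nirmc_argument_error")
  if (sd(y) < 1e-12) abort("response has zero variance",
                           class = "nirmc_degenerate_target_error")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  Xd <- Xc
  yd <- yc
  for (k in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(Xc^2)))) {
      abort(sprintf("x/y covariance exhausted at latent variable %d (rank)", k),
            class = "nirmc_rank_error")
    }
    w <- w / nw
    t_vec <- Xd %*% w
    tt <- as.numeric(crossprod(t_vec))
    if (tt < 1e-20) {
      abort(sprintf("degenerate score at latent variable %d (rank)", k),
            class = "nirmc_rank_error")
    }
    p_vec <- crossprod(Xd, t_vec) / tt
    q[k] <- as.numeric(crossprod(yd, t_vec)) / tt
    Xd <- Xd - t_vec %*% t(p_vec)
    yd <- yd - q[k] * t_vec
    W[, k] <- w
    P[, k] <- p_vec
    Tm[, k] <- t_vec
  }
  b <- as.numeric(W %*% solve(crossprod(P, W), q))
  fitted <- as.numeric(Xc %*% b) + y_mean
  structure(
    list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, q = q,
         scores = Tm, b = b, n_lv = n_lv, fitted = fitted,
         residuals = y - fitted, wavelengths = wl, n = n),
    class = "pls_model"
  )
}

#' Predict from a fitted PLS model
#'
#' @param object A `"pls_model"`.
#' @param newdata Spectra tibble or matrix with the columns the model was
#'   fitted on.
#' @param ... Unused.
#' @return Numeric vector of predicted MC, % wet basis (no clipping).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as_x_matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    abort("column count does not match the fitted model",
          class = "nirmc_shape_error")
  }
  as.numeric(sweep(X, 2, object$x_mean) %*% object$b) + object$y_mean
}

#' Leave-one-out cross validation of PLSR
#'
#' "Full cross validation" in the chemometric sense: each sample is held out
#' in turn, the PLS model refitted from scratch on the remainder (including
#' re-centering), and the held-out sample predicted, for every latent
#' variable count up to `max_lv`.
#'
#' @param x Calibration spectra (tibble or matrix).
#' @param y Response vector, % MC.
#' @param max_lv Largest latent-variable count to evaluate.
#' @return A tibble of class `"cv_curve"` with columns `n_lv`, `rmsecv`,
#'   `r2_cv`, and attribute `n`.
#' @export
full_cross_validation <- function(x, y, max_lv = 10) {
  X <- as_x_matrix(x)
  n <- nrow(X)
  if (n < max_lv + 2) abort("max_lv too large for the sample count",
                            class = "nirmc_rank_error")
  pred <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    fit <- fit_plsr(X[-i, , drop = FALSE], y[-i], n_lv = max_lv)
    xc <- X[i, ] - fit$x_mean
    # predictions at every LV count from one max_lv fit: b_L uses the first
    # L columns of W, P, q
    for (L in seq_len(max_lv)) {
      bL <- fit$W[, 1:L, drop = FALSE] %*%
        solve(crossprod(fit$P[, 1:L, drop = FALSE],
                        fit$W[, 1:L, drop = FALSE]), fit$q[1:L])
      pred[i, L] <- sum(xc * bL) + fit$y_mean
    }
  }
  sst <- sum((y - mean(y))^2)
  out <- tibble::tibble(
    n_lv = seq_len(max_lv),
    rmsecv = sqrt(colMeans((pred - y)^2)),
    r2_cv = 1 - colSums((pred - y)^2) / sst
  )
  attr(out, "n") <- n
  class(out) <- c("cv_curve", class(out))
  out
}

#' Choose the number of latent variables from a CV curve
#'
#' Parsimony rule: the smallest latent-variable count whose RMSECV is within
#' `tolerance` (relative) of the curve minimum — fewer latent variables mean
#' less risk of overfitting.
#'
#' @param curve A [full_cross_validation()] result (or anything with `n_lv`
#'   and `rmsecv` columns).
#' @param tolerance Relative slack above the minimum RMSECV; default 0.05.
#' @return The chosen latent-variable count (integer).
#' @export
choose_n_lv <- function(curve, tolerance = 0.05) {
  if (is.null(curve) || nrow(curve) == 0) {
    abort("empty CV curve", class = "nirmc_argument_error")
  }
  ok <- curve$rmsecv <= (1 + tolerance) * min(curve$rmsecv)
  as.integer(curve$n_lv[which(ok)[1]])
}

#' @export
print.pls_model <- function(x, ...) {
  cat("NIPALS PLS regression:", x$n, "samples,", length(x$b), "wavelengths,",
      x$n_lv, "latent variables\n")
  cat("RMSEC:", sprintf("%.4f", sqrt(mean(x$residuals^2))), "% MC\n")
  invisible(x)
}
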