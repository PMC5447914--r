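# ---- PCA + Hotelling's T^2 outlier screening ------------------------------

#' Principal component analysis of spectra (NIPALS)
#'
#' Mean-centered PCA computed by the NIPALS iteration, the workhorse
#' decomposition of chemometrics: components are extracted one at a time and
#' the matrix deflated, so only the few components needed for screening are
#' computed.
#'
#' @param x A spectra tibble (>= 2 rows).
#' @param n_pc Number of components, `<= min(rows - 1, columns)`.
#' @param max_iter,tol NIPALS iteration controls.
#' @return An object of class `"nir_pca"` with elements `mean`, `loadings`
#'   (orthonormal columns), `scores`, `eigenvalues` (score variances, n-1
#'   denominator), `var_fraction`, `total_var`, and `sample_id`.
#' @export
fit_pca <- function(x, n_pc = 2, max_iter = 500, tol = 1e-12) {
  m <- spectra_matrix(x)
  n <- nrow(m)
  if (n < 2) abort("need >= 2 rows", class = "nirmc_argument_error")
  if (n_pc < 1 || n_pc > min(n - 1, ncol(m))) {
    abort("n_pc must be in 1..min(rows - 1, columns)",
          class = "nirmc_argument_error")
  }
  mu <- colMeans(m)
  X <- sweep(m, 2, mu)
  total_var <- sum(X^2) / (n - 1)
  scores <- matrix(0, n, n_pc)
  loadings <- matrix(0, ncol(m), n_pc)
  for (k in seq_len(n_pc)) {
    t_vec <- X[, which.max(colSums(X^2))]
    for (it in seq_len(max_iter)) {
      p <- crossprod(X, t_vec) / as.numeric(crossprod(t_vec))
      p <- p / sqrt(sum(p^2))
      t_new <- X %*% p
      if (sqrt(sum((t_new - t_vec)^2)) <= tol * sqrt(sum(t_new^2))) {
        t_vec <- t_new
        break
      }
      t_vec <- t_new
    }
    scores[, k] <- t_vec
    loadings[, k] <- p
    X <- X - t_vec %*% t(p)
  }
  ev <- colSums(scores^2) / (n - 1)
  structure(
    list(mean = mu, loadings = loadings, scores = scores,
         eigenvalues = ev, var_fraction = ev / total_var,
         total_var = total_var, residual_var = sum(X^2) / (n - 1),
         sample_id = x$sample_id, n = n,
         wavelengths = spectra_wavelengths(x)),
    class = "nir_pca"
  )
}

#' Hotelling's T-squared control limit
#'
#' The F-distribution based critical value for the T-squared of PCA scores:
#' `p (n - 1) / (n - p) * F_{1 - alpha}(p, n - p)` with `p = n_pc`. With
#' `n_pc = 2` this is the radius of the "5% ellipse" drawn on score plots.
#'
#' @param n Number of samples the PCA was fitted on.
#' @param n_pc Number of retained components (`< n`).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return The T-squared threshold.
#' @export
hotelling_limit <- function(n, n_pc, alpha = 0.05) {
  if (n <= n_pc || n_pc < 1) {
    abort("need n > n_pc >= 1", class = "nirmc_argument_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)", class = "nirmc_argument_error")
  }
  n_pc * (n - 1) / (n - n_pc) * qf(1 - alpha, n_pc, n - n_pc)
}

#' Flag samples outside the Hotelling ellipse
#'
#' Each sample's T-squared is the sum of its squared scores scaled by the
#' component variances over the retained components; samples whose T-squared
#' exceeds [hotelling_limit()] are flagged as suspected spectral outliers.
#'
#' @param model A fitted [fit_pca()] model.
#' @param alpha Significance level; default 0.05 (the 5% ellipse).
#' @return A tibble ordered by descending T-squared with columns `sample_id`,
#'   `t2`, `threshold`, `flagged`.
#' @export
flag_outliers <- function(model, alpha = 0.05) {
  if (any(model$eigenvalues <= 1e-12 * max(model$eigenvalues, 1e-300))) {
    abort("degenerate (zero-variance) retained component",
          class = "nirmc_degenerate_error")
  }
  t2 <- as.numeric((model$scores^2) %*% (1 / model$eigenvalues))
  lim <- hotelling_limit(model$n, ncol(model$scores), alpha)
  tibble::tibble(sample_id = model$sample_id, t2 = t2,
                 threshold = lim, flagged = t2 > lim) |>
    dplyr::arrange(dplyr::desc(.data$t2))
}

#' Compare calibration with and without suspected outliers
#'
#' Reproduces the screening decision step: fit the calibration model with and
#' without the flagged samples and compare cross-validated performance. The
#' flagged samples are kept unless dropping them improves RMSECV by more than
#' a relative threshold.
#'
#' @param cal Calibration spectra tibble; its `mc` column is the response.
#' @param flagged Character vector of suspected `sample_id`s (subset of
#'   `cal$sample_id`).
#' @param n_lv Latent variables for the PLSR fits.
#' @param rel_threshold Relative RMSECV improvement required to recommend
#'   dropping (default 0.10, i.e. 10%).
#' @return A one-row tibble: RMSECV and R2cv with and without the flagged
#'   samples, their differences, and `recommendation` ("keep" or "drop").
#' @export
keep_or_drop <- function(cal, flagged, n_lv = 3, rel_threshold = 0.10) {
  stray <- setdiff(flagged, cal$sample_id)
  if (length(stray)) {
    abort(paste0("flagged ids not in the calibration set: ",
                 paste(stray, collapse = ", ")),
          class = "nirmc_argument_error")
  }
  without <- dplyr::filter(cal, !.data$sample_id %in% flagged)
  if (nrow(without) < n_lv + 2) {
    abort("dropping flagged samples leaves too few for the model",
          class = "nirmc_insufficient_data_error")
  }
  cv_with <- full_cross_validation(cal, cal$mc, max_lv = n_lv)
  cv_without <- full_cross_validation(without, without$mc, max_lv = n_lv)
  r_with <- cv_with$rmsecv[n_lv]
  r_without <- cv_without$rmsecv[n_lv]
  improvement <- (r_with - r_without) / r_with
  tibble::tibble(
    n_flagged = length(flagged),
    rmsecv_with = r_with, rmsecv_without = r_without,
    r2cv_with = cv_with$r2_cv[n_lv], r2cv_without = cv_without$r2_cv[n_lv],
    delta_rmsecv = r_without - r_with,
    delta_r2cv = cv_without$r2_cv[n_lv] - cv_with$r2_cv[n_lv],
    recommendation = if (isTRUE(improvement > rel_threshold)) "drop" else "keep"
  )
}

#' @export
print.nir_pca <- function(x, ...) {
  cat("NIPALS PCA:", x$n, "samples,", ncol(x$scores), "components\n")
  cat("explained variance fractions:",
      paste(sprintf("%.3f", x$var_fraction), collapse = " "), "\n")
  invisible(x)
}
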