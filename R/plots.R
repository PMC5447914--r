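# ---- ggplot2 graphics -----------------------------------------------------

#' Plot spectra
#'
#' Overlaid absorbance traces, optionally coloured by a metadata column.
#'
#' @param x A spectra tibble.
#' @param color_by Metadata column to colour by (default `"species"`).
#' @return A ggplot object.
#' @export
plot_spectra <- function(x, color_by = "species") {
  long <- x |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    tidyr::pivot_longer(-dplyr::all_of(c(META_COLS, ".row")),
                        names_to = "wavelength", values_to = "absorbance") |>
    dplyr::mutate(wavelength = as.numeric(.data$wavelength))
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$absorbance,
                                     group = .data$.row,
                                     colour = .data[[color_by]])) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "wavelength (nm)", y = "log(1/R)")
}

#' Score plot with the Hotelling ellipse
#'
#' PC1/PC2 scores with the T-squared control contour used for outlier
#' screening.
#'
#' @param object A `"nir_pca"`.
#' @param alpha Significance level of the ellipse.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nir_pca <- function(object, alpha = 0.05, ...) {
  sc <- tibble::tibble(pc1 = object$scores[, 1], pc2 = object$scores[, 2],
                       sample_id = object$sample_id)
  lim <- hotelling_limit(object$n, 2, alpha)
  th <- seq(0, 2 * pi, length.out = 200)
  ell <- tibble::tibble(
    pc1 = sqrt(lim * object$eigenvalues[1]) * cos(th),
    pc2 = sqrt(lim * object$eigenvalues[2]) * sin(th)
  )
  ggplot2::ggplot(sc, ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(data = ell, linetype = 2, colour = "red") +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_fraction[2])
    )
}

#' Cross-validation error curve
#'
#' @param object A `"cv_curve"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n_lv, .data$rmsecv)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "latent variables", y = "RMSECV (% MC)")
}

#' Regression-coefficient trace
#'
#' The PLS regression coefficient against wavelength — the trace whose peaks
#' drive wavelength selection.
#'
#' @param object A `"pls_model"`.
#' @param selected Optional wavelengths to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pls_model <- function(object, selected = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(.data$wavelength, .data$coefficient)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "regression coefficient")
  if (!is.null(selected)) {
    p <- p + ggplot2::geom_vline(xintercept = selected, linetype = 3,
                                 colour = "red")
  }
  p
}

#' Predicted versus measured moisture
#'
#' @param y_ref Reference MC, % wet basis.
#' @param y_hat Predicted MC, % wet basis.
#' @return A ggplot object with the identity line.
#' @export
plot_predictions <- function(y_ref, y_hat) {
  ggplot2::ggplot(tibble::tibble(measured = y_ref, predicted = y_hat),
                  ggplot2::aes(.data$measured, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "measured MC (%)", y = "predicted MC (%)")
}
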