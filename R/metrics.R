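# ---- validation statistics and model comparison ---------------------------

#' Evaluate predictions against reference moisture values
#'
#' Computes the standard validation statistics for a calibration transferred
#' to an independent set: with residuals `e = y_hat - y_ref`,
#' bias = mean(e), RMSEP = sqrt(mean(e^2)), SEP = sd(e) (n-1 denominator),
#' R2 of prediction = 1 - SSE/SST, and RPD = sd(y_ref)/SEP. A perfect
#' prediction yields RPD = Inf (reported as a sentinel, never dropped).
#'
#' @param y_ref Reference MC values, % wet basis (>= 3, non-constant).
#' @param y_hat Predicted MC values, same length.
#' @return A one-row tibble of class `"validation_report"`: `n`, `r2_pred`,
#'   `rmsep`, `sep`, `bias`, `rpd`.
#' @export
#' @examples
#' evaluate_predictions(c(10, 12, 14), c(11, 12, 13))
evaluate_predictions <- function(y_ref, y_hat) {
  if (length(y_ref) != length(y_hat)) {
    abort("reference and prediction lengths differ", class = "nirmc_shape_error")
  }
  n <- length(y_ref)
  if (n < 3) abort("need at least 3 validation samples",
                   class = "nirmc_argument_error")
  if (sd(y_ref) < 1e-12) abort("reference values are constant",
                               class = "nirmc_degenerate_error")
  e <- y_hat - y_ref
  bias <- mean(e)
  rmsep <- sqrt(mean(e^2))
  sep <- sqrt(sum((e - bias)^2) / (n - 1))
  r2 <- 1 - sum(e^2) / sum((y_ref - mean(y_ref))^2)
  rpd <- if (sep > 0) sd(y_ref) / sep else Inf
  out <- tibble::tibble(n = n, r2_pred = r2, rmsep = rmsep,
                        sep = sep, bias = bias, rpd = rpd)
  class(out) <- c("validation_report", class(out))
  out
}

#' Compare the prediction errors of two models
#'
#' Paired comparison of squared residuals on the same validation samples.
#' The default is a two-sided paired t-test on `d_i = e_a_i^2 - e_b_i^2`;
#' `"randomization"` replaces the t reference distribution with sign-flip
#' resampling of `d_i`.
#'
#' @param e_a,e_b Residual vectors of the two models on identical samples.
#' @param method `"paired_t_squared"` (default) or `"randomization"`.
#' @param n_resamples Sign-flip resamples for the randomization test.
#' @return A one-row tibble: `method`, `statistic` (mean of `d`), `p_value`.
#'   Identical errors give p = 1.
#' @export
compare_prediction_errors <- function(e_a, e_b,
                                      method = c("paired_t_squared",
                                                 "randomization"),
                                      n_resamples = 10000) {
  method <- match.arg(method)
  if (length(e_a) != length(e_b)) {
    abort("residual vectors must pair the same samples",
          class = "nirmc_pairing_error")
  }
  if (length(e_a) < 3) abort("need at least 3 pairs",
                             class = "nirmc_argument_error")
  d <- e_a^2 - e_b^2
  if (sd(d) < 1e-14 * max(1, mean(abs(d)))) {
    # degenerate: no paired difference variation
    p <- if (isTRUE(all.equal(mean(d), 0))) 1 else 0
    return(tibble::tibble(method = method, statistic = mean(d), p_value = p))
  }
  p <- if (method == "paired_t_squared") {
    stats::t.test(d)$p.value
  } else {
    obs <- abs(mean(d))
    n <- length(d)
    hits <- 0L
    for (r in seq_len(n_resamples)) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      if (abs(mean(signs * d)) >= obs - 1e-15) hits <- hits + 1L
    }
    (hits + 1) / (n_resamples + 1)
  }
  tibble::tibble(method = method, statistic = mean(d), p_value = p)
}

#' Assemble a model-comparison report table
#'
#' Lays out calibration and prediction statistics for several model
#' configurations side by side, one column per model, rounded to reporting
#' precision (4 decimals for R-squared, 2 for errors in % MC). An infinite
#' RPD is shown as the sentinel string `"Inf"`.
#'
#' @param entries Named list; each element is a list with optional
#'   `calibration` (a one-row data frame with any of `n_lv`, `r2_cal`,
#'   `r2_cv`, `rmsec`, `rmsecv`) and `prediction` (a
#'   [evaluate_predictions()] report).
#' @return A tibble with a `parameter` column and one character column per
#'   model configuration.
#' @export
report_table <- function(entries) {
  if (is.null(entries) || length(entries) == 0) {
    abort("no report entries supplied", class = "nirmc_argument_error")
  }
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    abort("entries must be a named list", class = "nirmc_argument_error")
  }
  params <- c("LVs", "R2 calibration", "R2 cross validation",
              "RMSEC (% MC)", "RMSECV (% MC)", "R2 prediction",
              "RMSEP (% MC)", "SEP (% MC)", "Bias (% MC)", "RPD")
  fmt_r2 <- function(v) if (is.null(v) || is.na(v)) "n/a" else sprintf("%.4f", v)
  fmt_err <- function(v) if (is.null(v) || is.na(v)) "n/a" else sprintf("%.2f", v)
  col_for <- function(entry) {
    cal <- entry$calibration
    prd <- entry$prediction
    g <- function(df, field) {
      if (!is.null(df) && field %in% names(df)) df[[field]][1] else NA_real_
    }
    rpd <- g(prd, "rpd")
    c(
      if (is.na(g(cal, "n_lv"))) "n/a" else sprintf("%d", as.integer(g(cal, "n_lv"))),
      fmt_r2(g(cal, "r2_cal")), fmt_r2(g(cal, "r2_cv")),
      fmt_err(g(cal, "rmsec")), fmt_err(g(cal, "rmsecv")),
      fmt_r2(g(prd, "r2_pred")), fmt_err(g(prd, "rmsep")),
      fmt_err(g(prd, "sep")), fmt_err(g(prd, "bias")),
      if (is.na(rpd)) "n/a" else if (is.infinite(rpd)) "Inf" else sprintf("%.2f", rpd)
    )
  }
  cols <- lapply(entries, col_for)
  dplyr::bind_cols(tibble::tibble(parameter = params),
                   tibble::as_tibble(cols))
}
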