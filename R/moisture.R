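#' Gravimetric moisture content, wet basis
#'
#' Moisture content of green coffee by the oven-drying reference method:
#' the mass lost on drying relative to the wet mass, `(ww - wd) / ww`.
#' Returned as a fraction; multiply by 100 for % MC.
#'
#' @param ww Wet weight, g (> 0).
#' @param wd Dry weight, g (0 <= wd <= ww).
#' @return Moisture fraction in `[0, 1)`. Vectorised.
#' @export
#' @examples
#' mc_wet_basis(10, 9)  # 0.1 -> 10% MC
mc_wet_basis <- function(ww, wd) {
  if (any(ww <= 0)) {
    abort("wet weight must be positive", class = "nirmc_argument_error")
  }
  if (any(wd < 0)) {
    abort("dry weight must be non-negative", class = "nirmc_argument_error")
  }
  if (any(wd > ww)) {
    abort("dry weight exceeds wet weight (negative moisture)",
          class = "nirmc_negative_moisture_error")
  }
  (ww - wd) / ww
}

#' Summarise duplicate gravimetric determinations
#'
#' Each sample is oven-dried in duplicate; its reference MC is the mean of the
#' duplicate determinations. The spread of duplicates estimates the precision
#' of the reference method.
#'
#' @param records Tibble/data frame with columns `sample_id`, `duplicate`,
#'   `ww_g`, `wd_g` (one row per weighing).
#' @return A tibble with one row per sample: `sample_id`, `n` (number of
#'   duplicates), `mc` (mean MC, % wet basis), and `sd_mc` (SD of the
#'   duplicate MCs, n-1 denominator; NA with a single duplicate). Attributes
#'   `avg_sd` and `median_sd` hold the mean and median of the per-sample SDs
#'   over samples with >= 2 duplicates.
#' @export
summarize_duplicates <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    abort("no weighing records supplied", class = "nirmc_empty_input_error")
  }
  out <- records |>
    dplyr::mutate(mc_pct = 100 * mc_wet_basis(.data$ww_g, .data$wd_g)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mc = mean(.data$mc_pct),
      sd_mc = if (dplyr::n() >= 2) sd(.data$mc_pct) else NA_real_,
      .by = "sample_id"
    )
  sds <- out$sd_mc[!is.na(out$sd_mc)]
  attr(out, "avg_sd") <- if (length(sds)) mean(sds) else NA_real_
  attr(out, "median_sd") <- if (length(sds)) median(sds) else NA_real_
  out
}

#' Classify moisture against the trade safety range
#'
#' Green coffee is tradeable when its moisture content lies in the closed
#' safety range 8.0--12.5% (wet basis): drier beans shrink, wetter beans risk
#' fungal growth and mycotoxins.
#'
#' @param mc_percent Moisture content, % wet basis (>= 0). Vectorised.
#' @return Character vector: `"below"`, `"in_range"`, or `"above"`
#'   (boundaries classify as in range).
#' @export
#' @examples
#' classify_safety(c(7.9, 8, 12.5, 12.6))
classify_safety <- function(mc_percent) {
  if (any(mc_percent < 0)) {
    abort("moisture content cannot be negative", class = "nirmc_argument_error")
  }
  dplyr::case_when(
    mc_percent < 8.0 ~ "below",
    mc_percent > 12.5 ~ "above",
    .default = "in_range"
  )
}

#' Read and write weighing-record CSVs
#'
#' Plain CSV with columns `sample_id,duplicate,ww_g,wd_g`.
#'
#' @param path File path.
#' @param records Weighing records tibble.
#' @return `read_weighing_records()` returns a tibble; the writer returns its
#'   input invisibly.
#' @export
read_weighing_records <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    duplicate = readr::col_integer(),
                    ww_g = readr::col_double(),
                    wd_g = readr::col_double()
                  ))
}

#' @rdname read_weighing_records
#' @export
write_weighing_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(records)
}

#' Per-sample moisture report with safety flags
#'
#' @param records Weighing records (see [summarize_duplicates()]).
#' @return A tibble with `sample_id`, `n`, `mc`, `sd_mc`, and `safety`.
#' @export
moisture_report <- function(records) {
  summarize_duplicates(records) |>
    dplyr::mutate(safety = classify_safety(.data$mc))
}
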