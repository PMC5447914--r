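# a single-species, constant-moisture, noise-free configuration: every
# sample shares one clean chemistry spectrum, so scatter is the only
# between-spectrum variation and EMSC can invert it exactly
constant_chem_config <- function(n_grid = 120) {
  ot <- tibble::tibble(origin = c("A", "B"), species = "Arabica",
                       role = c("calibration", "validation"), n = c(8, 4))
  sim_config(wavelengths = default_grid(n_grid), origin_table = ot,
             mc_range = c(14, 14), noise_sd = 0, duplicate_sd = 0)
}

test_that("EMSC exactly inverts its own distortion model", {
  cfg <- constant_chem_config()
  ds <- simulate_dataset(cfg, seed = 21)
  chem0 <- ds$truth$chemistry[1, ]
  expect_equal(max(abs(sweep(ds$truth$chemistry, 2, chem0))), 0)

  cal <- calibration(ds$spectra)
  corr <- fit_scatter(cal, "emsc", reference = chem0)
  fixed <- predict(corr, ds$spectra)
  # every replicate collapses back onto the clean spectrum at machine precision
  expect_lt(max(abs(sweep(spectra_matrix(fixed), 2, chem0))), 1e-9)
  # while the raw replicates differ from it by visible scatter
  expect_gt(max(abs(sweep(spectra_matrix(ds$spectra), 2, chem0))), 1e-2)
})

test_that("MSC removes pure offset/multiplier distortions", {
  set.seed(4)
  ref <- 0.5 + exp(-(seq(1000, 1200, by = 5) - 1100)^2 / 800)
  clean <- toy_spectra(rbind(ref, ref, ref), wl = seq(1000, 1200, by = 5))
  distorted <- apply_scatter(clean, a = c(0.1, -0.05, 0.02),
                             b = c(1.2, 0.8, 1.05))
  corr <- fit_scatter(distorted, "msc", reference = ref)
  out <- spectra_matrix(predict(corr, distorted))
  expect_equal(unname(out), matrix(ref, 3, length(ref), byrow = TRUE),
               tolerance = 1e-10)
})

test_that("EMSC on heterogeneous spectra shrinks scatter-induced spread", {
  ds <- simulate_dataset(small_config(120), seed = 3)
  cal <- calibration(ds$spectra)
  corr <- fit_scatter(cal, "emsc")
  out <- predict(corr, cal)
  # replicates of the same sample share chemistry; correction should pull
  # them together
  within_sd <- function(sp) {
    m <- spectra_matrix(sp)
    mean(vapply(split(seq_len(nrow(m)), sp$sample_id),
                function(i) mean(apply(m[i, , drop = FALSE], 2, sd)), 0))
  }
  expect_lt(within_sd(out), 0.3 * within_sd(cal))
})

test_that("scatter correction validates its inputs", {
  x <- toy_spectra(rbind(1:10, 2 * (1:10) + 1))
  expect_error(fit_scatter(x, "msc", poly_order = 2),
               class = "nirmc_argument_error")
  expect_error(fit_scatter(x, "emsc", poly_order = 5),
               class = "nirmc_argument_error")
  expect_error(fit_scatter(x[1, ], "msc"), class = "nirmc_argument_error")
  expect_error(fit_scatter(x, "emsc", reference = 1:3),
               class = "nirmc_shape_error")
  corr <- fit_scatter(x, "msc")
  other <- toy_spectra(rbind(1:8), wl = seq(1000, by = 2, length.out = 8))
  expect_error(predict(corr, other), class = "nirmc_grid_error")
  # a flat spectrum has no multiplicative component to divide by
  flat <- toy_spectra(rbind(rep(2, 10)))
  expect_error(predict(corr, flat), class = "nirmc_degenerate_error")
})

test_that("OSC removes response-orthogonal structure only", {
  ds <- simulate_dataset(small_config(120), seed = 9)
  cal <- average_replicates(calibration(ds$spectra))
  y <- cal$mc
  osc <- fit_osc(cal, y, n_components = 1)
  # the score actually removed from the calibration spectra is orthogonal to y
  Xc <- sweep(spectra_matrix(cal), 2, osc$x_mean)
  score <- Xc %*% osc$weights
  expect_lt(abs(as.numeric(crossprod(score, y - mean(y)))) /
              (sqrt(sum(score^2)) * sd(y)), 1e-8)
  # deflation strictly reduces spectral variance
  out <- predict(osc, cal)
  v0 <- sum(scale(spectra_matrix(cal), scale = FALSE)^2)
  v1 <- sum(scale(spectra_matrix(out), scale = FALSE)^2)
  expect_lt(v1, v0)
  # but preserves the x/y covariance direction enough to predict as well
  cv0 <- full_cross_validation(cal, y, max_lv = 3)
  cv1 <- full_cross_validation(out, y, max_lv = 3)
  expect_lt(cv1$rmsecv[3], 2 * cv0$rmsecv[3])

  # zero components is the identity
  id <- fit_osc(cal, y, n_components = 0)
  expect_equal(spectra_matrix(predict(id, cal)), spectra_matrix(cal))
})

test_that("OSC rejects invalid setups", {
  x <- toy_spectra(rbind(1:6, c(2, 1, 4, 3, 6, 5), 3:8, c(1, 3, 2, 5, 4, 7)))
  y <- c(1, 2, 3, 4)
  expect_error(fit_osc(x, y[1:3]), class = "nirmc_argument_error")
  expect_error(fit_osc(x, y, n_components = -1), class = "nirmc_argument_error")
  expect_error(fit_osc(x, y, n_components = 10), class = "nirmc_rank_error")
  osc <- fit_osc(x, y, n_components = 1)
  other <- toy_spectra(rbind(1:5), wl = seq(1000, by = 2, length.out = 5))
  expect_error(predict(osc, other), class = "nirmc_grid_error")
})
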