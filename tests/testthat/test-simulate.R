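test_that("the generator reproduces the study design exactly", {
  cfg <- small_config()
  ds <- simulate_dataset(cfg, seed = 31)
  ot <- default_origin_table()
  expect_equal(nrow(ds$spectra), sum(ot$n) * 3)          # 108 x 3 replicates
  expect_equal(dplyr::n_distinct(ds$spectra$sample_id), 108)
  avg <- average_replicates(ds$spectra)
  expect_equal(nrow(calibration(avg)), 64)
  expect_equal(nrow(validation(avg)), 44)
  expect_equal(nrow(ds$moisture), 108 * 2)               # duplicate weighings
  expect_setequal(unique(ds$spectra$species), c("Arabica", "Robusta"))
  expect_equal(dplyr::n_distinct(ds$spectra$origin), 12)
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- small_config(60)
  a <- simulate_dataset(cfg, seed = 5)
  b <- simulate_dataset(cfg, seed = 5)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$moisture, b$moisture)
  c <- simulate_dataset(cfg, seed = 6)
  expect_false(isTRUE(all.equal(spectra_matrix(a$spectra),
                                spectra_matrix(c$spectra))))
})

test_that("random draws come from independent per-stage streams", {
  base <- small_config(60)
  quiet <- sim_config(wavelengths = default_grid(60), noise_sd = 0)
  a <- simulate_dataset(base, seed = 9)
  b <- simulate_dataset(quiet, seed = 9)
  # changing the spectral-noise stage leaves moisture and scatter untouched
  expect_identical(a$moisture, b$moisture)
  expect_identical(a$truth$scatter, b$truth$scatter)
  expect_identical(a$truth$samples, b$truth$samples)
})

test_that("the spectra mc column is the duplicate-mean reference value", {
  ds <- simulate_dataset(small_config(60), seed = 12)
  ref <- summarize_duplicates(ds$moisture)
  expect_equal(ds$spectra$mc,
               ref$mc[match(ds$spectra$sample_id, ref$sample_id)])
  # weighing records are internally consistent with their observed MC
  mc_from_weights <- 100 * mc_wet_basis(ds$moisture$ww_g, ds$moisture$wd_g)
  expect_true(all(mc_from_weights > 4 & mc_from_weights < 24))
  # and the reference tracks the truth within duplicate noise
  tr <- ds$truth$samples
  expect_lt(max(abs(tr$mc_ref - tr$mc_true)), 1.5)
})

test_that("replicate spectra are scatter/noise variants of one chemistry", {
  cfg <- small_config(80)
  ds <- simulate_dataset(cfg, seed = 15)
  m <- spectra_matrix(ds$spectra)
  chem <- ds$truth$chemistry
  sc <- ds$truth$scatter
  lt <- lambda_tilde(cfg$wavelengths)
  i <- 10  # an arbitrary replicate row
  s_idx <- match(sc$sample_id[i], ds$truth$samples$sample_id)
  expected <- chem[s_idx, ] * sc$b[i] + sc$a[i] +
    sc$poly1[i] * lt + sc$poly2[i] * lt^2
  resid <- m[i, ] - expected
  # what is left is exactly the additive noise: small and structureless
  expect_lt(max(abs(resid)), 5 * cfg$noise_sd)
  expect_equal(sd(resid), cfg$noise_sd, tolerance = 0.3)
})

test_that("the species contrast dominates spectral variance", {
  ds <- simulate_dataset(small_config(), seed = 27)
  avg <- average_replicates(ds$spectra)
  pca <- fit_pca(avg, n_pc = 2)
  # the first two components carry nearly all variance, as in the study
  expect_gt(sum(pca$var_fraction), 0.95)
  # PC1 separates Arabica from Robusta cleanly
  s1 <- pca$scores[, 1]
  g <- avg$species == "Arabica"
  gap <- abs(mean(s1[g]) - mean(s1[!g]))
  pooled <- sqrt((var(s1[g]) + var(s1[!g])) / 2)
  expect_gt(gap, 2 * pooled)
})

test_that("apply_scatter matches its formula on a hand case", {
  x <- toy_spectra(rbind(c(1, 2, 3)), wl = c(1000, 1100, 1200))
  out <- apply_scatter(x, a = 0.5, b = 2, poly = c(0.1, 0.2))
  lt <- c(-1, 0, 1)
  expect_equal(unname(spectra_matrix(out)[1, ]),
               2 * c(1, 2, 3) + 0.5 + 0.1 * lt + 0.2 * lt^2)
  expect_error(apply_scatter(x, a = 0, b = 0), class = "nirmc_argument_error")
})

test_that("the c4 bias constant and stage-seed derivation are correct", {
  expect_equal(c4_const(2), sqrt(2 / pi))
  # E[sample SD] = c4 * sigma: Monte-Carlo check
  set.seed(1)
  sds <- replicate(4000, sd(rnorm(2)))
  expect_equal(mean(sds), c4_const(2), tolerance = 0.02)
  expect_equal(config_stage_seed(10, 3), 83L)
  expect_error(config_stage_seed(.Machine$integer.max, 3),
               class = "nirmc_config_error")
})

test_that("configuration validation rejects impossible setups", {
  expect_error(sim_config(noise_sd = -1), class = "nirmc_config_error")
  expect_error(sim_config(mc_range = c(12, 6)), class = "nirmc_config_error")
  bad_bands <- default_band_library()
  bad_bands$sigma[1] <- 0
  expect_error(sim_config(bands = bad_bands), class = "nirmc_config_error")
  bad_bands2 <- default_band_library()
  bad_bands2$center[1] <- 50
  expect_error(sim_config(bands = bad_bands2), class = "nirmc_config_error")
  expect_error(simulate_dataset(list(), seed = 1), class = "nirmc_config_error")
})
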