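# ---- synthetic study-structured dataset generator -------------------------
# Chemistry-driven NIR spectra for two coffee species with EMSC-form scatter,
# replicate spectra, and duplicate gravimetric references: the testbed that
# stands in for the (unreleased) experimental data.

default_band_library <- function() {
  # Gaussian absorption bands: two water bands (1450/1940 nm) carry most of
  # the moisture signal; constituent bands (lipids, carbohydrates, proteins,
  # caffeine/chlorogenic acids) near the selected wavelengths carry weaker,
  # indirect moisture information and the species contrast.
  tibble::tibble(
    center   = c(1155,  1212,  1340,  1409,  1450,  1724,  1940,  2249),
    sigma    = c(  25,    25,    25,    30,    40,    28,    50,    35),
    base     = c(0.45,  0.40,  0.35,  0.30,  0.10,  0.50,  0.15,  0.45),
    mc_sens  = c(0.0015, 0.0012, 0.0018, 0.0030, 0.0120, 0.0015, 0.0160, 0.0020),
    # Arabica minus Robusta compositional offsets at the band level
    species_off = c(0.060, 0.050, -0.040, 0.020, 0.000, 0.080, 0.000, -0.050)
  )
}

default_origin_table <- function() {
  # study-design origin structure: 7 calibration and 5 validation origins with
  # species per origin; validation labels duplicated in the calibration list
  # carry a " (val)" suffix so that origin alone determines the split.
  # Per-origin sample counts give the 64/44 calibration/validation totals.
  tibble::tibble(
    origin = c("West Nusa Tenggara", "South Sulawesi", "Aceh",
               "South Sumatera", "Bali", "East Java", "North Sumatera",
               "West Java", "North Sumatera (val)", "South Sumatera (val)",
               "East Java (val)", "Bengkulu"),
    species = c("Arabica", "Arabica", "Arabica",
                "Robusta", "Robusta", "Robusta", "Robusta",
                "Arabica", "Arabica", "Robusta", "Robusta", "Robusta"),
    role = rep(c("calibration", "validation"), c(7, 5)),
    n = c(10, 9, 9, 9, 9, 9, 9, 9, 9, 9, 9, 8)
  )
}

#' Build a simulation configuration
#'
#' All generator parameters with study-design defaults: 64 calibration + 44
#' validation samples from 12 origins of two species, true MC uniform on
#' 6--22% wet basis, 3 replicate spectra per sample, duplicate gravimetric
#' determinations whose per-sample SD averages 0.21% MC, Gaussian absorption
#' bands (water at 1450/1940 nm plus constituent bands), and per-replicate
#' multiplicative + polynomial-baseline scatter of the form EMSC removes.
#'
#' @param wavelengths Wavelength grid, nm (default [default_grid()], 1557
#'   points).
#' @param origin_table Tibble with columns `origin`, `species`, `role`, `n`
#'   giving per-origin sample counts.
#' @param mc_range True-moisture range, % wet basis.
#' @param bands Band library tibble (`center`, `sigma`, `base`, `mc_sens`,
#'   `species_off`).
#' @param background Coefficients of the smooth background
#'   `c0 + c1*lt + c2*lt^2` on the `[-1, 1]`-scaled wavelength axis.
#' @param species_background Broad compositional difference between species
#'   (Arabica minus Robusta), as polynomial coefficients on the same axis;
#'   this makes the species contrast the dominant direction of spectral
#'   variance, as observed for the two commercial coffee species.
#' @param scatter_a_sd,scatter_b_sd,scatter_poly_sd,scatter_poly_order
#'   Per-replicate scatter draws: additive offset `a ~ N(0, a_sd)`,
#'   multiplier `b ~ N(1, b_sd)`, polynomial coefficients
#'   `~ N(0, poly_sd)` up to `poly_order`.
#' @param noise_sd Additive spectral noise SD, absorbance units.
#' @param n_replicates Replicate spectra per sample.
#' @param duplicate_sd Target average per-sample SD of duplicate gravimetric
#'   MC determinations, % MC. The noise actually drawn is scaled by
#'   `1/c4(n)` so the *expected sample SD* equals this value.
#' @param n_duplicates Gravimetric duplicates per sample.
#' @param ww_mean,ww_sd Wet-weight draw, g.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(wavelengths = default_grid(),
                       origin_table = default_origin_table(),
                       mc_range = c(6, 22),
                       bands = default_band_library(),
                       background = c(0.30, 0.10, 0.05),
                       species_background = c(0.12, 0.03, 0),
                       scatter_a_sd = 0.02,
                       scatter_b_sd = 0.05,
                       scatter_poly_sd = 0.01,
                       scatter_poly_order = 2,
                       noise_sd = 0.002,
                       n_replicates = 3,
                       duplicate_sd = 0.21,
                       n_duplicates = 2,
                       ww_mean = 10, ww_sd = 0.1) {
  check_grid(wavelengths)
  sds <- c(scatter_a_sd, scatter_b_sd, scatter_poly_sd, noise_sd, duplicate_sd)
  if (any(sds < 0)) abort("all SDs must be >= 0", class = "nirmc_config_error")
  if (any(bands$sigma <= 0)) abort("band widths must be positive",
                                   class = "nirmc_config_error")
  if (any(bands$center < min(wavelengths) | bands$center > max(wavelengths))) {
    abort("band centers must lie within the grid span",
          class = "nirmc_config_error")
  }
  if (diff(mc_range) < 0) abort("mc_range must be non-decreasing",
                                class = "nirmc_config_error")
  structure(
    list(wavelengths = wavelengths, origin_table = origin_table,
         mc_range = mc_range, bands = bands, background = background,
         species_background = species_background,
         scatter_a_sd = scatter_a_sd, scatter_b_sd = scatter_b_sd,
         scatter_poly_sd = scatter_poly_sd,
         scatter_poly_order = scatter_poly_order,
         noise_sd = noise_sd, n_replicates = n_replicates,
         duplicate_sd = duplicate_sd, n_duplicates = n_duplicates,
         ww_mean = ww_mean, ww_sd = ww_sd),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
make_default_config <- function() sim_config()

# unbiasing constant for the SD of n normal draws
c4_const <- function(n) {
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

chemistry_matrix <- function(config, mc, species) {
  wl <- config$wavelengths
  lt <- lambda_tilde(wl)
  bg <- config$background[1] + config$background[2] * lt +
    config$background[3] * lt^2
  G <- vapply(seq_len(nrow(config$bands)), function(k) {
    exp(-(wl - config$bands$center[k])^2 / (2 * config$bands$sigma[k]^2))
  }, numeric(length(wl)))  # p x K
  amp <- outer(mc, config$bands$mc_sens) +
    matrix(config$bands$base, length(mc), nrow(config$bands), byrow = TRUE) +
    outer(as.numeric(species == "Arabica"), config$bands$species_off)
  sb <- config$species_background
  broad <- as.numeric(outer(lt, seq_along(sb) - 1, `^`) %*% sb)
  sweep(amp %*% t(G), 2, bg, `+`) +
    outer(as.numeric(species == "Arabica"), broad)  # n x p
}

#' Apply a multiplicative/baseline scatter distortion
#'
#' The generator-side scatter model, matched to the form EMSC removes:
#' `a + b * x + sum_i poly_i * lt^i` with `lt` the wavelength axis scaled to
#' `[-1, 1]`.
#'
#' @param x A spectra tibble.
#' @param a Additive offset (scalar or one per row).
#' @param b Multiplier, nonzero (scalar or one per row).
#' @param poly Polynomial coefficients (vector, or matrix one row per
#'   spectrum); may be empty.
#' @return The distorted spectra tibble.
#' @export
apply_scatter <- function(x, a, b, poly = numeric(0)) {
  if (any(b == 0)) abort("multiplier b must be nonzero",
                         class = "nirmc_argument_error")
  m <- spectra_matrix(x)
  lt <- lambda_tilde(spectra_wavelengths(x))
  n <- nrow(m)
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- m * b + a
  if (length(poly)) {
    pm <- if (is.matrix(poly)) poly else matrix(poly, n, length(poly), byrow = TRUE)
    basis <- vapply(seq_len(ncol(pm)), function(j) lt^j, numeric(length(lt)))
    out <- out + pm %*% t(basis)
  }
  set_spectra_matrix(x, out)
}

#' Simulate a study-structured dataset
#'
#' For each sample: a true MC drawn uniformly on the configured range, a
#' chemistry-only spectrum from the band library, `n_replicates` replicate
#' spectra each with an independent scatter draw and additive noise, and
#' duplicate gravimetric weighings realised as consistent (wet, dry) weight
#' pairs around 10 g. The spectra tibble's `mc` column holds the mean of the
#' duplicate gravimetric determinations (the reference value a practitioner
#' would use); the truth record keeps the noiseless quantities. A single seed
#' governs all draws through fixed per-stage streams (`seed*8 + stage`), so
#' identical `(config, seed)` gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with elements `spectra` (replicate-level spectra tibble),
#'   `moisture` (weighing records: `sample_id`, `duplicate`, `ww_g`, `wd_g`),
#'   and `truth` (list: `samples` tibble with true MC and reference MC,
#'   `chemistry` clean spectra matrix, `scatter` per-replicate draws,
#'   `config`).
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  if (!inherits(config, "sim_config")) {
    abort("config must be a sim_config object", class = "nirmc_config_error")
  }
  ot <- config$origin_table
  n_samples <- sum(ot$n)
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    species = rep(ot$species, ot$n),
    origin = rep(ot$origin, ot$n),
    role = rep(ot$role, ot$n)
  )

  # stage 0: true moisture
  set.seed(config_stage_seed(seed, 0))
  samples$mc_true <- runif(n_samples, config$mc_range[1], config$mc_range[2])

  # stage 1: gravimetric duplicates (noise scaled so E[sample SD] = duplicate_sd)
  set.seed(config_stage_seed(seed, 1))
  dup_noise_sd <- if (config$n_duplicates >= 2) {
    config$duplicate_sd / c4_const(config$n_duplicates)
  } else 0
  moisture <- tidyr::expand_grid(sample_id = samples$sample_id,
                                 duplicate = seq_len(config$n_duplicates)) |>
    dplyr::left_join(samples[, c("sample_id", "mc_true")], by = "sample_id") |>
    dplyr::mutate(
      mc_obs = .data$mc_true + rnorm(dplyr::n(), 0, dup_noise_sd),
      ww_g = rnorm(dplyr::n(), config$ww_mean, config$ww_sd),
      wd_g = .data$ww_g * (1 - .data$mc_obs / 100)
    )
  ref_mc <- moisture |>
    dplyr::summarise(mc = mean(.data$mc_obs), .by = "sample_id")
  samples$mc_ref <- ref_mc$mc[match(samples$sample_id, ref_mc$sample_id)]

  # clean chemistry spectra (noise- and scatter-free)
  chem <- chemistry_matrix(config, samples$mc_true, samples$species)

  # stage 2: per-replicate scatter draws
  set.seed(config_stage_seed(seed, 2))
  n_rep_rows <- n_samples * config$n_replicates
  scatter <- tibble::tibble(
    sample_id = rep(samples$sample_id, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), n_samples),
    a = rnorm(n_rep_rows, 0, config$scatter_a_sd),
    b = rnorm(n_rep_rows, 1, config$scatter_b_sd)
  )
  poly <- if (config$scatter_poly_order > 0) {
    matrix(rnorm(n_rep_rows * config$scatter_poly_order, 0,
                 config$scatter_poly_sd),
           n_rep_rows, config$scatter_poly_order)
  } else {
    matrix(0, n_rep_rows, 0)
  }

  # stage 3: additive spectral noise
  set.seed(config_stage_seed(seed, 3))
  p <- length(config$wavelengths)
  noise <- matrix(rnorm(n_rep_rows * p, 0, config$noise_sd), n_rep_rows, p)

  rep_idx <- rep(seq_len(n_samples), each = config$n_replicates)
  lt <- lambda_tilde(config$wavelengths)
  basis <- if (ncol(poly)) {
    vapply(seq_len(ncol(poly)), function(j) lt^j, numeric(p))
  } else NULL
  obs <- chem[rep_idx, , drop = FALSE] * scatter$b + scatter$a + noise
  if (!is.null(basis)) obs <- obs + poly %*% t(basis)

  spectra <- spectra_tbl(
    obs, config$wavelengths,
    sample_id = scatter$sample_id,
    species = samples$species[rep_idx],
    origin = samples$origin[rep_idx],
    replicate = scatter$replicate,
    role = samples$role[rep_idx],
    mc = samples$mc_ref[rep_idx]
  )

  list(
    spectra = spectra,
    moisture = moisture[, c("sample_id", "duplicate", "ww_g", "wd_g")],
    truth = list(samples = samples, chemistry = chem,
                 scatter = dplyr::bind_cols(scatter,
                                            tibble::as_tibble(poly, .name_repair = ~ paste0("poly", seq_along(.)))),
                 config = config, seed = seed)
  )
}

# documented stream-splitting: stage seeds derived from the master seed
config_stage_seed <- function(seed, stage) {
  s <- suppressWarnings(as.integer(seed) * 8L + as.integer(stage))
  if (is.na(s)) abort("seed too large for stage derivation",
                      class = "nirmc_config_error")
  s
}
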