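flat_line <- function(p = 41) toy_spectra(rep(2, p))
ramp_line <- function(p = 41) toy_spectra(seq_len(p))

test_that("smoothers preserve shape, constants, and reduce noise", {
  set.seed(1)
  x <- toy_spectra(rbind(sin(seq(0, 4 * pi, length.out = 101)) + rnorm(101, sd = 0.05)))
  for (method in c("moving_average", "gaussian", "median")) {
    sm <- smooth_spectra(x, method = method, window = 7)
    expect_equal(dim(spectra_matrix(sm)), dim(spectra_matrix(x)))
    # a constant spectrum is a fixed point
    expect_equal(unname(spectra_matrix(smooth_spectra(flat_line(), method, 7))[1, ]),
                 rep(2, 41))
  }
  # moving average of pure noise shrinks the SD roughly by sqrt(window)
  noise <- toy_spectra(rbind(rnorm(500)))
  sm <- smooth_spectra(noise, "moving_average", window = 11)
  expect_lt(sd(spectra_matrix(sm)), sd(spectra_matrix(noise)) / 2)
  expect_error(smooth_spectra(x, window = 4), class = "nirmc_argument_error")
  expect_error(smooth_spectra(x, window = 201), class = "nirmc_argument_error")
})

test_that("moving average matches a hand-computed interior value", {
  x <- toy_spectra(rbind(c(1, 2, 6, 2, 1)))
  sm <- smooth_spectra(x, "moving_average", window = 3)
  expect_equal(unname(spectra_matrix(sm)[1, 3]), mean(c(2, 6, 2)))
  md <- smooth_spectra(x, "median", window = 3)
  expect_equal(unname(spectra_matrix(md)[1, 3]), 2)
})

test_that("Savitzky-Golay derivatives are exact on polynomials in index", {
  idx <- 0:60
  # cubic in the grid index: derivatives are known exactly
  v <- 2 + 0.5 * idx - 0.02 * idx^2 + 0.001 * idx^3
  x <- toy_spectra(rbind(v))
  d1 <- spectra_matrix(sg_derivative(x, deriv = 1, poly = 3, window = 11))[1, ]
  d2 <- spectra_matrix(sg_derivative(x, deriv = 2, poly = 3, window = 11))[1, ]
  expected1 <- 0.5 - 0.04 * idx + 0.003 * idx^2
  expected2 <- -0.04 + 0.006 * idx
  interior <- 11:51  # away from reflection-padded edges
  expect_equal(unname(d1[interior]), expected1[interior], tolerance = 1e-8)
  expect_equal(unname(d2[interior]), expected2[interior], tolerance = 1e-8)
  # derivative of a constant is zero everywhere
  expect_equal(unname(spectra_matrix(sg_derivative(flat_line(), 1, 2, 7))[1, ]),
               rep(0, 41))
  expect_error(sg_derivative(x, deriv = 3, poly = 2), class = "nirmc_argument_error")
  expect_error(sg_derivative(x, deriv = 1, poly = 2, window = 3),
               class = "nirmc_argument_error")
})

test_that("normalisation fixes the mean or the absolute area", {
  set.seed(2)
  x <- toy_spectra(rbind(runif(50, 0.1, 1), runif(50, 0.1, 1)))
  nm <- normalize_spectra(x, "mean")
  expect_equal(unname(rowMeans(spectra_matrix(nm))), c(1, 1))
  na <- normalize_spectra(x, "area")
  wl <- spectra_wavelengths(x)
  delta <- c(wl[2] - wl[1], (wl[3:50] - wl[1:48]) / 2, wl[50] - wl[49])
  areas <- abs(spectra_matrix(na)) %*% delta
  expect_equal(unname(as.numeric(areas)), c(1, 1))
  # scaling a spectrum by any positive constant is removed
  y2 <- set_spectra_matrix(x, spectra_matrix(x) * c(3, 0.2))
  expect_equal(spectra_matrix(normalize_spectra(y2, "area")),
               spectra_matrix(na))
  expect_error(normalize_spectra(toy_spectra(rep(0, 10))),
               class = "nirmc_degenerate_error")
})

test_that("baseline correction removes offsets and straight lines", {
  off <- baseline_correct(flat_line(), "offset")
  expect_equal(unname(spectra_matrix(off)[1, ]), rep(0, 41))
  wl <- spectra_wavelengths(ramp_line())
  line <- toy_spectra(rbind(5 + 0.01 * wl))
  lin <- baseline_correct(line, "linear")
  expect_equal(unname(spectra_matrix(lin)[1, ]), rep(0, 41), tolerance = 1e-10)
  # linear correction leaves a pure quadratic's curvature intact
  quad <- toy_spectra(rbind(wl^2))
  lq <- spectra_matrix(baseline_correct(quad, "linear"))[1, ]
  expect_gt(diff(range(lq)), 0)
})

test_that("SNV standardises every spectrum and is idempotent up to scale", {
  set.seed(3)
  x <- toy_spectra(rbind(rnorm(60, 2, 0.3), rnorm(60, 5, 1)))
  s <- snv(x)
  m <- spectra_matrix(s)
  expect_equal(unname(rowMeans(m)), c(0, 0))
  expect_equal(unname(apply(m, 1, sd)), c(1, 1))
  # affine per-spectrum transforms are removed: SNV(a + b x) == SNV(x), b > 0
  y <- set_spectra_matrix(x, 3 + 2 * spectra_matrix(x))
  expect_equal(spectra_matrix(snv(y)), m)
  expect_error(snv(flat_line()), class = "nirmc_degenerate_error")
})

test_that("all stateless treatments preserve metadata and the grid", {
  ds <- simulate_dataset(small_config(60), seed = 11)
  x <- ds$spectra[1:4, ]
  for (f in list(function(z) smooth_spectra(z, "gaussian", 7),
                 function(z) sg_derivative(z, 1, 2, 7),
                 function(z) normalize_spectra(z, "area"),
                 function(z) baseline_correct(z, "linear"),
                 snv)) {
    out <- f(x)
    expect_equal(spectra_meta(out), spectra_meta(x))
    expect_equal(spectra_wavelengths(out), spectra_wavelengths(x))
  }
})
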