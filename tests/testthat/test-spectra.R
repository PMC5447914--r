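test_that("wide CSV parsing and writing round-trip spectra exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,species,origin,replicate,role,mc,1000,1002,1004,1006,1008",
    "A,Arabica,Aceh,1,calibration,10.5,0.1,0.2,0.3,0.4,0.5",
    "B,Robusta,Bali,1,calibration,12.0,0.2,0.3,0.4,0.5,0.6",
    "C,Robusta,Bali,2,validation,9.1,0.3,0.4,0.5,0.6,0.7"
  ), path)
  x <- read_spectra(path)
  expect_equal(nrow(x), 3)
  expect_equal(spectra_wavelengths(x), c(1000, 1002, 1004, 1006, 1008))
  expect_equal(unname(spectra_matrix(x)[2, ]), c(0.2, 0.3, 0.4, 0.5, 0.6))

  # round trip of a generated set is value-identical
  ds <- simulate_dataset(small_config(40), seed = 7)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds$spectra, p2)
  back <- read_spectra(p2)
  expect_equal(as.data.frame(back), as.data.frame(ds$spectra))
})

test_that("malformed spectra files raise descriptive errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,species,origin,replicate,role,mc,1000,1002,1004,1006,1008",
    "A,Arabica,Aceh,1,calibration,10.5,0.1,0.2,0.3,0.4"
  ), path)
  expect_error(read_spectra(path), "row 2", class = "nirmc_format_error")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,species,origin,replicate,role,mc,1004,1002",
    "A,Arabica,Aceh,1,calibration,10.5,0.1,0.2"
  ), p2)
  expect_error(read_spectra(p2), class = "nirmc_grid_error")

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,species,origin,replicate,role,mc,1000,1002",
    "A,Arabica,Aceh,1,calibration,10.5,0.1,oops"
  ), p3)
  expect_error(read_spectra(p3), class = "nirmc_parse_error")

  expect_error(read_spectra("no/such/file.csv"), class = "nirmc_io_error")
})

test_that("JCAMP-DX-like single spectra are read onto a sorted nm grid", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=bean42", "##XUNITS=NANOMETERS", "##XYDATA=(X,Y)",
    "1000, 0.10", "1004, 0.30", "1002, 0.20", "##END="
  ), path)
  x <- read_spectra(path, dialect = "jcampdx")
  expect_equal(x$sample_id, "bean42")
  expect_equal(spectra_wavelengths(x), c(1000, 1002, 1004))
  expect_equal(unname(spectra_matrix(x)[1, ]), c(0.1, 0.2, 0.3))
})

test_that("replicate averaging is the arithmetic mean and guards metadata", {
  x <- toy_spectra(rbind(c(0, 0), c(2, 2), c(4, 4)), wl = c(1000, 1002))
  x$sample_id <- "S1"
  x$replicate <- 1:3
  avg <- average_replicates(x)
  expect_equal(nrow(avg), 1)
  expect_equal(unname(spectra_matrix(avg)[1, ]), c(2, 2))

  same <- toy_spectra(rbind(c(1, 2), c(1, 2), c(1, 2)), wl = c(1000, 1002))
  same$sample_id <- "S1"
  expect_equal(unname(spectra_matrix(average_replicates(same))[1, ]), c(1, 2))

  bad <- x
  bad$species <- c("Arabica", "Robusta", "Arabica")
  expect_error(average_replicates(bad), class = "nirmc_consistency_error")
})

test_that("origin-based splitting assigns roles and validates its inputs", {
  ds <- simulate_dataset(small_config(40), seed = 1)
  avg <- average_replicates(ds$spectra)
  ot <- default_origin_table()
  relabeled <- dplyr::mutate(avg, role = "unassigned")
  split <- split_by_origin(relabeled,
                           ot$origin[ot$role == "calibration"],
                           ot$origin[ot$role == "validation"])
  expect_equal(dplyr::n_distinct(calibration(split)$origin), 7)
  expect_equal(dplyr::n_distinct(validation(split)$origin), 5)
  expect_equal(nrow(calibration(split)) + nrow(validation(split)), nrow(avg))
  expect_equal(split$role, avg$role)  # recovers the generated design

  expect_error(split_by_origin(relabeled, c("Bali", "Aceh"), c("Bali")),
               class = "nirmc_argument_error")
  expect_error(split_by_origin(relabeled, c("Bali"), character(0)),
               class = "nirmc_coverage_error")
  all_cal <- split_by_origin(relabeled, unique(avg$origin), character(0))
  expect_equal(nrow(validation(all_cal)), 0)
})

test_that("averaging and origin splitting commute", {
  ds <- simulate_dataset(small_config(40), seed = 5)
  x <- dplyr::mutate(ds$spectra, role = "unassigned")
  ot <- default_origin_table()
  cal_o <- ot$origin[ot$role == "calibration"]
  val_o <- ot$origin[ot$role == "validation"]
  a <- split_by_origin(average_replicates(x), cal_o, val_o)
  b <- average_replicates(split_by_origin(x, cal_o, val_o))
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("wavelength subsetting picks nearest grid columns, no interpolation", {
  ds <- simulate_dataset(small_config(), seed = 2)
  avg <- average_replicates(ds$spectra)
  # the reduced 160-point test grid is ~5-19 nm spaced, so allow a wider match
  sub <- subset_wavelengths(avg, wl7, tolerance = 15)
  expect_equal(ncol(spectra_matrix(sub)), 7)
  wl <- spectra_wavelengths(avg)
  for (j in seq_along(wl7)) {
    d <- abs(wl - wl7[j])
    expect_equal(spectra_matrix(sub)[, j], spectra_matrix(avg)[, which.min(d)])
  }

  tie <- toy_spectra(c(0.1, 0.2, 0.3), wl = c(1154, 1156, 1200))
  matched <- subset_wavelengths(tie, c(1155, 1200), tolerance = 2)
  expect_equal(spectra_wavelengths(matched), c(1154, 1200))  # tie toward lower nm

  expect_error(subset_wavelengths(avg, 900, tolerance = 2),
               class = "nirmc_lookup_error")
})
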