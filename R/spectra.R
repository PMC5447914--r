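#' Default instrument wavelength grid
#'
#' The benchtop FT-NIR emulated here samples uniformly in wavenumber, as
#' Fourier-transform instruments do. The default grid has 1557 points spanning
#' 1000--2500 nm: wavenumbers run uniformly from 10000 to 4000 cm^-1 and are
#' converted to nm, which reconciles the nominal nm range with the instrument's
#' constant-wavenumber sampling. Wavelengths are rounded to 4 decimal places
#' (0.1 pm, far below any optical resolution) so that grids survive text
#' round-trips exactly.
#'
#' @param n Number of grid points (default 1557).
#' @param range Wavelength range in nm (default `c(1000, 2500)`).
#' @return Numeric vector of strictly increasing wavelengths in nm.
#' @export
#' @examples
#' wl <- default_grid()
#' length(wl)
#' range(wl)
default_grid <- function(n = 1557, range = c(1000, 2500)) {
  if (n < 2) abort("grid needs at least 2 points", class = "nirmc_grid_error")
  nu <- seq(1e7 / range[1], 1e7 / range[2], length.out = n)
  round(1e7 / nu, 4)
}

check_grid <- function(wl) {
  if (length(wl) < 2 || anyNA(wl) || any(diff(wl) <= 0)) {
    abort("wavelength grid must be strictly increasing with >= 2 points",
          class = "nirmc_grid_error")
  }
  invisible(wl)
}

#' Build a spectra tibble
#'
#' A spectra set is an ordinary tibble: the metadata columns `sample_id`,
#' `species`, `origin`, `replicate`, `role`, `mc` followed by one numeric
#' column per wavelength, named by the wavelength in nm. All `nirmc` functions
#' that take spectra accept and return this shape, so sets compose with dplyr
#' verbs and the pipe.
#'
#' @param absorbance Numeric matrix of log(1/R) values, one row per
#'   sample-replicate, columns in grid order.
#' @param wavelengths Strictly increasing wavelengths in nm, one per column.
#' @param sample_id,species,origin,replicate,role,mc Per-row metadata;
#'   recycled where length 1. `role` is one of `"calibration"`,
#'   `"validation"`, `"unassigned"`; `mc` is the reference moisture content in
#'   % wet basis (NA when not measured).
#' @return A tibble with `nrow(absorbance)` rows.
#' @export
spectra_tbl <- function(absorbance, wavelengths,
                        sample_id, species = NA_character_,
                        origin = NA_character_, replicate = 1L,
                        role = "unassigned", mc = NA_real_) {
  absorbance <- rbind(absorbance)
  check_grid(wavelengths)
  if (ncol(absorbance) != length(wavelengths)) {
    abort("absorbance columns must match wavelength grid length",
          class = "nirmc_shape_error")
  }
  if (!all(is.finite(absorbance))) {
    abort("absorbance values must all be finite", class = "nirmc_value_error")
  }
  n <- nrow(absorbance)
  meta <- tibble::tibble(
    sample_id = rep_len(as.character(sample_id), n),
    species   = rep_len(as.character(species), n),
    origin    = rep_len(as.character(origin), n),
    replicate = rep_len(as.integer(replicate), n),
    role      = rep_len(as.character(role), n),
    mc        = rep_len(as.numeric(mc), n)
  )
  bad <- setdiff(unique(meta$role), c("calibration", "validation", "unassigned"))
  if (length(bad)) {
    abort(paste0("unknown role(s): ", paste(bad, collapse = ", ")),
          class = "nirmc_value_error")
  }
  abs_tbl <- tibble::as_tibble(absorbance, .name_repair = "minimal")
  names(abs_tbl) <- as.character(wavelengths)
  dplyr::bind_cols(meta, abs_tbl)
}

#' Spectra tibble accessors
#'
#' `spectra_wavelengths()` returns the wavelength grid (nm) encoded in the
#' column names; `spectra_matrix()` the absorbance matrix; `spectra_meta()`
#' the metadata columns.
#'
#' @param x A spectra tibble (see [spectra_tbl()]).
#' @return A numeric vector, numeric matrix, or tibble respectively.
#' @export
spectra_wavelengths <- function(x) {
  wl_cols <- setdiff(names(x), META_COLS)
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) {
    abort("non-wavelength extra columns present in spectra tibble",
          class = "nirmc_shape_error")
  }
  wl
}

#' @rdname spectra_wavelengths
#' @export
spectra_matrix <- function(x) {
  wl_cols <- setdiff(names(x), META_COLS)
  m <- as.matrix(x[, wl_cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

#' @rdname spectra_wavelengths
#' @export
spectra_meta <- function(x) {
  x[, intersect(META_COLS, names(x)), drop = FALSE]
}

# replace absorbance values, keeping metadata; optionally a new grid
set_spectra_matrix <- function(x, m, wavelengths = spectra_wavelengths(x)) {
  spectra_tbl(m, wavelengths,
              sample_id = x$sample_id, species = x$species,
              origin = x$origin, replicate = x$replicate,
              role = x$role, mc = x$mc)
}

#' Read and write spectra files
#'
#' The canonical on-disk format is a wide CSV whose header is
#' `sample_id,species,origin,replicate,role,mc` followed by one column per
#' wavelength (nm), UTF-8, `.` decimal separator. A minimal JCAMP-DX-like
#' reader (`##XUNITS=NANOMETERS`, `##XYDATA` x,y pairs) is provided for single
#' spectra; writing always emits the wide CSV dialect.
#'
#' @param path File to read or write.
#' @param dialect `"wide_csv"` (default) or `"jcampdx"`.
#' @param x A spectra tibble.
#' @return `read_spectra()` returns a spectra tibble; `write_spectra()`
#'   returns `x` invisibly.
#' @export
read_spectra <- function(path, dialect = c("wide_csv", "jcampdx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "nirmc_io_error")
  }
  if (dialect == "jcampdx") return(read_jcampdx(path))

  counts <- readr::count_fields(path, readr::tokenizer_csv())
  if (length(counts) < 2) {
    abort("wide CSV needs a header row and at least one data row",
          class = "nirmc_format_error")
  }
  ragged <- which(counts[-1] != counts[1])
  if (length(ragged)) {
    abort(sprintf("ragged CSV: row %d has %d fields, header has %d",
                  ragged[1] + 1L, counts[ragged[1] + 1L], counts[1]),
          class = "nirmc_format_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  if (!identical(header[seq_along(META_COLS)], META_COLS)) {
    abort("wide CSV header must start with sample_id,species,origin,replicate,role,mc",
          class = "nirmc_format_error")
  }
  wl <- suppressWarnings(as.numeric(header[-seq_along(META_COLS)]))
  if (anyNA(wl)) {
    abort("non-numeric wavelength column in header", class = "nirmc_format_error")
  }
  check_grid(wl)
  # readr warns about parsing problems; they are re-raised as errors below
  df <- suppressWarnings(readr::read_csv(
    path, show_col_types = FALSE,
    col_types = do.call(readr::cols, c(
      list(sample_id = readr::col_character(), species = readr::col_character(),
           origin = readr::col_character(), replicate = readr::col_integer(),
           role = readr::col_character(), mc = readr::col_double()),
      stats::setNames(rep(list(readr::col_double()),
                          length(header) - length(META_COLS)),
                      header[-seq_along(META_COLS)])
    ))
  ))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(sprintf("non-numeric absorbance value at file row %d", probs$row[1]),
          class = "nirmc_parse_error")
  }
  m <- as.matrix(df[, -seq_along(META_COLS), drop = FALSE])
  spectra_tbl(m, wl, sample_id = df$sample_id, species = df$species,
              origin = df$origin, replicate = df$replicate,
              role = df$role, mc = df$mc)
}

read_jcampdx <- function(path) {
  lines <- readr::read_lines(path)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^##", key, "="), "", hit[1]))
  }
  xunits <- get_field("XUNITS")
  if (!is.na(xunits) && toupper(xunits) != "NANOMETERS") {
    abort("only XUNITS=NANOMETERS is supported", class = "nirmc_format_error")
  }
  start <- grep("^##XYDATA", lines)
  if (!length(start)) {
    abort("no ##XYDATA block found", class = "nirmc_format_error")
  }
  stop_at <- grep("^##END", lines)
  stop_at <- if (length(stop_at)) min(stop_at[stop_at > start[1]]) else length(lines) + 1L
  body <- lines[seq(start[1] + 1L, stop_at - 1L)]
  body <- body[nzchar(trimws(body))]
  pairs <- do.call(rbind, lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[,;[:space:]]+")[[1]]))
    if (length(v) != 2 || anyNA(v)) {
      abort(paste0("malformed XYDATA line: ", l), class = "nirmc_parse_error")
    }
    v
  }))
  ord <- order(pairs[, 1])
  title <- get_field("TITLE")
  spectra_tbl(matrix(pairs[ord, 2], nrow = 1), pairs[ord, 1],
              sample_id = if (is.na(title)) "jcamp" else title)
}

#' @rdname read_spectra
#' @export
write_spectra <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' Average replicate spectra
#'
#' The instrument records several replicate spectra per sample; these are
#' averaged before any modelling. Metadata (`species`, `origin`, `role`, `mc`)
#' must be constant within each `sample_id` and is carried through;
#' `replicate` becomes 1.
#'
#' @param x A spectra tibble with >= 1 row per `sample_id`.
#' @return A spectra tibble with one row per `sample_id`, absorbance the
#'   arithmetic mean over that sample's replicates, in first-appearance order.
#' @export
average_replicates <- function(x) {
  wl <- spectra_wavelengths(x)
  consistent <- x |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species),
      n_origin = dplyr::n_distinct(.data$origin),
      n_role = dplyr::n_distinct(.data$role),
      n_mc = dplyr::n_distinct(.data$mc),
      .by = "sample_id"
    )
  bad <- consistent |>
    dplyr::filter(.data$n_species > 1 | .data$n_origin > 1 |
                    .data$n_role > 1 | .data$n_mc > 1)
  if (nrow(bad)) {
    abort(paste0("inconsistent metadata within sample_id: ",
                 paste(bad$sample_id, collapse = ", ")),
          class = "nirmc_consistency_error")
  }
  m <- spectra_matrix(x)
  ids <- unique(x$sample_id)
  avg <- t(vapply(ids, function(id) colMeans(m[x$sample_id == id, , drop = FALSE]),
                  numeric(ncol(m))))
  first <- x[match(ids, x$sample_id), ]
  spectra_tbl(avg, wl, sample_id = ids, species = first$species,
              origin = first$origin, replicate = 1L,
              role = first$role, mc = first$mc)
}

#' Assign calibration/validation roles by origin
#'
#' The study design splits samples into calibration and validation subsets by
#' geographic origin. The two origin lists must be disjoint and jointly cover
#' every origin present.
#'
#' @param x A spectra tibble.
#' @param cal_origins,val_origins Character vectors of origin labels.
#' @return The spectra tibble with its `role` column set to `"calibration"` or
#'   `"validation"`; use [calibration()] / [validation()] to extract subsets.
#' @export
split_by_origin <- function(x, cal_origins, val_origins) {
  overlap <- intersect(cal_origins, val_origins)
  if (length(overlap)) {
    abort(paste0("origin lists overlap: ", paste(overlap, collapse = ", ")),
          class = "nirmc_argument_error")
  }
  missing <- setdiff(unique(x$origin), c(cal_origins, val_origins))
  if (length(missing)) {
    abort(paste0("origin(s) not covered by either list: ",
                 paste(missing, collapse = ", ")),
          class = "nirmc_coverage_error")
  }
  dplyr::mutate(x, role = ifelse(.data$origin %in% cal_origins,
                                 "calibration", "validation"))
}

#' @rdname split_by_origin
#' @export
calibration <- function(x) dplyr::filter(x, .data$role == "calibration")

#' @rdname split_by_origin
#' @export
validation <- function(x) dplyr::filter(x, .data$role == "validation")

#' Extract selected wavelength columns
#'
#' Picks, for each target wavelength, the nearest grid point within
#' `tolerance` (ties broken toward the lower wavelength) and returns the set
#' restricted to those columns, in target order. No interpolation is done.
#'
#' @param x A spectra tibble.
#' @param targets Wavelengths to extract, nm.
#' @param tolerance Maximum allowed distance to the nearest grid point, nm.
#' @return A spectra tibble whose grid is the matched points in target order.
#' @export
subset_wavelengths <- function(x, targets, tolerance = 2) {
  wl <- spectra_wavelengths(x)
  idx <- vapply(targets, function(t) {
    d <- abs(wl - t)
    i <- which(d == min(d))[1]  # ties: lower wavelength wins (wl increasing)
    if (d[i] > tolerance) {
      abort(sprintf("no grid point within %g nm of target %g nm", tolerance, t),
            class = "nirmc_lookup_error")
    }
    i
  }, integer(1))
  if (any(diff(wl[idx]) <= 0)) {
    abort("matched wavelengths must be strictly increasing; reorder targets",
          class = "nirmc_grid_error")
  }
  m <- spectra_matrix(x)[, idx, drop = FALSE]
  set_spectra_matrix(x, m, wavelengths = wl[idx])
}
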