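#' Construct a dual-channel SHG/TPEF slide
#'
#' Holds the two co-registered rasters acquired from one biopsy section:
#' the second-harmonic generation (SHG) channel, in which fibrillar collagen
#' emits at half the 780 nm excitation wavelength (390 nm), and the
#' two-photon excited fluorescence (TPEF) channel (550 nm) showing tissue
#' autofluorescence. Intensities are stored as numeric matrices; any
#' non-negative scale is accepted.
#'
#' @param shg Numeric matrix, SHG (collagen) intensities, all finite and >= 0.
#' @param tpef Numeric matrix of identical dimensions, TPEF (tissue)
#'   intensities.
#' @param calibration A [calibration()] object.
#' @param sample_id Character scalar identifying the sample.
#' @param acquisition_meta Optional named list of acquisition metadata
#'   (excitation/emission wavelengths etc.); carried along, never interpreted.
#' @return An object of class `qfib_slide`.
#' @export
dual_channel_slide <- function(shg, tpef, calibration = qfib::calibration(),
                               sample_id = "sample",
                               acquisition_meta = list(excitation_nm = 780,
                                                       shg_nm = 390,
                                                       tpef_nm = 550)) {
  shg <- as_intensity_matrix(shg, "shg")
  tpef <- as_intensity_matrix(tpef, "tpef")
  if (!identical(dim(shg), dim(tpef))) {
    stop("shg and tpef must have identical dimensions")
  }
  stopifnot(inherits(calibration, "qfib_calibration"))
  structure(
    list(shg = shg, tpef = tpef, calibration = calibration,
         sample_id = as.character(sample_id),
         acquisition_meta = acquisition_meta),
    class = "qfib_slide"
  )
}

as_intensity_matrix <- function(x, what) {
  if (!is.matrix(x)) stop(what, " must be a matrix")
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop(what, " intensities must all be finite")
  if (any(x < 0)) stop(what, " intensities must be non-negative")
  x
}

#' @export
print.qfib_slide <- function(x, ...) {
  cat(sprintf("<qfib_slide> '%s' %d x %d px (%.1f x %.1f um), SHG max %.3g, TPEF max %.3g\n",
              x$sample_id, nrow(x$shg), ncol(x$shg),
              nrow(x$shg) * x$calibration$microns_per_pixel,
              ncol(x$shg) * x$calibration$microns_per_pixel,
              max(x$shg), max(x$tpef)))
  invisible(x)
}

#' @export
dim.qfib_slide <- function(x) dim(x$shg)

#' Read a calibrated dual-channel slide from TIFF
#'
#' Accepts either a single TIFF whose first two samples per pixel are the
#' SHG and TPEF channels (in that order), or a character vector of two
#' single-channel TIFF paths `c(shg, tpef)`.
#'
#' @param image_path Path to a >= 2-channel TIFF, or a length-2 character
#'   vector of single-channel TIFF paths (SHG first, TPEF second).
#' @param calibration A [calibration()] object (default 0.390625 um/px).
#' @param sample_id Sample identifier; defaults to the file name sans
#'   extension.
#' @return A `qfib_slide`.
#' @export
read_slide <- function(image_path, calibration = qfib::calibration(),
                       sample_id = NULL) {
  for (p in image_path) {
    if (!file.exists(p)) stop("image file not found: ", p)
  }
  if (length(image_path) == 2L) {
    shg <- read_tiff_channel(image_path[[1]])
    tpef <- read_tiff_channel(image_path[[2]])
    if (is.null(sample_id)) {
      sample_id <- tools::file_path_sans_ext(basename(image_path[[1]]))
    }
    return(dual_channel_slide(shg, tpef, calibration, sample_id))
  }
  img <- suppressWarnings(tiff::readTIFF(image_path))
  if (length(dim(img)) < 3L || dim(img)[3] < 2L) {
    stop("channel count < 2: '", image_path,
         "' has a single channel; supply c(shg_path, tpef_path) instead")
  }
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(image_path))
  }
  dual_channel_slide(img[, , 1], img[, , 2], calibration, sample_id)
}

read_tiff_channel <- function(path) {
  img <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write a dual-channel slide as a 2-sample TIFF
#'
#' Intensities are rescaled to \[0, 1\] by `scale_max` (default: the larger
#' channel maximum, or 1 for an all-zero slide) and stored at 16 bits.
#'
#' @param slide A `qfib_slide`.
#' @param path Output TIFF path.
#' @param scale_max Intensity mapped to full scale.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path, scale_max = NULL) {
  stopifnot(inherits(slide, "qfib_slide"))
  if (is.null(scale_max)) scale_max <- max(slide$shg, slide$tpef, 1e-12)
  arr <- array(0, c(dim(slide$shg), 2L))
  arr[, , 1] <- pmin(slide$shg / scale_max, 1)
  arr[, , 2] <- pmin(slide$tpef / scale_max, 1)
  tiff::writeTIFF(arr, path, bits.per.sample = 16L)
  invisible(path)
}

#' Stitch a grid of image tiles into one mosaic slide
#'
#' Tiles are assumed pre-aligned and abutting (no overlap, no blending),
#' supplied in row-major order with the origin at the top-left tile.
#'
#' @param tiles List of `qfib_slide` tiles sharing dimensions and calibration.
#' @param grid_shape Integer vector `c(rows, cols)`.
#' @return A `qfib_slide` mosaic of dimensions
#'   `(rows * tile_rows, cols * tile_cols)`.
#' @export
stitch_tiles <- function(tiles, grid_shape) {
  stopifnot(length(grid_shape) == 2L)
  rows <- as.integer(grid_shape[1]); cols <- as.integer(grid_shape[2])
  if (length(tiles) != rows * cols) {
    stop("tile count (", length(tiles), ") != rows * cols (", rows * cols, ")")
  }
  d0 <- dim(tiles[[1]]$shg)
  cal <- tiles[[1]]$calibration
  for (t in tiles) {
    if (!identical(dim(t$shg), d0)) stop("tile shape mismatch")
    if (!same_calibration(t$calibration, cal)) stop("tile calibration mismatch")
  }
  shg <- matrix(0, rows * d0[1], cols * d0[2])
  tpef <- matrix(0, rows * d0[1], cols * d0[2])
  k <- 0L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      k <- k + 1L
      ri <- (r - 1L) * d0[1] + seq_len(d0[1])
      ci <- (cc - 1L) * d0[2] + seq_len(d0[2])
      shg[ri, ci] <- tiles[[k]]$shg
      tpef[ri, ci] <- tiles[[k]]$tpef
    }
  }
  dual_channel_slide(shg, tpef, cal, tiles[[1]]$sample_id)
}

#' Split a slide into an abutting grid of tiles
#'
#' Inverse of [stitch_tiles()] for slides whose dimensions are divisible by
#' the tile size.
#'
#' @param slide A `qfib_slide`.
#' @param tile_shape Integer vector `c(tile_rows, tile_cols)`.
#' @return List of tiles in row-major order.
#' @export
split_into_tiles <- function(slide, tile_shape) {
  d <- dim(slide$shg)
  tr <- as.integer(tile_shape[1]); tc <- as.integer(tile_shape[2])
  if (d[1] %% tr != 0L || d[2] %% tc != 0L) {
    stop("slide dimensions are not divisible by the tile size")
  }
  rows <- d[1] %/% tr; cols <- d[2] %/% tc
  tiles <- vector("list", rows * cols)
  k <- 0L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      k <- k + 1L
      ri <- (r - 1L) * tr + seq_len(tr)
      ci <- (cc - 1L) * tc + seq_len(tc)
      tiles[[k]] <- dual_channel_slide(slide$shg[ri, ci], slide$tpef[ri, ci],
                                       slide$calibration, slide$sample_id)
    }
  }
  tiles
}

#' Read a sample manifest
#'
#' The manifest is a CSV with columns `sample_id`, `stage_label` (one of
#' F0..F4), `group_label`, `image_path`, `portal_mask_path`. Relative paths
#' are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A data.frame of class `qfib_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "stage_label", "group_label",
                "image_path", "portal_mask_path")
  missing <- setdiff(required, names(m))
  if (length(missing)) stop("manifest missing columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("manifest sample_id values must be unique")
  bad <- setdiff(unique(m$stage_label), c("F0", "F1", "F2", "F3", "F4"))
  if (length(bad)) stop("unknown stage_label(s): ", paste(bad, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (col in c("image_path", "portal_mask_path")) {
    rel <- !is.na(m[[col]]) & nzchar(m[[col]]) &
      !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  class(m) <- c("qfib_manifest", "data.frame")
  m
}

#' Write a cohort parameter table
#'
#' One row per sample, a `sample_id` column followed by the 56 parameter
#' columns in canonical schema order. Values are written at full double
#' precision so that a write/read round trip is lossless to 1e-12 relative.
#'
#' @param vectors List of `qfib_params` objects (see [compute_parameters()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(vectors, path) {
  schema <- parameter_schema()
  rows <- lapply(vectors, function(v) {
    stopifnot(inherits(v, "qfib_params"))
    if (!identical(names(v$values), schema)) {
      stop("parameter vector for sample '", v$sample_id,
           "' does not match the 56-name schema")
    }
    v
  })
  df <- as.data.frame(
    matrix(NA_real_, nrow = length(rows), ncol = length(schema),
           dimnames = list(NULL, schema)),
    check.names = FALSE
  )
  for (i in seq_along(rows)) df[i, ] <- unname(rows[[i]]$values)
  df <- cbind(data.frame(sample_id = vapply(rows, function(v) v$sample_id,
                                            character(1))),
              df)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a cohort parameter table written by [write_parameter_table()]
#'
#' @param path CSV path.
#' @return data.frame with `sample_id` plus the 56 parameter columns.
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  schema <- parameter_schema()
  missing <- setdiff(schema, names(df))
  if (length(missing)) stop("parameter table missing columns: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  for (p in schema) df[[p]] <- as.numeric(df[[p]])
  df
}

#' Read a binary mask image (PNG or TIFF)
#'
#' Any nonzero pixel is inside the mask.
#'
#' @param path Mask image path.
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    suppressWarnings(tiff::readTIFF(path))
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}

#' Write a binary mask as an 8-bit PNG (nonzero = inside)
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}
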