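#' Spatial calibration of a slide
#'
#' A calibration ties pixel coordinates to physical micrometres. Acquisition
#' for this pipeline uses 512 x 512 px tiles covering 200 x 200 um, i.e. an
#' isotropic scale of 200/512 = 0.390625 um/px; that is the package default.
#'
#' @param microns_per_pixel Isotropic pixel size in um/px. If missing it is
#'   derived as `tile_microns / tile_pixels`.
#' @param tile_pixels Tile edge length in pixels (default 512).
#' @param tile_microns Tile edge length in micrometres (default 200).
#' @return An object of class `qfib_calibration` with fields
#'   `microns_per_pixel`, `tile_pixels`, `tile_microns`.
#' @examples
#' calibration()                      # 0.390625 um/px
#' calibration(microns_per_pixel = 1)
#' @export
calibration <- function(microns_per_pixel = NULL, tile_pixels = 512L,
                        tile_microns = 200) {
  tile_pixels <- as.integer(tile_pixels)
  if (is.null(microns_per_pixel)) {
    stopifnot(tile_pixels > 0L, tile_microns > 0)
    microns_per_pixel <- tile_microns / tile_pixels
  }
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("microns_per_pixel must be a single positive finite number")
  }
  if (!is.null(tile_pixels) && !is.null(tile_microns)) {
    implied <- tile_microns / tile_pixels
    if (abs(implied - microns_per_pixel) > 1e-9 * max(implied, microns_per_pixel)) {
      stop("calibration inconsistent: microns_per_pixel (", microns_per_pixel,
           ") != tile_microns / tile_pixels (", implied, ")")
    }
  }
  structure(
    list(microns_per_pixel = as.numeric(microns_per_pixel),
         tile_pixels = tile_pixels,
         tile_microns = as.numeric(tile_microns)),
    class = "qfib_calibration"
  )
}

#' @export
print.qfib_calibration <- function(x, ...) {
  cat(sprintf("<qfib_calibration> %g um/px (tile %d px = %g um)\n",
              x$microns_per_pixel, x$tile_pixels, x$tile_microns))
  invisible(x)
}

# um^2 covered by one pixel
px_area_um2 <- function(cal) cal$microns_per_pixel^2

# convert an area threshold in um^2 to a pixel count (can be fractional)
um2_to_px <- function(area_um2, cal) area_um2 / px_area_um2(cal)

same_calibration <- function(a, b, tol = 1e-9) {
  abs(a$microns_per_pixel - b$microns_per_pixel) <=
    tol * max(a$microns_per_pixel, b$microns_per_pixel)
}
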