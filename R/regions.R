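#' Region-construction configuration
#'
#' The periportal region is the radial margin around portal tracts within
#' which periportal fibrosis is scored; its default width is 100 um,
#' measured as Euclidean distance from the portal-tract boundary.
#'
#' @param periportal_margin_um Margin width in micrometres (> 0).
#' @return A list of class `qfib_region_config`.
#' @export
region_config <- function(periportal_margin_um = 100) {
  stopifnot(is.numeric(periportal_margin_um),
            length(periportal_margin_um) == 1L, periportal_margin_um > 0)
  structure(list(periportal_margin_um = as.numeric(periportal_margin_um)),
            class = "qfib_region_config")
}

#' Euclidean distance to the portal-tract mask, in micrometres
#'
#' For every pixel, the exact Euclidean distance (on the pixel grid,
#' converted through the calibration) to the nearest portal pixel; 0
#' inside the portal, `Inf` everywhere when the portal mask is empty.
#' When `max_um` is given, distances are only resolved up to that bound
#' (farther pixels report `Inf`), which lets the computation run on a
#' window around the portal bounding box.
#'
#' @param portal Logical portal mask (or `qfib_mask`).
#' @param cal A [calibration()] object.
#' @param max_um Optional distance bound in micrometres.
#' @return Numeric matrix of distances in micrometres.
#' @export
portal_distance_um <- function(portal, cal, max_um = NULL) {
  pm <- if (inherits(portal, "qfib_mask")) portal$mask else (portal > 0)
  if (!any(pm)) {
    return(matrix(Inf, nrow(pm), ncol(pm)))
  }
  mpp <- cal$microns_per_pixel
  if (is.null(max_um)) {
    d <- EBImage::distmap(1 - pm, metric = "euclidean")
    return(as.matrix(d) * mpp)
  }
  pad <- ceiling(max_um / mpp) + 3L
  w <- which(pm, arr.ind = TRUE)
  r0 <- max(1L, min(w[, 1]) - pad); r1 <- min(nrow(pm), max(w[, 1]) + pad)
  c0 <- max(1L, min(w[, 2]) - pad); c1 <- min(ncol(pm), max(w[, 2]) + pad)
  sub <- EBImage::distmap(1 - pm[r0:r1, c0:c1, drop = FALSE],
                          metric = "euclidean")
  out <- matrix(Inf, nrow(pm), ncol(pm))
  out[r0:r1, c0:c1] <- as.matrix(sub) * mpp
  out
}

#' Build the periportal region mask
#'
#' The periportal region is every tissue pixel whose Euclidean distance to
#' the portal-tract mask lies in `(0, margin]`, i.e. a radial margin of
#' `periportal_margin_um` around each portal tract, clipped to tissue and
#' excluding the tract itself. Margins of nearby tracts merge by set union.
#' Distances are measured on the pixel grid and converted to micrometres
#' through the calibration, so the boundary is inclusive at the margin.
#'
#' @param portal Portal `qfib_mask` (or logical matrix).
#' @param tissue Tissue `qfib_mask` (or logical matrix); must be non-empty.
#' @param cfg A [region_config()].
#' @param calibration Required when masks are plain matrices.
#' @return Logical matrix: the periportal mask.
#' @export
build_periportal <- function(portal, tissue, cfg = region_config(),
                             calibration = NULL) {
  pm <- as_mask_matrix(portal)
  tm <- as_mask_matrix(tissue)
  cal <- mask_calibration(portal, tissue, calibration)
  if (!identical(dim(pm), dim(tm))) stop("portal and tissue mask shape mismatch")
  if (!any(tm)) stop("no tissue")
  if (!any(pm)) return(matrix(FALSE, nrow(pm), ncol(pm)))
  d <- portal_distance_um(pm, cal, max_um = cfg$periportal_margin_um)
  d > 0 & d <= cfg$periportal_margin_um & tm & !pm
}

#' Build the reduced perisinusoidal (RPS) region mask
#'
#' The perisinusoidal compartment that remains after carving the portal
#' tracts and the periportal margin out of tissue:
#' `rps = tissue - portal - periportal`.
#'
#' @param tissue Tissue `qfib_mask` or logical matrix.
#' @param portal Portal logical matrix.
#' @param periportal Periportal logical matrix.
#' @return Logical matrix: the RPS mask.
#' @export
build_rps <- function(tissue, portal, periportal) {
  tm <- as_mask_matrix(tissue)
  tm & !as_mask_matrix(portal) & !as_mask_matrix(periportal)
}

#' Partition tissue into portal / periportal / RPS regions
#'
#' Produces the mutually exclusive trichotomy used by all downstream
#' parameters: the portal tracts, the periportal margin around them, and
#' the reduced perisinusoidal remainder. The three masks are pairwise
#' disjoint and their union is exactly the tissue mask.
#'
#' @param slide A `qfib_slide` (provides calibration).
#' @param tissue Tissue `qfib_mask`.
#' @param portal Portal `qfib_mask`.
#' @param cfg A [region_config()].
#' @return An object of class `qfib_regions` with logical matrices
#'   `portal`, `periportal`, `rps`, `tissue` and the calibration.
#' @export
partition_regions <- function(slide, tissue, portal, cfg = region_config()) {
  cal <- slide$calibration
  tm <- as_mask_matrix(tissue)
  pm <- as_mask_matrix(portal) & tm   # portal clipped to tissue
  pp <- build_periportal(pm, tm, cfg, calibration = cal)
  rps <- build_rps(tm, pm, pp)
  structure(list(portal = pm, periportal = pp, rps = rps, tissue = tm,
                 calibration = cal,
                 periportal_margin_um = cfg$periportal_margin_um),
            class = "qfib_regions")
}

#' @export
print.qfib_regions <- function(x, ...) {
  a <- px_area_um2(x$calibration)
  cat(sprintf(paste0("<qfib_regions> %d x %d px, margin %g um\n",
                     "  portal:     %8d px (%.0f um^2)\n",
                     "  periportal: %8d px (%.0f um^2)\n",
                     "  rps:        %8d px (%.0f um^2)\n"),
              nrow(x$tissue), ncol(x$tissue), x$periportal_margin_um,
              sum(x$portal), sum(x$portal) * a,
              sum(x$periportal), sum(x$periportal) * a,
              sum(x$rps), sum(x$rps) * a))
  invisible(x)
}

#' Region areas in square micrometres
#'
#' @param regions A `qfib_regions`.
#' @return Named numeric vector with `portal`, `periportal`, `rps`,
#'   `tissue` areas (um^2).
#' @export
region_areas_um2 <- function(regions) {
  a <- px_area_um2(regions$calibration)
  c(portal = sum(regions$portal) * a,
    periportal = sum(regions$periportal) * a,
    rps = sum(regions$rps) * a,
    tissue = sum(regions$tissue) * a)
}

#' Export a region partition as an indexed PNG
#'
#' Pixel codes: 0 = background, 1 = portal, 2 = periportal, 3 = RPS,
#' stored as 8-bit grey values `code / 255`.
#'
#' @param regions A `qfib_regions`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_region_png <- function(regions, path) {
  code <- matrix(0, nrow(regions$tissue), ncol(regions$tissue))
  code[regions$portal] <- 1
  code[regions$periportal] <- 2
  code[regions$rps] <- 3
  png::writePNG(code / 255, path)
  invisible(path)
}

#' Read a region partition written by [write_region_png()]
#'
#' @param path PNG path.
#' @param calibration A [calibration()] object.
#' @param periportal_margin_um Margin recorded with the partition.
#' @return A `qfib_regions`.
#' @export
read_region_png <- function(path, calibration = qfib::calibration(),
                            periportal_margin_um = 100) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  code <- round(img * 255)
  structure(list(portal = code == 1, periportal = code == 2,
                 rps = code == 3, tissue = code > 0,
                 calibration = calibration,
                 periportal_margin_um = periportal_margin_um),
            class = "qfib_regions")
}

as_mask_matrix <- function(x) {
  if (inherits(x, "qfib_mask")) x$mask else (x > 0)
}

mask_calibration <- function(a, b, calibration) {
  if (inherits(a, "qfib_mask")) return(a$calibration)
  if (inherits(b, "qfib_mask")) return(b$calibration)
  if (is.null(calibration)) stop("calibration required with plain-matrix masks")
  calibration
}
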