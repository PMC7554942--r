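#' Segmentation configuration
#'
#' Controls how the collagen (SHG) and tissue (TPEF) masks are extracted.
#' Collagen is thresholded on the SHG channel restricted to tissue pixels;
#' the default method is Otsu's parameter-free threshold, with fixed-value
#' and percentile overrides. Tissue is thresholded on a Gaussian-smoothed
#' TPEF channel, with small interior holes filled.
#'
#' @param collagen_threshold_method One of `"otsu"`, `"fixed"`, `"percentile"`.
#' @param collagen_threshold For `"fixed"`: absolute intensity; for
#'   `"percentile"`: percentile in \[0, 100\] of tissue-restricted SHG.
#' @param min_object_area_um2 Collagen components smaller than this (um^2)
#'   are removed. Default 0.5 um^2.
#' @param min_separability Guard for automatic (Otsu) collagen
#'   thresholding: the threshold is only accepted when its between-class /
#'   total variance ratio (Otsu's effectiveness eta) reaches this value,
#'   otherwise the channel is declared signal-free and the mask is empty.
#'   A detector-noise-only SHG channel (clipped Gaussian) has eta ~ 0.75
#'   regardless of the noise level, while any genuine collagen signal is
#'   strongly bimodal (eta >= 0.9); the default 0.8 sits between the two
#'   regimes.
#' @param tissue_sigma_px Gaussian sigma (px) applied to TPEF before
#'   thresholding. Default 2.
#' @param fill_holes_um2 Background holes inside tissue up to this area
#'   (um^2) are filled. Default 500.
#' @param largest_component_only Keep only the largest tissue component.
#' @param portal_min_area_um2 Minimum blob area for the experimental
#'   heuristic portal detector. Default 2000 um^2.
#' @return A list of class `qfib_seg_config`.
#' @export
segmentation_config <- function(collagen_threshold_method = c("otsu", "fixed",
                                                              "percentile"),
                                collagen_threshold = NULL,
                                min_object_area_um2 = 0.5,
                                min_separability = 0.8,
                                tissue_sigma_px = 2,
                                fill_holes_um2 = 500,
                                largest_component_only = FALSE,
                                portal_min_area_um2 = 2000) {
  method <- match.arg(collagen_threshold_method)
  if (method != "otsu" && is.null(collagen_threshold)) {
    stop("collagen_threshold must be given for method '", method, "'")
  }
  stopifnot(min_object_area_um2 >= 0, tissue_sigma_px >= 0,
            fill_holes_um2 >= 0, portal_min_area_um2 > 0,
            min_separability >= 0, min_separability <= 1)
  structure(list(collagen_threshold_method = method,
                 collagen_threshold = collagen_threshold,
                 min_object_area_um2 = min_object_area_um2,
                 min_separability = min_separability,
                 tissue_sigma_px = tissue_sigma_px,
                 fill_holes_um2 = fill_holes_um2,
                 largest_component_only = largest_component_only,
                 portal_min_area_um2 = portal_min_area_um2),
            class = "qfib_seg_config")
}

#' Construct a named mask layer
#'
#' @param name One of `"collagen"`, `"tissue"`, `"portal"`.
#' @param mask Logical matrix (TRUE = inside).
#' @param calibration A [calibration()] object.
#' @return Object of class `qfib_mask`.
#' @export
mask_layer <- function(name = c("collagen", "tissue", "portal"), mask,
                       calibration = qfib::calibration()) {
  name <- match.arg(name)
  stopifnot(is.matrix(mask))
  structure(list(name = name, mask = mask > 0, calibration = calibration),
            class = "qfib_mask")
}

#' @export
print.qfib_mask <- function(x, ...) {
  cat(sprintf("<qfib_mask> '%s' %d x %d px, %d px inside (%.1f um^2)\n",
              x$name, nrow(x$mask), ncol(x$mask), sum(x$mask),
              sum(x$mask) * px_area_um2(x$calibration)))
  invisible(x)
}

#' Segment collagen from the SHG channel
#'
#' Thresholds the SHG channel restricted to tissue pixels (Otsu by default),
#' drops collagen falling outside tissue, and removes connected components
#' (8-connectivity) smaller than `min_object_area_um2`. An all-zero SHG
#' channel yields an empty mask.
#'
#' @param slide A `qfib_slide`.
#' @param cfg A [segmentation_config()].
#' @param tissue Optional tissue `qfib_mask`; computed by [segment_tissue()]
#'   when omitted.
#' @return A collagen `qfib_mask`.
#' @export
segment_collagen <- function(slide, cfg = segmentation_config(),
                             tissue = NULL) {
  stopifnot(inherits(slide, "qfib_slide"))
  if (is.null(tissue)) tissue <- segment_tissue(slide, cfg)
  tis <- tissue$mask
  shg <- slide$shg
  vals <- shg[tis]
  mask <- matrix(FALSE, nrow(shg), ncol(shg))
  if (length(vals) && max(vals) > 0) {
    thr <- switch(cfg$collagen_threshold_method,
      otsu = otsu_threshold(vals),
      fixed = cfg$collagen_threshold,
      percentile = stats::quantile(vals, cfg$collagen_threshold / 100,
                                   names = FALSE)
    )
    ok <- cfg$collagen_threshold_method != "otsu" ||
      otsu_eta(vals, thr) >= cfg$min_separability
    if (ok) {
      mask <- shg > thr & tis
      mask <- drop_small_components(mask, um2_to_px(cfg$min_object_area_um2,
                                                    slide$calibration))
    }
  }
  mask_layer("collagen", mask, slide$calibration)
}

# Otsu's threshold on a numeric vector, 256-bin histogram over the data range.
otsu_threshold <- function(vals) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(matrix(vals, nrow = 1L), range = rng, levels = 256L)
}

# Otsu effectiveness: between-class variance at the threshold over total
# variance; 0 when one class is empty
otsu_eta <- function(vals, thr) {
  lo <- vals <= thr
  w0 <- mean(lo); w1 <- 1 - w0
  if (w0 == 0 || w1 == 0) return(0)
  w0 * w1 * (mean(vals[!lo]) - mean(vals[lo]))^2 / stats::var(vals)
}

#' Segment tissue from the TPEF channel
#'
#' Gaussian-smooths TPEF (`tissue_sigma_px`), applies Otsu's threshold,
#' fills interior background holes up to `fill_holes_um2`, and optionally
#' keeps only the largest component. Degenerate channels are handled
#' directly: an all-zero TPEF gives an empty mask and a strictly uniform
#' positive TPEF gives a full-frame mask.
#'
#' @inheritParams segment_collagen
#' @return A tissue `qfib_mask`.
#' @export
segment_tissue <- function(slide, cfg = segmentation_config()) {
  stopifnot(inherits(slide, "qfib_slide"))
  tpef <- slide$tpef
  rng <- range(tpef)
  if (rng[2] == 0) {
    return(mask_layer("tissue", matrix(FALSE, nrow(tpef), ncol(tpef)),
                      slide$calibration))
  }
  if (diff(rng) == 0) {
    return(mask_layer("tissue", matrix(TRUE, nrow(tpef), ncol(tpef)),
                      slide$calibration))
  }
  sm <- if (cfg$tissue_sigma_px > 0) {
    as.matrix(EBImage::gblur(EBImage::Image(tpef), sigma = cfg$tissue_sigma_px))
  } else tpef
  thr <- otsu_threshold(as.vector(sm))
  mask <- sm > thr
  mask <- fill_small_holes(mask, um2_to_px(cfg$fill_holes_um2,
                                           slide$calibration))
  if (cfg$largest_component_only && any(mask)) {
    lab <- label_components(mask)
    keep <- which.max(tabulate(lab[lab > 0]))
    mask <- lab == keep
  }
  mask_layer("tissue", mask, slide$calibration)
}

#' Load a portal-tract annotation mask
#'
#' Portal tracts are taken from user-supplied annotation masks (any nonzero
#' pixel is portal). The mask must match the slide dimensions and is
#' clipped to the tissue mask when one is given.
#'
#' @param path Mask image path (PNG or TIFF), or a logical matrix.
#' @param slide The `qfib_slide` the mask annotates.
#' @param tissue Optional tissue `qfib_mask` to clip against.
#' @return A portal `qfib_mask`.
#' @export
load_portal_mask <- function(path, slide, tissue = NULL) {
  m <- if (is.matrix(path)) path > 0 else read_mask(path)
  if (!identical(dim(m), dim(slide$shg))) {
    stop("portal mask dimensions (", paste(dim(m), collapse = "x"),
         ") do not match slide dimensions (",
         paste(dim(slide$shg), collapse = "x"), ")")
  }
  if (!is.null(tissue)) m <- m & tissue$mask
  mask_layer("portal", m, slide$calibration)
}

#' Heuristic portal-tract detector (experimental)
#'
#' Flags dense, bright TPEF blobs of at least `portal_min_area_um2` as
#' candidate portal tracts. Annotation masks are the supported input for
#' analysis; this detector exists only for exploratory triage and its
#' output should be reviewed before use.
#'
#' @inheritParams segment_collagen
#' @return A portal `qfib_mask`.
#' @export
detect_portal_heuristic <- function(slide, cfg = segmentation_config()) {
  tis <- segment_tissue(slide, cfg)
  tpef <- slide$tpef
  vals <- tpef[tis$mask]
  mask <- matrix(FALSE, nrow(tpef), ncol(tpef))
  if (length(vals) && diff(range(vals)) > 0) {
    thr <- otsu_threshold(vals)
    cand <- tpef > thr & tis$mask
    cand <- fill_small_holes(cand, um2_to_px(500, slide$calibration))
    mask <- drop_small_components(cand, um2_to_px(cfg$portal_min_area_um2,
                                                  slide$calibration))
  }
  mask_layer("portal", mask, slide$calibration)
}

## ---- binary-mask utilities (8-connectivity throughout) ----

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# diagonal-touching 4-components are merged afterwards with a union-find
# over diagonally adjacent label pairs.
label_components <- function(mask) {
  mask <- mask > 0
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1L) return(matrix(as.integer(lab), nrow(mask), ncol(mask)))
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- matrix(0L, nr, nc)
  pos <- lab > 0
  out[pos] <- relab[lab[pos]]
  out
}

# drop 8-connected components with fewer than min_px pixels (strictly smaller)
drop_small_components <- function(mask, min_px) {
  if (!any(mask) || min_px <= 1) return(mask > 0)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# fill background holes (background components not touching the border)
# of at most max_px pixels; background uses 4-connectivity, the dual of the
# 8-connected foreground
fill_small_holes <- function(mask, max_px) {
  mask <- mask > 0
  if (max_px <= 0 || all(mask)) return(mask)
  bg <- EBImage::bwlabel(!mask)
  if (max(bg) == 0L) return(mask)
  border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labs <- border_labs[border_labs > 0]
  sizes <- tabulate(bg[bg > 0])
  fill <- setdiff(which(sizes <= max_px), border_labs)
  if (length(fill)) mask[matrix(bg %in% fill, nrow(bg), ncol(bg))] <- TRUE
  mask
}
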