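#' Fiber morphometry configuration
#'
#' Cut-offs for the dichotomous fiber classes. Each threshold is inclusive
#' at the boundary and is recorded alongside every parameter vector so that
#' results are never reported without the cut-offs that produced them.
#'
#' @param long_length_um Fibers with skeleton length >= this are "long"
#'   (else "short"). Default 20 um.
#' @param thick_width_um Fibers with mean width >= this are "thick" (else
#'   "thin"). Default 3 um.
#' @param aggregated_component_area_um2 Fibers with area >= this are
#'   "aggregated" (else "distributed"). Default 200 um^2.
#' @param intersection_merge_radius_um Skeleton branch points closer than
#'   this are merged into one intersection. Default 1 um.
#' @return A list of class `qfib_morph_config`.
#' @export
morphometry_config <- function(long_length_um = 20,
                               thick_width_um = 3,
                               aggregated_component_area_um2 = 200,
                               intersection_merge_radius_um = 1) {
  stopifnot(long_length_um > 0, thick_width_um > 0,
            aggregated_component_area_um2 > 0,
            intersection_merge_radius_um > 0)
  structure(list(long_length_um = long_length_um,
                 thick_width_um = thick_width_um,
                 aggregated_component_area_um2 = aggregated_component_area_um2,
                 intersection_merge_radius_um = intersection_merge_radius_um),
            class = "qfib_morph_config")
}

#' Morphological skeleton of a binary mask
#'
#' Zhang-Suen parallel thinning: pixels are iteratively deleted from the
#' boundary, alternating two sub-iterations, until stable. The result is a
#' (mostly) one-pixel-wide, 8-connected medial line that preserves
#' component connectivity and line ends.
#'
#' @param mask Logical matrix.
#' @return Logical matrix: the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- (mask > 0) * 1L
  if (!any(m)) return(mask > 0)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north: p2..p9
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1L) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m == 1L & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# shift a matrix by (dr, dc) with zero padding
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# skeleton arc length in pixel units: each 8-adjacent skeleton pixel pair
# contributes one step of 1 (orthogonal) or sqrt(2) (diagonal); a single
# isolated skeleton pixel counts as one pixel of length.
skeleton_length_px <- function(skel) {
  n <- sum(skel)
  if (n == 0L) return(0)
  if (n == 1L) return(1)
  s <- skel * 1L
  nr <- nrow(s); nc <- ncol(s)
  horiz <- sum(s[, -nc] & s[, -1])
  vert <- sum(s[-nr, ] & s[-1, ])
  diag1 <- sum(s[-nr, -nc] & s[-1, -1])
  diag2 <- sum(s[-1, -nc] & s[-nr, -1])
  len <- horiz + vert + sqrt(2) * (diag1 + diag2)
  max(len, 1)
}

#' Skeleton arc length of one fiber component
#'
#' Sums the inter-pixel steps along the morphological skeleton (1 px for
#' orthogonal, sqrt(2) px for diagonal neighbours) and converts to
#' micrometres. A single-pixel component has a declared floor of one pixel
#' of length.
#'
#' @param component Logical matrix containing one connected component.
#' @param calibration A [calibration()] object.
#' @param skeleton Optional precomputed skeleton of `component`.
#' @return Length in micrometres.
#' @export
measure_length <- function(component, calibration = qfib::calibration(),
                           skeleton = NULL) {
  if (!any(component > 0)) stop("empty component")
  if (is.null(skeleton)) skeleton <- skeletonize(component)
  skeleton_length_px(skeleton) * calibration$microns_per_pixel
}

#' Extract and measure collagen fiber strings
#'
#' A fiber string is one 8-connected component of the collagen mask. Each
#' fiber is measured (pixel count, area, skeleton length, mean width =
#' area / length), classified (short/long, thin/thick,
#' aggregated/distributed; see [morphometry_config()]), and assigned to the
#' region containing the majority of its pixels, with ties broken by the
#' precedence periportal > portal > RPS.
#'
#' @param collagen Collagen mask (`qfib_mask` or logical matrix); must lie
#'   inside the tissue mask of `regions`.
#' @param regions A `qfib_regions` partition.
#' @param cfg A [morphometry_config()].
#' @return A data.frame of class `qfib_fibers` with one row per fiber:
#'   `fiber_id`, `pixel_count`, `area_um2`, `length_um`, `width_um`,
#'   `region`, `is_long`, `is_thick`, `is_aggregated`.
#' @export
extract_fibers <- function(collagen, regions, cfg = morphometry_config()) {
  cm <- as_mask_matrix(collagen)
  cal <- regions$calibration
  lab <- label_components(cm)
  n <- max(lab)
  empty <- data.frame(fiber_id = integer(0), pixel_count = integer(0),
                      area_um2 = numeric(0), length_um = numeric(0),
                      width_um = numeric(0), region = character(0),
                      is_long = logical(0), is_thick = logical(0),
                      is_aggregated = logical(0))
  if (n == 0L) return(structure(empty, class = c("qfib_fibers", "data.frame")))

  skel <- skeletonize(cm)
  idx <- which(lab > 0)
  labv <- lab[idx]
  pixel_count <- tabulate(labv, n)

  # per-fiber region vote
  reg_code <- matrix(0L, nrow(cm), ncol(cm))
  reg_code[regions$rps] <- 1L
  reg_code[regions$portal] <- 2L
  reg_code[regions$periportal] <- 3L
  votes <- function(code) {
    v <- integer(n)
    sel <- reg_code[idx] == code
    if (any(sel)) {
      t <- tabulate(labv[sel], n)
      v <- t
    }
    v
  }
  v_rps <- votes(1L); v_portal <- votes(2L); v_peri <- votes(3L)
  vm <- cbind(periportal = v_peri, portal = v_portal, rps = v_rps)
  if (any(rowSums(vm) == 0)) {
    stop("collagen component lies entirely outside the tissue partition; ",
         "collagen must be a subset of tissue")
  }
  region <- colnames(vm)[max.col(vm, ties.method = "first")]

  # per-fiber skeleton length via bounding boxes (skeleton computed once on
  # the whole mask; components are 8-disconnected so thinning is identical)
  rows <- ((idx - 1L) %% nrow(cm)) + 1L
  cols <- ((idx - 1L) %/% nrow(cm)) + 1L
  length_um <- numeric(n)
  for (f in seq_len(n)) {
    sel <- labv == f
    r0 <- range(rows[sel]); c0 <- range(cols[sel])
    sub <- matrix(FALSE, r0[2] - r0[1] + 1L, c0[2] - c0[1] + 1L)
    in_box <- lab[r0[1]:r0[2], c0[1]:c0[2], drop = FALSE] == f
    sub[in_box] <- skel[r0[1]:r0[2], c0[1]:c0[2], drop = FALSE][in_box]
    length_um[f] <- skeleton_length_px(sub) * cal$microns_per_pixel
  }

  area_um2 <- pixel_count * px_area_um2(cal)
  fibers <- data.frame(fiber_id = seq_len(n), pixel_count = pixel_count,
                       area_um2 = area_um2, length_um = length_um,
                       width_um = area_um2 / length_um, region = region,
                       is_long = NA, is_thick = NA, is_aggregated = NA)
  fibers <- classify_fibers(fibers, cfg)
  fibers <- classify_aggregation(fibers, cfg)
  structure(fibers, class = c("qfib_fibers", "data.frame"))
}

#' Classify fibers as short/long and thin/thick
#'
#' Dichotomous and exhaustive: `is_long = length_um >= long_length_um`
#' (short otherwise), `is_thick = width_um >= thick_width_um` (thin
#' otherwise); both boundaries inclusive.
#'
#' @param fibers A `qfib_fibers` data.frame (measured).
#' @param cfg A [morphometry_config()].
#' @return `fibers` with `is_long` and `is_thick` filled in.
#' @export
classify_fibers <- function(fibers, cfg = morphometry_config()) {
  fibers$is_long <- fibers$length_um >= cfg$long_length_um
  fibers$is_thick <- fibers$width_um >= cfg$thick_width_um
  fibers
}

#' Classify fibers as aggregated or distributed
#'
#' A fiber is aggregated when its area reaches
#' `aggregated_component_area_um2` (inclusive); distributed otherwise.
#'
#' @inheritParams classify_fibers
#' @return `fibers` with `is_aggregated` filled in.
#' @export
classify_aggregation <- function(fibers, cfg = morphometry_config()) {
  fibers$is_aggregated <- fibers$area_um2 >= cfg$aggregated_component_area_um2
  fibers
}

#' Count fiber intersections within a region
#'
#' Intersections are branch points of the collagen skeleton: skeleton
#' pixels with at least three skeleton neighbours (8-connectivity). Branch
#' points inside the region are clustered by single linkage at
#' `intersection_merge_radius_um` (a junction typically produces a small
#' clump of branch pixels) and each cluster counts once.
#'
#' @param collagen Collagen mask (`qfib_mask` or logical matrix).
#' @param region Logical matrix restricting the count.
#' @param cfg A [morphometry_config()].
#' @param calibration A [calibration()] object (taken from `collagen` when
#'   it is a `qfib_mask`).
#' @param skeleton Optional precomputed skeleton.
#' @return Integer intersection count.
#' @export
count_intersections <- function(collagen, region, cfg = morphometry_config(),
                                calibration = NULL, skeleton = NULL) {
  cm <- as_mask_matrix(collagen)
  cal <- if (inherits(collagen, "qfib_mask")) collagen$calibration else calibration
  if (is.null(cal)) cal <- qfib::calibration()
  if (!identical(dim(cm), dim(region))) stop("mask shape mismatch")
  if (is.null(skeleton)) skeleton <- skeletonize(cm)
  s <- skeleton * 1L
  nb <- shift_mat(s, -1, 0) + shift_mat(s, -1, 1) + shift_mat(s, 0, 1) +
        shift_mat(s, 1, 1) + shift_mat(s, 1, 0) + shift_mat(s, 1, -1) +
        shift_mat(s, 0, -1) + shift_mat(s, -1, -1)
  branch <- skeleton & nb >= 3 & (region > 0)
  pts <- which(branch, arr.ind = TRUE)
  n <- nrow(pts)
  if (n <= 1L) return(n)
  r_px <- cfg$intersection_merge_radius_um / cal$microns_per_pixel
  # single-linkage clusters: union pairs closer than the merge radius
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  d <- as.matrix(stats::dist(pts))
  close <- which(d < r_px & upper.tri(d), arr.ind = TRUE)
  for (k in seq_len(nrow(close))) {
    a <- find(close[k, 1]); b <- find(close[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Write a per-fiber CSV
#'
#' @param fibers A `qfib_fibers` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiber_table <- function(fibers, path) {
  utils::write.csv(as.data.frame(fibers), path, row.names = FALSE)
  invisible(path)
}
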