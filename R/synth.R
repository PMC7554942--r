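#' Stage profile for the synthetic-slide generator
#'
#' Encodes the fibrosis pattern a synthetic slide emulates. The F1-like
#' profile carries perisinusoidal collagen away from portal tracts and
#' essentially no periportal collagen; the F2-like profile adds collagen
#' inside the periportal margin; the F0-like profile carries no collagen.
#' Fiber rates are expressed per 10^4 um^2 of the target region's area, so
#' realized counts are Poisson with mean `rate * region_area / 1e4`.
#'
#' @param name Profile label.
#' @param n_portal_tracts Number of portal tracts per slide.
#' @param portal_radius_um Length-2 range of portal-tract radii (um).
#' @param periportal_fiber_rate Fibers per 10^4 um^2 of periportal area.
#' @param rps_fiber_rate Fibers per 10^4 um^2 of RPS area.
#' @param fiber_length_um `c(meanlog, sdlog)` of the log-normal length of
#'   ordinary (distributed) fibers, in um.
#' @param fiber_width_um `c(meanlog, sdlog)` of distributed fiber width.
#' @param agg_length_um,agg_width_um Log-normal parameters for aggregated
#'   bundles (larger, so their area exceeds the aggregation cut-off).
#' @param aggregate_fraction Probability a fiber is drawn as an aggregated
#'   bundle.
#' @param noise_sd Gaussian noise sd added to both channels (0 = noise
#'   free).
#' @param portal_rim Render a collagen-rich rim just inside each portal
#'   tract (off for the collagen-free F0-like profile, whose SHG channel
#'   is pure noise).
#' @return A list of class `qfib_profile`.
#' @export
stage_profile <- function(name,
                          n_portal_tracts = 1L,
                          portal_radius_um = c(30, 50),
                          periportal_fiber_rate = 0,
                          rps_fiber_rate = 0,
                          fiber_length_um = c(log(15), 0.4),
                          fiber_width_um = c(log(1.5), 0.3),
                          agg_length_um = c(log(40), 0.25),
                          agg_width_um = c(log(6), 0.2),
                          aggregate_fraction = 0.15,
                          noise_sd = 0.02,
                          portal_rim = TRUE) {
  stopifnot(n_portal_tracts >= 0, length(portal_radius_um) == 2L,
            periportal_fiber_rate >= 0, rps_fiber_rate >= 0,
            aggregate_fraction >= 0, aggregate_fraction <= 1, noise_sd >= 0)
  structure(list(name = name, n_portal_tracts = as.integer(n_portal_tracts),
                 portal_radius_um = portal_radius_um,
                 periportal_fiber_rate = periportal_fiber_rate,
                 rps_fiber_rate = rps_fiber_rate,
                 fiber_length_um = fiber_length_um,
                 fiber_width_um = fiber_width_um,
                 agg_length_um = agg_length_um,
                 agg_width_um = agg_width_um,
                 aggregate_fraction = aggregate_fraction,
                 noise_sd = noise_sd, portal_rim = portal_rim),
            class = "qfib_profile")
}

#' Built-in stage profiles
#'
#' `F0like`: no collagen. `F1like`: perisinusoidal fibers only (periportal
#' rate near zero). `F2like`: perisinusoidal plus periportal fibers, with
#' perisinusoidal settings identical to `F1like` so that the F1/F2
#' contrast is localised to the periportal compartment.
#'
#' @return Named list of three [stage_profile()] objects.
#' @export
stage_profiles <- function() {
  list(
    F0like = stage_profile("F0like", periportal_fiber_rate = 0,
                           rps_fiber_rate = 0, portal_rim = FALSE),
    F1like = stage_profile("F1like", periportal_fiber_rate = 0.2,
                           rps_fiber_rate = 6),
    F2like = stage_profile("F2like", periportal_fiber_rate = 8,
                           rps_fiber_rate = 6)
  )
}

# run code with a private RNG state seeded by `seed`
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic slide with exact ground truth
#'
#' Deterministic for a fixed seed. Builds an irregular elliptical tissue
#' silhouette, places disk-shaped portal tracts inside it, partitions the
#' tissue with the periportal margin rule, and draws fibers as smoothed
#' random-walk polylines thickened to a constant per-fiber width. Fibers
#' never touch each other or the portal tracts, so every fiber survives as
#' its own connected component. The TPEF channel is the tissue silhouette
#' (portal tracts brighter); the SHG channel is the rendered collagen plus
#' a collagen-rich rim inside each portal tract; Gaussian noise
#' (`profile$noise_sd`) is added to both.
#'
#' With `render = FALSE` no images are produced: fiber lengths/widths are
#' drawn from the profile, areas are taken as length x width, and region
#' areas come from the mask partition. This fast path feeds cohort-level
#' simulations; rendered slides feed image-pipeline validation.
#'
#' @param profile A [stage_profile()].
#' @param size_px `c(rows, cols)` image size; default 1024 x 1024 px
#'   (400 x 400 um at default calibration).
#' @param calibration A [calibration()] object.
#' @param seed Integer seed.
#' @param render Produce images and pixel-exact bookkeeping (default TRUE).
#' @return List of class `qfib_truth` with elements `slide` (`qfib_slide`,
#'   or NULL when `render = FALSE`), `tissue`, `portal`, `regions`
#'   (`qfib_regions`), `fibers` (data.frame: region, area_um2, length_um,
#'   width_um, is_long, is_thick, is_aggregated), `intersections`
#'   (named counts), `collagen` (logical matrix or NULL), `profile`,
#'   `seed`.
#' @export
generate_slide <- function(profile, size_px = c(1024L, 1024L),
                           calibration = qfib::calibration(),
                           seed = 1L, render = TRUE) {
  stopifnot(inherits(profile, "qfib_profile"))
  with_seed(seed, {
    nr <- as.integer(size_px[1]); nc <- as.integer(size_px[2])
    mpp <- calibration$microns_per_pixel
    # the truth-only fast path resolves region geometry on a coarser grid
    # (up to 8x, ~3.1 um/px at default calibration): only region areas feed
    # the bookkeeping there, and the area discretisation error (< 1%) is
    # far below the Poisson sampling noise of the fiber counts
    factor <- if (render) 1L else max(Filter(function(f) nr %% f == 0L &&
                                               nc %% f == 0L,
                                             c(1L, 2L, 4L, 8L)))
    nr_g <- nr %/% factor; nc_g <- nc %/% factor; mpp_g <- mpp * factor
    cal_g <- calibration(mpp_g, tile_pixels = calibration$tile_pixels,
                         tile_microns = mpp_g * calibration$tile_pixels)
    geom <- sample_geometry(profile, nr_g, nc_g, mpp_g,
                            need_rim = render && isTRUE(profile$portal_rim))
    regions <- structure(list(portal = geom$portal,
                              periportal = geom$periportal,
                              rps = geom$rps, tissue = geom$tissue,
                              calibration = cal_g,
                              periportal_margin_um = 100),
                         class = "qfib_regions")
    areas <- region_areas_um2(regions)
    n_peri <- stats::rpois(1, profile$periportal_fiber_rate *
                              areas[["periportal"]] / 1e4)
    n_rps <- stats::rpois(1, profile$rps_fiber_rate * areas[["rps"]] / 1e4)
    targets <- c(rep("periportal", n_peri), rep("rps", n_rps))
    n_fib <- length(targets)
    agg <- stats::runif(n_fib) < profile$aggregate_fraction
    meanlog_len <- ifelse(agg, profile$agg_length_um[1],
                          profile$fiber_length_um[1])
    sdlog_len <- ifelse(agg, profile$agg_length_um[2],
                        profile$fiber_length_um[2])
    meanlog_w <- ifelse(agg, profile$agg_width_um[1],
                        profile$fiber_width_um[1])
    sdlog_w <- ifelse(agg, profile$agg_width_um[2], profile$fiber_width_um[2])
    len_um <- stats::rlnorm(n_fib, meanlog_len, sdlog_len)
    wid_um <- stats::rlnorm(n_fib, meanlog_w, sdlog_w)

    if (!render) {
      fibers <- data.frame(region = targets, area_um2 = len_um * wid_um,
                           length_um = len_um, width_um = wid_um)
      fibers <- finish_truth_fibers(fibers)
      inter <- c(periportal = stats::rpois(1, 0.15 * sum(fibers$region == "periportal")),
                 rps = stats::rpois(1, 0.15 * sum(fibers$region == "rps")))
      return(structure(list(slide = NULL, tissue = geom$tissue,
                            portal = geom$portal, regions = regions,
                            fibers = fibers, intersections = inter,
                            collagen = NULL, profile = profile, seed = seed),
                       class = "qfib_truth"))
    }

    drawn <- draw_fibers(targets, len_um, wid_um, geom, regions, mpp)
    fibers <- finish_truth_fibers(drawn$fibers)

    shg <- drawn$shg
    tpef <- matrix(0.02, nr, nc)
    tpef[geom$tissue] <- 0.5
    tpef[geom$portal] <- 0.85
    # collagen-rich rim just inside each portal tract
    if (isTRUE(profile$portal_rim)) shg[geom$rim] <- pmax(shg[geom$rim], 0.7)
    if (profile$noise_sd > 0) {
      shg <- pmax(shg + stats::rnorm(nr * nc, 0, profile$noise_sd), 0)
      tpef <- pmax(tpef + stats::rnorm(nr * nc, 0, profile$noise_sd), 0)
    }
    slide <- dual_channel_slide(shg, tpef, calibration,
                                sample_id = paste0(profile$name, "_", seed))
    cfg <- morphometry_config()
    skel <- skeletonize(drawn$collagen)
    inter <- c(periportal = count_intersections(drawn$collagen,
                                                regions$periportal, cfg,
                                                calibration, skeleton = skel),
               rps = count_intersections(drawn$collagen, regions$rps, cfg,
                                         calibration, skeleton = skel))
    structure(list(slide = slide, tissue = geom$tissue, portal = geom$portal,
                   regions = regions, fibers = fibers, intersections = inter,
                   collagen = drawn$collagen, profile = profile, seed = seed),
              class = "qfib_truth")
  })
}

finish_truth_fibers <- function(fibers, cfg = morphometry_config()) {
  fibers$is_long <- fibers$length_um >= cfg$long_length_um
  fibers$is_thick <- fibers$width_um >= cfg$thick_width_um
  fibers$is_aggregated <- fibers$area_um2 >= cfg$aggregated_component_area_um2
  fibers
}

.grid_cache <- new.env(parent = emptyenv())

# row/column index matrices and the polar angle about the centre, cached
# per grid size (they are deterministic and reused across samples)
grid_coords <- function(nr, nc) {
  key <- paste0(nr, "x", nc)
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    theta <- atan2(rr - nr / 2, cc - nc / 2)
    g <- list(rr = rr, cc = cc, theta = theta)
    .grid_cache[[key]] <- g
  }
  g
}

# tissue silhouette, portal tracts and the region partition; the rim is
# only rendered, so the truth-only path skips it
sample_geometry <- function(profile, nr, nc, mpp, need_rim = TRUE) {
  g <- grid_coords(nr, nc)
  rr <- g$rr; cc <- g$cc
  cy <- nr / 2; cx <- nc / 2
  a <- stats::runif(1, 0.40, 0.47) * nr
  b <- stats::runif(1, 0.40, 0.47) * nc
  phase <- stats::runif(1, 0, 2 * pi)
  wobble <- 1 + 0.05 * sin(3 * g$theta + phase)
  tissue <- ((rr - cy) / a)^2 + ((cc - cx) / b)^2 <= wobble^2

  portal <- matrix(FALSE, nr, nc)
  rim <- matrix(FALSE, nr, nc)
  centers <- NULL
  inner_ok <- ((rr - cy) / (0.6 * a))^2 + ((cc - cx) / (0.6 * b))^2 <= 1
  cand <- which(inner_ok)
  for (k in seq_len(profile$n_portal_tracts)) {
    r_um <- stats::runif(1, profile$portal_radius_um[1],
                         profile$portal_radius_um[2])
    r_px <- r_um / mpp
    placed <- FALSE
    for (try in 1:50) {
      p <- cand[sample.int(length(cand), 1)]
      py <- ((p - 1) %% nr) + 1; px <- ((p - 1) %/% nr) + 1
      if (!is.null(centers) &&
          any(sqrt((centers[, 1] - py)^2 + (centers[, 2] - px)^2) <
              r_px + 60 / mpp)) next
      d2 <- (rr - py)^2 + (cc - px)^2
      portal <- portal | (d2 <= r_px^2)
      if (need_rim) rim <- rim | (d2 <= (r_px - 1)^2 & d2 >= (r_px - 4)^2)
      centers <- rbind(centers, c(py, px))
      placed <- TRUE
      break
    }
    if (!placed) stop("profile infeasible: could not place portal tract ", k,
                      " in the requested field")
  }
  portal <- portal & tissue
  rim <- rim & tissue
  pp <- if (any(portal)) {
    d <- portal_distance_um(portal, list(microns_per_pixel = mpp),
                            max_um = 100)
    d > 0 & d <= 100 & tissue
  } else matrix(FALSE, nr, nc)
  rps <- tissue & !portal & !pp
  list(tissue = tissue, portal = portal, rim = rim, periportal = pp,
       rps = rps)
}

# render fibers as thickened random-walk polylines; fibers never touch
# each other or the (2 px dilated) portal tracts
draw_fibers <- function(targets, len_um, wid_um, geom, regions, mpp) {
  nr <- nrow(geom$tissue); nc <- ncol(geom$tissue)
  shg <- matrix(0, nr, nc)
  occupied <- matrix(FALSE, nr, nc)
  forbidden <- dilate_px(geom$portal, 2L)
  reg_code <- matrix(0L, nr, nc)
  reg_code[regions$rps] <- 1L
  reg_code[regions$periportal] <- 3L
  start_pool <- list(periportal = which(regions$periportal),
                     rps = which(regions$rps))
  out <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    rec <- NULL
    for (try in 1:12) {
      pix <- trace_fiber(start_pool[[targets[i]]], len_um[i], wid_um[i],
                         geom$tissue, forbidden, nr, nc, mpp)
      if (is.null(pix) || length(pix$idx) == 0L) next
      if (any(occupied[pix$neigh]) || any(occupied[pix$idx])) next
      occupied[pix$idx] <- TRUE
      shg[pix$idx] <- stats::runif(1, 0.7, 0.85)
      codes <- reg_code[pix$idx]
      n_pp <- sum(codes == 3L); n_rps <- sum(codes == 1L)
      region <- if (n_pp >= n_rps) "periportal" else "rps"
      if (n_pp == 0L && n_rps == 0L) region <- targets[i]
      area <- length(pix$idx) * mpp^2
      rec <- data.frame(region = region, area_um2 = area,
                        length_um = pix$arc_um,
                        width_um = area / max(pix$arc_um, mpp))
      break
    }
    out[[i]] <- rec
  }
  fibers <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(fibers)) {
    fibers <- data.frame(region = character(0), area_um2 = numeric(0),
                         length_um = numeric(0), width_um = numeric(0))
  }
  list(fibers = fibers, shg = shg, collagen = occupied)
}

# one candidate fiber: random-walk polyline stamped with a disk of the
# target width; returns pixel indices, their 8-neighbourhood and arc length
trace_fiber <- function(pool, len_um, wid_um, tissue, forbidden, nr, nc, mpp) {
  if (!length(pool)) return(NULL)
  p0 <- pool[sample.int(length(pool), 1)]
  y <- ((p0 - 1) %% nr) + 1; x <- ((p0 - 1) %/% nr) + 1
  theta <- stats::runif(1, 0, 2 * pi)
  step_px <- 1.2
  n_steps <- max(2L, ceiling(len_um / (step_px * mpp)))
  ys <- numeric(n_steps + 1L); xs <- numeric(n_steps + 1L)
  ys[1] <- y; xs[1] <- x
  n_pts <- 1L
  for (s in seq_len(n_steps)) {
    theta <- theta + stats::rnorm(1, 0, 0.18)
    y <- y + step_px * sin(theta)
    x <- x + step_px * cos(theta)
    yi <- round(y); xi <- round(x)
    if (yi < 3 || yi > nr - 2 || xi < 3 || xi > nc - 2) break
    if (!tissue[yi, xi] || forbidden[yi, xi]) break
    n_pts <- n_pts + 1L
    ys[n_pts] <- y; xs[n_pts] <- x
  }
  if (n_pts < 2L) return(NULL)
  ys <- ys[seq_len(n_pts)]; xs <- xs[seq_len(n_pts)]
  arc_um <- sum(sqrt(diff(ys)^2 + diff(xs)^2)) * mpp
  r_px <- max(wid_um / mpp / 2, 0.5)
  off <- disk_offsets(r_px)
  yy <- as.vector(outer(off[, 1], round(ys), `+`))
  xx <- as.vector(outer(off[, 2], round(xs), `+`))
  keep <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
  idx <- unique((xx[keep] - 1L) * nr + yy[keep])
  # drop pixels outside tissue or in the portal buffer
  idx <- idx[tissue[idx] & !forbidden[idx]]
  if (!length(idx)) return(NULL)
  neigh <- neighbourhood_idx(idx, nr, nc)
  list(idx = idx, neigh = neigh, arc_um = arc_um)
}

disk_offsets <- function(r_px) {
  r <- ceiling(r_px)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  as.matrix(g[g$dy^2 + g$dx^2 <= r_px^2, , drop = FALSE])
}

# linear indices of the 8-neighbourhood (plus the pixels themselves)
neighbourhood_idx <- function(idx, nr, nc) {
  y <- ((idx - 1L) %% nr) + 1L
  x <- ((idx - 1L) %/% nr) + 1L
  dy <- c(-1L, -1L, -1L, 0L, 0L, 0L, 1L, 1L, 1L)
  dx <- c(-1L, 0L, 1L, -1L, 0L, 1L, -1L, 0L, 1L)
  yy <- rep(y, each = 9L) + dy
  xx <- rep(x, each = 9L) + dx
  keep <- yy >= 1L & yy <= nr & xx >= 1L & xx <= nc
  unique((xx[keep] - 1L) * nr + yy[keep])
}

dilate_px <- function(mask, n) {
  m <- mask > 0
  for (k in seq_len(n)) {
    m <- m | shift_mat(m * 1L, -1, 0) > 0 | shift_mat(m * 1L, 1, 0) > 0 |
         shift_mat(m * 1L, 0, -1) > 0 | shift_mat(m * 1L, 0, 1) > 0 |
         shift_mat(m * 1L, -1, -1) > 0 | shift_mat(m * 1L, -1, 1) > 0 |
         shift_mat(m * 1L, 1, -1) > 0 | shift_mat(m * 1L, 1, 1) > 0
  }
  m
}

#' Parameter vector implied by a ground truth
#'
#' Computes the 56-parameter vector directly from a generator truth's
#' bookkeeping (fiber records, region areas, intersection counts), without
#' touching images.
#'
#' @param truth A `qfib_truth` from [generate_slide()].
#' @param sample_id Sample identifier.
#' @return A `qfib_params`.
#' @export
truth_parameters <- function(truth, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- paste0(truth$profile$name, "_", truth$seed)
  }
  compute_parameters(truth$fibers, truth$regions, truth$intersections,
                     sample_id = sample_id)
}

#' Generate a reproducible two-group synthetic cohort
#'
#' Per-sample seeds are drawn from the master seed, so the cohort is fully
#' reproducible and samples are independent.
#'
#' @param n_per_group Samples per group (>= 3).
#' @param profiles Length-2 list of [stage_profile()] objects, one per
#'   group.
#' @param seed Master seed.
#' @param labels Group labels (default: profile names).
#' @param render Render images (slow) or truth-only (fast, default).
#' @param size_px Slide size passed to [generate_slide()].
#' @return List of class `qfib_synth_cohort`: `truths` (list of
#'   `qfib_truth`), `group`, `labels`, `seed`.
#' @export
generate_cohort <- function(n_per_group, profiles, seed = 1L, labels = NULL,
                            render = FALSE, size_px = c(1024L, 1024L)) {
  stopifnot(n_per_group >= 3L, length(profiles) == 2L)
  if (is.null(labels)) {
    labels <- vapply(profiles, function(p) p$name, character(1))
    if (labels[1] == labels[2]) labels <- paste0(labels, c("_a", "_b"))
  }
  sub_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max - 1L, 2L * n_per_group))
  group <- rep(labels, each = n_per_group)
  prof <- rep(profiles, each = n_per_group)
  truths <- vector("list", 2L * n_per_group)
  for (i in seq_along(truths)) {
    truths[[i]] <- generate_slide(prof[[i]], size_px = size_px, seed = sub_seeds[i],
                                  render = render)
  }
  structure(list(truths = truths, group = group, labels = labels,
                 seed = seed),
            class = "qfib_synth_cohort")
}

#' Null-calibration simulation of the parameter screen
#'
#' Simulates replicate null cohorts (both groups drawn from the same
#' profile) and tests one parameter per cohort, rotating through the
#' requested parameter list, so the replicate tests are mutually
#' independent. Returns the fraction flagged at `alpha`, which should sit
#' near `alpha` for a calibrated screen. Under the default F1-like profile
#' the periportal family is structurally empty, so calibration is assessed
#' on the perisinusoidal parameters.
#'
#' @param n_tests Number of replicate parameter tests (one per cohort).
#' @param n_per_group Samples per group in each cohort.
#' @param profile Profile drawn for both groups (default F1-like).
#' @param parameters Parameters to rotate through (default: the 28 RPS
#'   parameters).
#' @param alpha Significance level.
#' @param seed Master seed.
#' @return List with `fraction`, `flags` (logical vector), `parameters`
#'   (the rotation), `alpha`.
#' @export
simulate_null_screen <- function(n_tests = 1000, n_per_group = 15,
                                 profile = stage_profiles()$F1like,
                                 parameters = grep("RPS",
                                                   parameter_schema(),
                                                   value = TRUE),
                                 alpha = 0.05, seed = 1L) {
  rotation <- rep_len(parameters, n_tests)
  flags <- logical(n_tests)
  for (r in seq_len(n_tests)) {
    syn <- generate_cohort(n_per_group, list(profile, profile),
                           seed = seed + r)
    sc <- compare_groups(cohort_parameters(syn), syn$labels[1],
                         syn$labels[2], alpha = alpha,
                         parameters = rotation[r])
    flags[r] <- sc$significant[1]
  }
  list(fraction = mean(flags), flags = flags, parameters = rotation,
       alpha = alpha)
}

#' Power / specificity simulation for a two-profile contrast
#'
#' Simulates replicate cohorts contrasting two profiles and reports, per
#' parameter, the fraction of cohorts in which it is significant. For
#' parameters the contrast drives (periportal counts under F1-like vs
#' F2-like) this is the power; for unaffected parameters it is the
#' false-positive rate.
#'
#' @param n_cohorts Number of replicate cohorts.
#' @param n_per_group Samples per group.
#' @param profiles Length-2 profile list (default F1-like vs F2-like).
#' @param parameters Parameters to track (default: the periportal count
#'   parameters that the profile contrast drives).
#' @param alpha Significance level.
#' @param seed Master seed.
#' @return Named numeric vector: per-parameter fraction significant.
#' @export
simulate_power <- function(n_cohorts = 100, n_per_group = 15,
                           profiles = stage_profiles()[c("F1like", "F2like")],
                           parameters = c("#StrPeriportal",
                                          "#ShortStrPeriportal",
                                          "#LongStrPeriportal",
                                          "#ThinStrPeriportal",
                                          "#ThickStrPeriportal",
                                          "#StrPeriportalAgg",
                                          "#StrPeriportalDis"),
                           alpha = 0.05, seed = 1L) {
  parameters <- resolve_parameter_alias(parameters)
  hits <- matrix(FALSE, n_cohorts, length(parameters),
                 dimnames = list(NULL, parameters))
  for (r in seq_len(n_cohorts)) {
    syn <- generate_cohort(n_per_group, profiles, seed = seed + r)
    sc <- compare_groups(cohort_parameters(syn), syn$labels[1],
                         syn$labels[2], alpha = alpha,
                         parameters = parameters)
    hits[r, ] <- sc$significant
  }
  colMeans(hits)
}

#' Cohort parameter table from a synthetic cohort's ground truth
#'
#' @param synth A `qfib_synth_cohort`.
#' @return A `qfib_cohort` ready for [compare_groups()].
#' @export
cohort_parameters <- function(synth) {
  vecs <- lapply(seq_along(synth$truths), function(i) {
    truth_parameters(synth$truths[[i]], sample_id = paste0("s", i))
  })
  values <- do.call(rbind, lapply(vecs, function(v) v$values))
  colnames(values) <- parameter_schema()
  cohort_table(values, synth$group,
               sample_id = vapply(vecs, function(v) v$sample_id, character(1)))
}
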