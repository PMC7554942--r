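#' Quantify one slide: segmentation, regions, fibers, 56 parameters
#'
#' The per-sample pipeline: segment tissue (TPEF) and collagen (SHG), load
#' the portal-tract annotation, partition tissue into portal / periportal /
#' RPS with the radial-margin rule, extract and classify fiber strings,
#' count skeleton intersections per region, and assemble the 56-parameter
#' vector.
#'
#' @param slide A `qfib_slide`.
#' @param portal_mask Portal annotation: path, logical matrix, or
#'   `qfib_mask`.
#' @param seg_cfg A [segmentation_config()].
#' @param region_cfg A [region_config()].
#' @param morph_cfg A [morphometry_config()].
#' @return List of class `qfib_quantification`: `params` (`qfib_params`),
#'   `fibers`, `regions`, `collagen`, `tissue`, `intersections`.
#' @examples
#' truth <- generate_slide(stage_profiles()$F2like, size_px = c(256, 256),
#'                         seed = 7)
#' q <- quantify_slide(truth$slide, truth$portal)
#' q$params
#' @export
quantify_slide <- function(slide, portal_mask,
                           seg_cfg = segmentation_config(),
                           region_cfg = region_config(),
                           morph_cfg = morphometry_config()) {
  tissue <- segment_tissue(slide, seg_cfg)
  collagen <- segment_collagen(slide, seg_cfg, tissue = tissue)
  portal <- if (inherits(portal_mask, "qfib_mask")) portal_mask
            else load_portal_mask(portal_mask, slide, tissue = tissue)
  regions <- partition_regions(slide, tissue, portal, region_cfg)
  fibers <- extract_fibers(collagen, regions, morph_cfg)
  skel <- skeletonize(collagen$mask)
  inter <- c(periportal = count_intersections(collagen, regions$periportal,
                                              morph_cfg, slide$calibration,
                                              skeleton = skel),
             rps = count_intersections(collagen, regions$rps, morph_cfg,
                                       slide$calibration, skeleton = skel))
  params <- compute_parameters(fibers, regions, inter,
                               sample_id = slide$sample_id, cfg = morph_cfg)
  structure(list(params = params, fibers = fibers, regions = regions,
                 collagen = collagen, tissue = tissue,
                 intersections = inter),
            class = "qfib_quantification")
}

#' @export
print.qfib_quantification <- function(x, ...) {
  cat(sprintf("<qfib_quantification> sample '%s': %d fibers\n",
              x$params$sample_id, nrow(x$fibers)))
  print(x$regions)
  print(x$params)
  invisible(x)
}
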