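#' The canonical 56-parameter schema
#'
#' 28 periportal parameters followed by 28 reduced-perisinusoidal (RPS)
#' parameters, in fixed table order. For each region the parameters are:
#' collagen area percentages (all / aggregated / distributed fibers),
#' fiber counts overall and by class (short/long, thin/thick), summed
#' area, length and width, the same counts and sums restricted to the
#' aggregated and to the distributed stratum, and the intersection count.
#'
#' @return Character vector of the 56 canonical parameter names.
#' @examples
#' length(parameter_schema())  # 56
#' @export
parameter_schema <- function() {
  as.vector(vapply(c("Periportal", "RPS"), region_schema, character(28)))
}

region_schema <- function(region) {
  c(paste0("%", region),
    paste0("%", region, "Agg"),
    paste0("%", region, "Dis"),
    paste0("#Str", region),
    paste0("#ShortStr", region),
    paste0("#LongStr", region),
    paste0("#ThinStr", region),
    paste0("#ThickStr", region),
    paste0("StrArea", region),
    paste0("StrLength", region),
    paste0("StrWidth", region),
    paste0("#Str", region, "Agg"),
    paste0("#ShortStr", region, "Agg"),
    paste0("#LongStr", region, "Agg"),
    paste0("#ThinStr", region, "Agg"),
    paste0("#ThickStr", region, "Agg"),
    paste0("StrArea", region, "Agg"),
    paste0("StrLength", region, "Agg"),
    paste0("StrWidth", region, "Agg"),
    paste0("#Str", region, "Dis"),
    paste0("#ShortStr", region, "Dis"),
    paste0("#LongStr", region, "Dis"),
    paste0("#ThinStr", region, "Dis"),
    paste0("#ThickStr", region, "Dis"),
    paste0("StrArea", region, "Dis"),
    paste0("StrLength", region, "Dis"),
    paste0("StrWidth", region, "Dis"),
    paste0("#Intersection", region))
}

#' Resolve a parameter name or its "PS" alias to the canonical name
#'
#' Reduced-perisinusoidal parameters are sometimes written with a plain
#' "PS" region token (e.g. `#ThickStrPS`); these resolve to the canonical
#' "RPS" names (`#ThickStrRPS`). Canonical names pass through unchanged.
#'
#' @param name Parameter name or alias (vectorised).
#' @return Canonical parameter name(s).
#' @export
resolve_parameter_alias <- function(name) {
  schema <- parameter_schema()
  out <- vapply(name, function(nm) {
    if (nm %in% schema) return(nm)
    cand <- sub("PS", "RPS", nm, fixed = TRUE)
    if (cand %in% schema) return(cand)
    stop("unknown parameter name or alias: '", nm, "'")
  }, character(1))
  unname(out)
}

#' Parse a parameter name into its region family, stratum and metric
#'
#' @param name Parameter name or "PS" alias (vectorised).
#' @return data.frame with columns `name` (canonical), `region_family`
#'   (`"periportal"` or `"perisinusoidal"`), `stratum` (`"all"`, `"Agg"`,
#'   `"Dis"`) and `metric` (`"percent"`, `"count"`, `"area"`, `"length"`,
#'   `"width"`, `"intersection"`).
#' @examples
#' classify_parameter_name("#LongStrPeriportalAgg")
#' classify_parameter_name("StrWidthPSAgg")  # alias for StrWidthRPSAgg
#' @export
classify_parameter_name <- function(name) {
  canon <- resolve_parameter_alias(name)
  region_family <- ifelse(grepl("Periportal", canon), "periportal",
                          "perisinusoidal")
  stratum <- ifelse(grepl("Agg$", canon), "Agg",
                    ifelse(grepl("Dis$", canon), "Dis", "all"))
  metric <- ifelse(startsWith(canon, "%"), "percent",
            ifelse(startsWith(canon, "#Intersection"), "intersection",
            ifelse(startsWith(canon, "#"), "count",
            ifelse(startsWith(canon, "StrArea"), "area",
            ifelse(startsWith(canon, "StrLength"), "length", "width")))))
  data.frame(name = canon, region_family = region_family,
             stratum = stratum, metric = metric)
}

#' Compute the 56-parameter vector for one sample
#'
#' For each region (periportal, RPS) and stratum (all fibers, aggregated,
#' distributed): the percentage parameters are the collagen area of the
#' stratum's fibers in the region as a percentage of the region area
#' (collagen-proportionate-area convention); `#Str*` count fibers by class;
#' `StrArea`/`StrLength`/`StrWidth` sum per-fiber area, skeleton length and
#' mean width; `#Intersection*` are the supplied branch-point counts.
#' Portal-tract collagen contributes to no parameter. A region without
#' fibers scores 0 everywhere; a zero-area region scores 0 for its
#' percentages with a warning.
#'
#' @param fibers A `qfib_fibers` data.frame (see [extract_fibers()]).
#' @param regions A `qfib_regions` partition.
#' @param intersections Named list/vector with `periportal` and `rps`
#'   intersection counts (see [count_intersections()]).
#' @param sample_id Sample identifier stored with the vector.
#' @param cfg The [morphometry_config()] snapshot recorded with the vector.
#' @return Object of class `qfib_params`: fields `sample_id`, `values`
#'   (named numeric of length 56) and `thresholds_used`.
#' @export
compute_parameters <- function(fibers, regions,
                               intersections = c(periportal = 0, rps = 0),
                               sample_id = "sample",
                               cfg = morphometry_config()) {
  bad <- setdiff(unique(fibers$region), c("portal", "periportal", "rps"))
  if (length(bad)) stop("fiber region label(s) not in the region set: ",
                        paste(bad, collapse = ", "))
  areas <- region_areas_um2(regions)
  values <- c(region_parameter_values(fibers, "periportal",
                                      areas[["periportal"]],
                                      as.numeric(intersections[["periportal"]]),
                                      "Periportal"),
              region_parameter_values(fibers, "rps", areas[["rps"]],
                                      as.numeric(intersections[["rps"]]),
                                      "RPS"))
  stopifnot(identical(names(values), parameter_schema()))
  structure(list(sample_id = as.character(sample_id), values = values,
                 thresholds_used = cfg),
            class = "qfib_params")
}

region_parameter_values <- function(fibers, region, area_um2, n_intersection,
                                    tag) {
  f <- fibers[fibers$region == region, , drop = FALSE]
  strata <- list(all = rep(TRUE, nrow(f)), Agg = f$is_aggregated,
                 Dis = !f$is_aggregated)
  if (area_um2 <= 0 && nrow(f) > 0) {
    warning("region '", region, "' has zero area but carries collagen; ",
            "percentages reported as 0")
  }
  pct <- function(sel) {
    if (area_um2 <= 0) return(0)
    100 * sum(f$area_um2[sel]) / area_um2
  }
  block <- function(sel) {
    c(sum(sel), sum(sel & !f$is_long), sum(sel & f$is_long),
      sum(sel & !f$is_thick), sum(sel & f$is_thick),
      sum(f$area_um2[sel]), sum(f$length_um[sel]), sum(f$width_um[sel]))
  }
  vals <- c(pct(strata$all), pct(strata$Agg), pct(strata$Dis),
            block(strata$all), block(strata$Agg), block(strata$Dis),
            n_intersection)
  # reorder: schema lists all-strata block, then Agg block, then Dis block
  names(vals) <- c(paste0("%", tag), paste0("%", tag, "Agg"),
                   paste0("%", tag, "Dis"),
                   paste0(c("#Str", "#ShortStr", "#LongStr", "#ThinStr",
                            "#ThickStr", "StrArea", "StrLength", "StrWidth"),
                          tag),
                   paste0(c("#Str", "#ShortStr", "#LongStr", "#ThinStr",
                            "#ThickStr", "StrArea", "StrLength", "StrWidth"),
                          tag, "Agg"),
                   paste0(c("#Str", "#ShortStr", "#LongStr", "#ThinStr",
                            "#ThickStr", "StrArea", "StrLength", "StrWidth"),
                          tag, "Dis"),
                   paste0("#Intersection", tag))
  vals[region_schema(tag)]
}

#' @export
print.qfib_params <- function(x, ...) {
  cat(sprintf("<qfib_params> sample '%s': 56 parameters\n", x$sample_id))
  v <- x$values
  cat(sprintf("  %%Periportal = %.4g, #StrPeriportal = %g, %%RPS = %.4g, #StrRPS = %g\n",
              v[["%Periportal"]], v[["#StrPeriportal"]],
              v[["%RPS"]], v[["#StrRPS"]]))
  invisible(x)
}

#' @export
summary.qfib_params <- function(object, ...) {
  info <- classify_parameter_name(names(object$values))
  info$value <- unname(object$values)
  info
}

#' Write one parameter vector as JSON
#'
#' The JSON records the sample id, the schema version, the class
#' thresholds in force, and the 56 named values.
#'
#' @param params A `qfib_params`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_parameter_json <- function(params, path) {
  jsonlite::write_json(
    list(sample_id = params$sample_id,
         schema_version = "qfib-56/1",
         thresholds = unclass(params$thresholds_used),
         values = as.list(params$values)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
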