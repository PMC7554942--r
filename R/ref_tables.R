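#' Reference screening p-values from the original clinical study
#'
#' The refined algorithm was originally screened on two clinical cohorts:
#' cases whose fibrosis stage changed between F1 and F2/3 on expert
#' consensus review versus cases whose stage did not change. In the
#' single-expert-read cohort (`pkuh_p`) no parameter separated the groups;
#' in the routine-read cohort (`sgh_p`) 28 of the 56 parameters did. These
#' published per-parameter p-values are shipped so that the panel rule can
#' be exercised and tested against its reference outcome without access to
#' the clinical images. Perisinusoidal rows use the "PS" alias spelling in
#' which they were originally reported.
#'
#' @return data.frame with columns `parameter` (28 names, 20 periportal +
#'   8 perisinusoidal), `pkuh_p`, `sgh_p`.
#' @seealso [reference_validation_pvalues()], [build_panel()]
#' @export
reference_screen_pvalues <- function() {
  data.frame(
    parameter = c("%PeriportalDis", "#StrPeriportal", "#ShortStrPeriportal",
                  "#LongStrPeriportal", "#ThinStrPeriportal",
                  "#ThickStrPeriportal", "StrLengthPeriportal",
                  "StrWidthPeriportal", "#StrPeriportalAgg",
                  "#ShortStrPeriportalAgg", "#LongStrPeriportalAgg",
                  "#ThickStrPeriportalAgg", "StrWidthPeriportalAgg",
                  "#StrPeriportalDis", "#ShortStrPeriportalDis",
                  "#ThinStrPeriportalDis", "#ThickStrPeriportalDis",
                  "StrAreaPeriportalDis", "StrLengthPeriportalDis",
                  "StrWidthPeriportalDis", "#StrPS", "#ThickStrPS",
                  "StrLengthPS", "StrWidthPS", "#StrPSAgg", "#LongStrPSAgg",
                  "#ThickStrPSAgg", "StrWidthPSAgg"),
    pkuh_p = c(0.825, 0.414, 0.710, 0.604, 0.710, 0.439, 1.000, 0.330,
               0.825, 0.940, 0.484, 0.629, 0.199, 0.825, 0.940, 0.940,
               0.710, 0.825, 0.604, 0.825, 0.454, 0.454, 0.635, 0.539,
               0.839, 0.733, 0.733, 0.635),
    sgh_p = c(0.022, 0.003, 0.003, 0.009, 0.024, 0.004, 0.019, 0.004,
              0.005, 0.004, 0.008, 0.005, 0.006, 0.009, 0.005, 0.013,
              0.009, 0.022, 0.013, 0.019, 0.049, 0.049, 0.049, 0.026,
              0.042, 0.036, 0.042, 0.036)
  )
}

#' Reference validation p-values (true F1 versus true F2)
#'
#' Published p-values for the 28 screen-significant parameters re-tested
#' between consolidated true-F1 and true-F2 cases of both clinical
#' cohorts. Applying the `p < 0.05` retention rule to this table yields
#' the 26-parameter discriminant panel (the two `#ThinStr` periportal
#' rows, at p = 0.054, are excluded). Perisinusoidal rows use the
#' canonical "RPS" spelling in which they were originally reported.
#'
#' @return data.frame with columns `parameter` (28 names) and `p_value`.
#' @seealso [reference_screen_pvalues()], [build_panel()]
#' @export
reference_validation_pvalues <- function() {
  data.frame(
    parameter = c("%PeriportalDis", "#StrPeriportal", "#ShortStrPeriportal",
                  "#LongStrPeriportal", "#ThinStrPeriportal",
                  "#ThickStrPeriportal", "StrLengthPeriportal",
                  "StrWidthPeriportal", "#StrPeriportalAgg",
                  "#ShortStrPeriportalAgg", "#LongStrPeriportalAgg",
                  "#ThickStrPeriportalAgg", "StrWidthPeriportalAgg",
                  "#StrPeriportalDis", "#ShortStrPeriportalDis",
                  "#ThinStrPeriportalDis", "#ThickStrPeriportalDis",
                  "StrAreaPeriportalDis", "StrLengthPeriportalDis",
                  "StrWidthPeriportalDis", "#StrRPS", "#ThickStrRPS",
                  "StrLengthRPS", "StrWidthRPS", "#StrRPSAgg",
                  "#LongStrRPSAgg", "#ThickStrRPSAgg", "StrWidthRPSAgg"),
    p_value = c(0.011, 0.003, 0.003, 0.005, 0.054, 0.005, 0.005, 0.011,
                0.005, 0.005, 0.005, 0.008, 0.011, 0.003, 0.003, 0.054,
                0.004, 0.011, 0.011, 0.008, 0.022, 0.022, 0.022, 0.022,
                0.018, 0.018, 0.022, 0.022)
  )
}
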