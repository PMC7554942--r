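#' Two-sample Wilcoxon rank-sum test
#'
#' Thin module surface over [stats::wilcox.test()]. The reported statistic
#' is the rank sum of `x` (Mann-Whitney U plus `n_x (n_x + 1) / 2`); the
#' p-value is two-sided. In `"auto"` mode the exact null distribution is
#' used for tie-free samples with `n_x + n_y <= 16`, otherwise the normal
#' approximation with midranks, tie correction and continuity correction.
#' `"exact"` forces exact enumeration (falls back to the approximation,
#' with a warning, when ties make the exact null unavailable).
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return List with `statistic` (rank sum of `x`), `p_value`, and the
#'   `mode` actually used.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 (exact)
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  # perfectly tied pooled sample: the null is exactly symmetric, p = 1
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = nx * (nx + ny + 1) / 2, p_value = 1,
                mode = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = (nx + ny <= 16) && !ties
  )
  if (use_exact && ties) {
    warning("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  p <- unname(wt$p.value)
  if (!is.finite(p)) p <- 1
  list(statistic = unname(wt$statistic) + nx * (nx + 1) / 2,
       p_value = min(p, 1),
       mode = if (use_exact) "exact" else "approx")
}

#' Assemble a cohort table
#'
#' @param values Numeric matrix or data.frame: rows = samples, columns =
#'   the 56 parameters (canonical names or "PS" aliases).
#' @param group Per-sample group labels (length `nrow(values)`).
#' @param sample_id Optional per-sample ids.
#' @return Object of class `qfib_cohort` with `values` (matrix, canonical
#'   column names), `group`, `sample_id`.
#' @export
cohort_table <- function(values, group, sample_id = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  colnames(values) <- resolve_parameter_alias(colnames(values))
  schema <- parameter_schema()
  missing <- setdiff(schema, colnames(values))
  if (length(missing)) stop("cohort is missing parameters: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  values <- values[, schema, drop = FALSE]
  if (length(group) != nrow(values)) stop("group length != sample count")
  if (anyNA(values)) stop("cohort values must be complete (no NA)")
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(nrow(values)))
  structure(list(values = values, group = as.character(group),
                 sample_id = as.character(sample_id)),
            class = "qfib_cohort")
}

#' Screen parameters between two groups
#'
#' Runs the two-sided Wilcoxon rank-sum test for every schema parameter
#' between the two named groups, flagging parameters with `p < alpha`
#' (strict inequality: a p-value exactly at alpha is not significant).
#' No multiplicity correction is applied by default, so the screen is a
#' per-parameter error-rate procedure; Benjamini-Hochberg adjustment is
#' available behind `adjust = "BH"`.
#'
#' @param cohort A `qfib_cohort`.
#' @param group_a,group_b Group labels to contrast.
#' @param alpha Significance level (default 0.05).
#' @param mode Test mode passed to [rank_sum_test()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @param parameters Parameter subset to test (default: full schema).
#' @return data.frame of class `qfib_screen`: `parameter`, `statistic`,
#'   `p_value`, `significant`, `alpha`, in schema order.
#' @export
compare_groups <- function(cohort, group_a, group_b, alpha = 0.05,
                           mode = "auto", adjust = c("none", "BH"),
                           parameters = NULL) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(cohort, "qfib_cohort"))
  for (g in c(group_a, group_b)) {
    if (!any(cohort$group == g)) stop("group '", g, "' not present in cohort")
  }
  if (is.null(parameters)) parameters <- parameter_schema()
  parameters <- resolve_parameter_alias(parameters)
  a <- cohort$values[cohort$group == group_a, , drop = FALSE]
  b <- cohort$values[cohort$group == group_b, , drop = FALSE]
  res <- lapply(parameters, function(p) {
    t <- rank_sum_test(a[, p], b[, p], mode = mode)
    data.frame(parameter = p, statistic = t$statistic, p_value = t$p_value)
  })
  res <- do.call(rbind, res)
  if (adjust == "BH") res$p_value <- stats::p.adjust(res$p_value, "BH")
  res$significant <- res$p_value < alpha
  res$alpha <- alpha
  structure(res, class = c("qfib_screen", "data.frame"))
}

#' @export
print.qfib_screen <- function(x, ...) {
  cat(sprintf("<qfib_screen> %d parameters tested, %d significant at p < %g\n",
              nrow(x), sum(x$significant), x$alpha[1]))
  sig <- x[x$significant, c("parameter", "p_value")]
  if (nrow(sig)) print.data.frame(utils::head(sig, 30), row.names = FALSE)
  invisible(x)
}

#' Build a discriminant parameter panel from screen results
#'
#' Retains, in schema order, every candidate parameter whose p-value is
#' strictly below alpha.
#'
#' @param results A `qfib_screen` (or data.frame with `parameter`,
#'   `p_value`).
#' @param candidates Candidate parameter names (canonical or aliases);
#'   default: all tested parameters.
#' @param alpha Retention threshold (default: the screen's alpha, else
#'   0.05).
#' @return Object of class `qfib_panel`: `candidate_names`,
#'   `retained_names`, `alpha`, `p_values`.
#' @export
build_panel <- function(results, candidates = NULL, alpha = NULL) {
  if (is.null(alpha)) alpha <- if ("alpha" %in% names(results)) results$alpha[1] else 0.05
  if (is.null(candidates)) candidates <- results$parameter
  candidates <- resolve_parameter_alias(candidates)
  missing <- setdiff(candidates, results$parameter)
  if (length(missing)) stop("no test result for candidate(s): ",
                            paste(missing, collapse = ", "))
  schema <- parameter_schema()
  candidates <- schema[schema %in% candidates]
  p <- results$p_value[match(candidates, results$parameter)]
  structure(list(candidate_names = candidates,
                 retained_names = candidates[p < alpha],
                 alpha = alpha,
                 p_values = stats::setNames(p, candidates)),
            class = "qfib_panel")
}

#' @export
print.qfib_panel <- function(x, ...) {
  cat(sprintf("<qfib_panel> %d of %d candidates retained at p < %g\n",
              length(x$retained_names), length(x$candidate_names), x$alpha))
  dropped <- setdiff(x$candidate_names, x$retained_names)
  if (length(dropped)) {
    cat("  dropped:", paste(sprintf("%s (p = %g)", dropped,
                                    x$p_values[dropped]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Two-stage screen and validation
#'
#' Stage 1 screens all 56 parameters on the discovery contrast (e.g. cases
#' whose fibrosis stage changed on consensus review versus cases that did
#' not). Stage 2 re-tests only the stage-1 significant parameters on the
#' validation contrast (true F1 versus true F2 cases); the discriminant
#' panel is built from stage 2.
#'
#' @param cohort_discovery A `qfib_cohort` for stage 1.
#' @param cohort_validation A `qfib_cohort` for stage 2.
#' @param groups_discovery,groups_validation Length-2 label vectors naming
#'   the contrast in each cohort.
#' @param alpha Significance level used at both stages.
#' @param mode Test mode passed to [rank_sum_test()].
#' @return Object of class `qfib_two_stage`: `screen` (stage-1
#'   `qfib_screen`), `validation` (stage-2 `qfib_screen` over stage-1 hits),
#'   `panel` (`qfib_panel`).
#' @export
screen_and_validate <- function(cohort_discovery, cohort_validation,
                                groups_discovery = c("changed", "unchanged"),
                                groups_validation = c("F1", "F2"),
                                alpha = 0.05, mode = "auto") {
  screen <- compare_groups(cohort_discovery, groups_discovery[1],
                           groups_discovery[2], alpha = alpha, mode = mode)
  hits <- screen$parameter[screen$significant]
  if (!length(hits)) {
    validation <- screen[0, , drop = FALSE]
    panel <- structure(list(candidate_names = character(0),
                            retained_names = character(0),
                            alpha = alpha, p_values = numeric(0)),
                       class = "qfib_panel")
  } else {
    validation <- compare_groups(cohort_validation, groups_validation[1],
                                 groups_validation[2], alpha = alpha,
                                 mode = mode, parameters = hits)
    panel <- build_panel(validation, candidates = hits, alpha = alpha)
  }
  structure(list(screen = screen, validation = validation, panel = panel),
            class = "qfib_two_stage")
}

#' @export
print.qfib_two_stage <- function(x, ...) {
  cat(sprintf("<qfib_two_stage> stage 1: %d/%d significant; stage 2: %d/%d retained\n",
              sum(x$screen$significant), nrow(x$screen),
              length(x$panel$retained_names), length(x$panel$candidate_names)))
  invisible(x)
}

#' Write a panel specification as JSON
#'
#' @param panel A `qfib_panel`.
#' @param path Output JSON path.
#' @param provenance Free-text comparison identifier stored in the file.
#' @return `path`, invisibly.
#' @export
write_panel_json <- function(panel, path, provenance = "") {
  jsonlite::write_json(
    list(candidate_names = panel$candidate_names,
         retained_names = panel$retained_names,
         alpha = panel$alpha,
         p_values = as.list(panel$p_values),
         provenance = provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
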