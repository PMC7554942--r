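test_that("exact rank-sum p-values match hand enumeration", {
  # {1,2,3} vs {4,5,6}: 2 of C(6,3)=20 assignments as extreme -> p = 0.1
  got <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(got$p_value, 0.1)
  expect_equal(got$statistic, 6)   # ranks 1+2+3
  expect_equal(got$mode, "exact")
  # identical multisets: perfectly symmetric null
  expect_equal(rank_sum_test(c(2, 2, 5), c(2, 5, 2))$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("exact mode equals brute-force enumeration on random samples", {
  set.seed(101)
  for (case in 1:200) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    vals <- sample(1000, nx + ny)          # tie-free
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(rank_sum_test(x, y, mode = "exact")$p_value,
                 enumerate_rank_sum_p(x, y), tolerance = 1e-12)
  }
})

test_that("the test is symmetric and invariant to monotone transforms", {
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(8); y <- rnorm(9, 0.5)
    p_xy <- rank_sum_test(x, y)$p_value
    expect_equal(p_xy, rank_sum_test(y, x)$p_value)
    expect_equal(p_xy, rank_sum_test(exp(x), exp(y))$p_value)
    expect_equal(p_xy, rank_sum_test(x^3, y^3)$p_value)
  }
})

test_that("exact and approximate p-values agree at moderate n", {
  set.seed(17)
  for (rep in 1:25) {
    x <- rnorm(8); y <- rnorm(8)
    pe <- rank_sum_test(x, y, mode = "exact")$p_value
    pa <- rank_sum_test(x, y, mode = "approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("auto mode switches at combined n = 16 and on ties", {
  expect_equal(rank_sum_test(1:8, 9:16)$mode, "exact")
  expect_equal(rank_sum_test(1:8, 9:17)$mode, "approx")
  expect_equal(rank_sum_test(c(1, 2, 2), c(3, 4, 5))$mode, "approx")
  expect_warning(rank_sum_test(c(1, 2, 2), c(3, 4, 5), mode = "exact"),
                 "ties")
})

test_that("the per-test false-positive rate is near the nominal level", {
  set.seed(1)
  p <- replicate(2000, rank_sum_test(rnorm(15), rnorm(15),
                                     mode = "approx")$p_value)
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("group screening flags strictly below alpha in schema order", {
  set.seed(33)
  n <- 10
  vals <- matrix(rnorm(2 * n * 56), 2 * n, 56,
                 dimnames = list(NULL, parameter_schema()))
  # inject a strong shift into one parameter
  vals[seq_len(n), "#StrPeriportal"] <- vals[seq_len(n), "#StrPeriportal"] + 50
  cohort <- cohort_table(vals, rep(c("a", "b"), each = n))
  res <- compare_groups(cohort, "a", "b")
  expect_identical(res$parameter, parameter_schema())
  expect_true(res$significant[res$parameter == "#StrPeriportal"])
  expect_identical(res$significant, res$p_value < 0.05)
  expect_error(compare_groups(cohort, "a", "nope"), "not present")
  # alpha extremes, on a cohort where every parameter is shifted
  vals2 <- vals + outer(rep(c(50, 0), each = n), rep(1, 56))
  cohort2 <- cohort_table(vals2, rep(c("a", "b"), each = n))
  expect_true(all(compare_groups(cohort2, "a", "b", alpha = 1)$significant))
  expect_false(any(compare_groups(cohort2, "a", "b", alpha = 0)$significant))
})

test_that("a p-value exactly at alpha is not significant", {
  res <- data.frame(parameter = c("%Periportal", "%RPS"),
                    p_value = c(0.05, 0.049999))
  panel <- build_panel(res, alpha = 0.05)
  expect_identical(panel$retained_names, "%RPS")
})

test_that("panel construction follows the retention rule on edge cases", {
  res <- data.frame(parameter = parameter_schema()[1:5], p_value = rep(1, 5))
  expect_length(build_panel(res)$retained_names, 0)
  res$p_value <- rep(0.001, 5)
  expect_identical(build_panel(res)$retained_names, parameter_schema()[1:5])
  expect_error(build_panel(res, candidates = "%RPS"), "no test result")
})

test_that("the reference validation p-values reproduce the 26-name panel", {
  ref <- reference_validation_pvalues()
  panel <- build_panel(ref, alpha = 0.05)
  expect_length(panel$candidate_names, 28)
  expect_length(panel$retained_names, 26)
  expect_setequal(setdiff(panel$candidate_names, panel$retained_names),
                  c("#ThinStrPeriportal", "#ThinStrPeriportalDis"))
})

test_that("two-stage screening validates only stage-1 hits", {
  set.seed(55)
  n <- 12
  mk_cohort <- function(shift_cols, labels) {
    vals <- matrix(rnorm(2 * n * 56), 2 * n, 56,
                   dimnames = list(NULL, parameter_schema()))
    vals[seq_len(n), shift_cols] <- vals[seq_len(n), shift_cols] + 40
    cohort_table(vals, rep(labels, each = n))
  }
  peri <- c("#StrPeriportal", "%Periportal", "StrAreaPeriportal")
  disc <- mk_cohort(peri, c("changed", "unchanged"))
  val <- mk_cohort(peri, c("F1", "F2"))
  ts <- screen_and_validate(disc, val)
  expect_identical(ts$validation$parameter,
                   ts$screen$parameter[ts$screen$significant])
  expect_identical(ts$panel$candidate_names,
                   parameter_schema()[parameter_schema() %in%
                                        ts$validation$parameter])
  expect_true(all(peri %in% ts$panel$retained_names))

  # empty stage 1 (all values tied -> p = 1 everywhere) -> empty panel
  flat <- matrix(1, 2 * n, 56, dimnames = list(NULL, parameter_schema()))
  ts0 <- screen_and_validate(cohort_table(flat, rep(c("changed", "unchanged"),
                                                    each = n)), val)
  expect_length(ts0$panel$candidate_names, 0)
  expect_equal(nrow(ts0$validation), 0)
})
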