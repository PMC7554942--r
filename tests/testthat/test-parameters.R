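test_that("the schema has 28 periportal followed by 28 RPS names", {
  s <- parameter_schema()
  expect_length(s, 56)
  expect_length(unique(s), 56)
  expect_true(all(grepl("Periportal", s[1:28])))
  expect_true(all(grepl("RPS", s[29:56])))
  # spot-check table order and spelling
  expect_equal(s[1], "%Periportal")
  expect_equal(s[4], "#StrPeriportal")
  expect_equal(s[28], "#IntersectionPeriportal")
  expect_equal(s[29], "%RPS")
  expect_equal(s[56], "#IntersectionRPS")
})

test_that("PS aliases resolve to canonical RPS names", {
  expect_equal(resolve_parameter_alias("#ThickStrPS"), "#ThickStrRPS")
  expect_equal(resolve_parameter_alias("StrWidthPSAgg"), "StrWidthRPSAgg")
  expect_equal(resolve_parameter_alias("%PS"), "%RPS")
  expect_equal(resolve_parameter_alias("#StrRPS"), "#StrRPS")
  expect_error(resolve_parameter_alias("#BogusStr"), "unknown parameter")
})

test_that("the name grammar parses region family, stratum and metric", {
  got <- classify_parameter_name("#LongStrPeriportalAgg")
  expect_equal(got$region_family, "periportal")
  expect_equal(got$stratum, "Agg")
  expect_equal(got$metric, "count")
  got2 <- classify_parameter_name("StrWidthPSAgg")
  expect_equal(got2$region_family, "perisinusoidal")
  expect_equal(got2$metric, "width")
  expect_equal(classify_parameter_name("%RPSDis")$metric, "percent")
  expect_equal(classify_parameter_name("#IntersectionRPS")$metric,
               "intersection")
})

test_that("the reference screen names split 20 periportal / 8 perisinusoidal", {
  info <- classify_parameter_name(reference_screen_pvalues()$parameter)
  expect_equal(sum(info$region_family == "periportal"), 20)
  expect_equal(sum(info$region_family == "perisinusoidal"), 8)
})

test_that("counts, sums and percentages follow the fiber bookkeeping", {
  regions <- uniform_regions(100, 100, region = "periportal")
  # 10 periportal fibers: 6 distributed, 4 aggregated
  f <- do.call(rbind, c(
    lapply(1:6, function(i) fiber_row("periportal", 50 + i, 20 + i)),
    lapply(1:4, function(i) fiber_row("periportal", 300 + i, 60 + i))
  ))
  pv <- compute_parameters(f, regions, c(periportal = 3, rps = 0))
  v <- pv$values
  expect_equal(v[["#StrPeriportal"]], 10)
  expect_equal(v[["#StrPeriportalAgg"]], 4)
  expect_equal(v[["#StrPeriportalDis"]], 6)
  expect_equal(v[["StrAreaPeriportal"]], sum(f$area_um2))
  expect_equal(v[["StrLengthPeriportal"]], sum(f$length_um))
  expect_equal(v[["StrWidthPeriportal"]], sum(f$width_um))
  expect_equal(v[["#IntersectionPeriportal"]], 3)
  # all RPS parameters zero
  expect_true(all(v[grepl("RPS", names(v))] == 0))
})

test_that("percentages are the collagen area fraction of the region", {
  regions <- uniform_regions(100, 100, region = "periportal")
  px_area <- calibration()$microns_per_pixel^2
  # one fiber of exactly 100 px in a 10000-px region -> 1%
  f <- fiber_row("periportal", 100 * px_area, 10)
  pv <- compute_parameters(f, regions)
  expect_equal(pv$values[["%Periportal"]], 1.0)
  expect_equal(pv$values[["%PeriportalDis"]], 1.0)
  expect_equal(pv$values[["%PeriportalAgg"]], 0)
})

test_that("no fibers means all 56 parameters are zero", {
  f <- extract_fibers(matrix(FALSE, 32, 32), uniform_regions(32, 32))
  pv <- compute_parameters(f, uniform_regions(32, 32))
  expect_true(all(pv$values == 0))
  expect_length(pv$values, 56)
})

test_that("aggregated and distributed strata add up across random fibersets", {
  set.seed(21)
  regions <- uniform_regions(200, 200, region = "rps")
  regions$periportal[, 1:60] <- TRUE
  regions$rps[, 1:60] <- FALSE
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    f <- do.call(rbind, lapply(seq_len(n), function(i) {
      fiber_row(sample(c("periportal", "rps"), 1),
                runif(1, 1, 500), runif(1, 2, 80))
    }))
    v <- compute_parameters(f, regions)$values
    for (tag in c("Periportal", "RPS")) {
      expect_equal(v[[paste0("%", tag)]],
                   v[[paste0("%", tag, "Agg")]] + v[[paste0("%", tag, "Dis")]],
                   tolerance = 1e-9)
      expect_equal(v[[paste0("#Str", tag)]],
                   v[[paste0("#Str", tag, "Agg")]] +
                     v[[paste0("#Str", tag, "Dis")]])
      expect_equal(v[[paste0("#Str", tag)]],
                   v[[paste0("#ShortStr", tag)]] + v[[paste0("#LongStr", tag)]])
      expect_equal(v[[paste0("#Str", tag)]],
                   v[[paste0("#ThinStr", tag)]] + v[[paste0("#ThickStr", tag)]])
    }
    # permutation invariance
    v2 <- compute_parameters(f[sample(nrow(f)), ], regions)$values
    expect_identical(v, v2)
  }
})

test_that("parameter vectors are invariant under slide translation", {
  m <- matrix(FALSE, 96, 96)
  m[30:32, 20:60] <- TRUE
  m[50, 30:70] <- TRUE
  shift10 <- function(x) qfib:::shift_mat(x * 1L, 10, 10) > 0
  regions <- uniform_regions(96, 96)
  f1 <- extract_fibers(m, regions)
  f2 <- extract_fibers(shift10(m), regions)
  v1 <- compute_parameters(f1, regions)$values
  v2 <- compute_parameters(f2, regions)$values
  expect_equal(v1, v2)
})

test_that("a zero-area region with collagen warns and reports 0 percent", {
  regions <- uniform_regions(32, 32, region = "rps")
  regions$periportal[, ] <- FALSE
  f <- fiber_row("periportal", 50, 10)
  expect_warning(pv <- compute_parameters(f, regions), "zero area")
  expect_equal(pv$values[["%Periportal"]], 0)
  expect_equal(pv$values[["#StrPeriportal"]], 1)
})

test_that("unknown fiber region labels are rejected", {
  f <- fiber_row("lobule", 50, 10)
  expect_error(compute_parameters(f, uniform_regions(16, 16)),
               "not in the region set")
})
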