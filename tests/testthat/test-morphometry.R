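cal <- calibration()
mpp <- cal$microns_per_pixel

test_that("skeleton arc length matches path-length arithmetic", {
  # straight 11-px horizontal segment: 10 unit steps
  m <- matrix(FALSE, 20, 20); m[10, 5:15] <- TRUE
  expect_equal(measure_length(m, cal), 10 * mpp)
  # 11-px 45-degree diagonal: 10 sqrt(2) steps
  d <- matrix(FALSE, 20, 20)
  for (i in 0:10) d[5 + i, 5 + i] <- TRUE
  expect_equal(measure_length(d, cal), 10 * sqrt(2) * mpp)
  # single pixel: declared one-pixel floor
  s <- matrix(FALSE, 5, 5); s[3, 3] <- TRUE
  expect_equal(measure_length(s, cal), mpp)
  expect_error(measure_length(matrix(FALSE, 5, 5), cal), "empty")
})

test_that("a 40-px line extracts as one fiber with the derived morphometry", {
  m <- matrix(FALSE, 64, 64); m[30, 11:50] <- TRUE
  f <- extract_fibers(m, uniform_regions(64, 64))
  expect_equal(nrow(f), 1)
  expect_equal(f$pixel_count, 40)
  expect_equal(f$area_um2, 40 * mpp^2)
  expect_equal(f$length_um, 39 * mpp)          # ~ 15.234 um
  expect_equal(f$width_um, f$area_um2 / f$length_um)
  expect_false(f$is_long); expect_false(f$is_thick)
})

test_that("disjoint blobs become separate fibers; empty mask gives none", {
  m <- matrix(FALSE, 64, 64)
  m[10:11, 10:14] <- TRUE        # 10 px blob
  m[40:41, 40:44] <- TRUE        # 10 px blob
  f <- extract_fibers(m, uniform_regions(64, 64))
  expect_equal(nrow(f), 2)
  expect_equal(f$pixel_count, c(10, 10))
  expect_equal(nrow(extract_fibers(matrix(FALSE, 8, 8),
                                   uniform_regions(8, 8))), 0)
})

test_that("class thresholds are inclusive dichotomies", {
  cfg <- morphometry_config()
  f <- rbind(fiber_row("rps", 25, 25),       # long (25 >= 20), thin (1 um)
             fiber_row("rps", 20 * 1, 20),   # boundary: exactly 20 um long
             fiber_row("rps", 3.5 * 10, 10), # width 3.5 -> thick
             fiber_row("rps", 3 * 10, 10),   # boundary: exactly 3 um wide
             fiber_row("rps", 250, 50),      # area 250 -> aggregated
             fiber_row("rps", 10, 10))       # area 10 -> distributed
  f <- classify_aggregation(classify_fibers(f, cfg), cfg)
  expect_equal(f$is_long, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(f$is_thick, c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(f$is_aggregated, c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # forced dichotomies: every fiber is exactly one of each pair
  expect_true(all(xor(f$is_long, !f$is_long)))
})

test_that("region assignment follows majority with periportal precedence", {
  nr <- 40
  tissue <- matrix(TRUE, nr, nr)
  empty <- matrix(FALSE, nr, nr)
  periportal <- empty; periportal[, 1:20] <- TRUE
  rps <- tissue & !periportal
  regions <- structure(list(portal = empty, periportal = periportal,
                            rps = rps, tissue = tissue, calibration = cal,
                            periportal_margin_um = 100),
                       class = "qfib_regions")
  m <- matrix(FALSE, nr, nr)
  m[10, 15:24] <- TRUE   # 6 px periportal, 4 px rps -> periportal
  m[30, 16:25] <- TRUE   # 5 px each -> tie -> periportal precedence
  f <- extract_fibers(m, regions)
  expect_equal(sort(f$region), c("periportal", "periportal"))
})

test_that("branch-point counting matches the neighbour-count oracle", {
  reg <- matrix(TRUE, 31, 31)
  # straight line: no branch point
  line <- matrix(FALSE, 31, 31); line[16, 6:26] <- TRUE
  expect_equal(count_intersections(line, reg, calibration = cal), 0)
  # "+" cross of two 21-px lines: one merged intersection
  cross <- matrix(FALSE, 31, 31)
  cross[16, 6:26] <- TRUE; cross[6:26, 16] <- TRUE
  expect_equal(count_intersections(cross, reg, calibration = cal), 1)
  # center outside the region mask: not counted there
  reg2 <- matrix(TRUE, 31, 31); reg2[10:22, 10:22] <- FALSE
  expect_equal(count_intersections(cross, reg2, calibration = cal), 0)
  # brute-force oracle on the skeleton
  sk <- skeletonize(cross)
  nb <- sapply(which(sk), function(i) {
    y <- (i - 1) %% 31 + 1; x <- (i - 1) %/% 31 + 1
    sum(sk[max(1, y - 1):min(31, y + 1), max(1, x - 1):min(31, x + 1)]) - 1
  })
  expect_gte(sum(nb >= 3), 1)   # raw branch pixels exist and merge to 1
})

test_that("morphometry is scale-equivariant in the calibration", {
  m <- matrix(FALSE, 48, 48)
  m[20:22, 10:40] <- TRUE
  cal2 <- calibration(mpp * 2, tile_pixels = 512, tile_microns = 400)
  f1 <- extract_fibers(m, uniform_regions(48, 48, cal = cal))
  f2 <- extract_fibers(m, uniform_regions(48, 48, cal = cal2))
  expect_equal(f2$length_um, 2 * f1$length_um)
  expect_equal(f2$area_um2, 4 * f1$area_um2)
  expect_equal(f2$width_um, 2 * f1$width_um)
})

test_that("extraction rejects collagen outside the tissue partition", {
  regions <- uniform_regions(16, 16)
  regions$tissue[, ] <- FALSE
  regions$rps[, ] <- FALSE
  m <- matrix(FALSE, 16, 16); m[8, 4:12] <- TRUE
  expect_error(extract_fibers(m, regions), "outside the tissue")
})
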