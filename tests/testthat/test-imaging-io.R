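test_that("calibration defaults to the 200 um / 512 px acquisition scale", {
  cal <- calibration()
  expect_equal(cal$microns_per_pixel, 0.390625)
  expect_error(calibration(-1), "positive")
  expect_error(calibration(0.5, tile_pixels = 512, tile_microns = 200),
               "inconsistent")
})

test_that("slides round-trip through 2-channel TIFF with SHG first", {
  set.seed(42)
  shg <- matrix(runif(32 * 32), 32, 32)
  tpef <- matrix(runif(32 * 32), 32, 32)
  slide <- dual_channel_slide(shg, tpef, sample_id = "rt")
  path <- withr::local_tempfile(fileext = ".tif")
  write_slide(slide, path, scale_max = 1)
  back <- read_slide(path, sample_id = "rt")
  # 16-bit storage quantises to ~1.5e-5
  expect_lt(max(abs(back$shg - shg)), 1e-4)
  expect_lt(max(abs(back$tpef - tpef)), 1e-4)
  expect_identical(dim(back$shg), dim(shg))
})

test_that("single-channel TIFF is rejected; paired files are accepted", {
  m <- matrix(runif(16 * 16), 16, 16)
  p1 <- withr::local_tempfile(fileext = ".tif")
  p2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m, p1, bits.per.sample = 16L)
  tiff::writeTIFF(m * 0.5, p2, bits.per.sample = 16L)
  expect_error(read_slide(p1), "channel count < 2")
  expect_error(read_slide("no/such/file.tif"), "not found")
  slide <- read_slide(c(p1, p2))
  expect_equal(slide$shg, m, tolerance = 1e-4)
  expect_equal(slide$tpef, m * 0.5, tolerance = 1e-4)
})

test_that("all-zero slides are valid and negative intensities are not", {
  z <- matrix(0, 64, 64)
  slide <- dual_channel_slide(z, z)
  expect_equal(max(slide$shg), 0)
  expect_equal(max(slide$tpef), 0)
  expect_error(dual_channel_slide(z - 1, z), "non-negative")
  expect_error(dual_channel_slide(z, matrix(0, 32, 32)), "identical dimensions")
})

test_that("stitching tiles a grid row-major with abutting offsets", {
  mk <- function(marker) {
    shg <- matrix(0, 8, 8)
    shg[1, 1] <- marker   # unique top-left corner marker
    dual_channel_slide(shg, matrix(1, 8, 8))
  }
  tiles <- lapply(1:6, mk)
  mosaic <- stitch_tiles(tiles, c(2, 3))
  expect_identical(dim(mosaic$shg), c(16L, 24L))
  # row-major: tile k sits at row (k-1) %/% 3, col (k-1) %% 3
  for (k in 1:6) {
    r <- ((k - 1) %/% 3) * 8 + 1
    cc <- ((k - 1) %% 3) * 8 + 1
    expect_equal(mosaic$shg[r, cc], k)
  }
  # 1x1 grid is the identity
  one <- stitch_tiles(tiles[1], c(1, 1))
  expect_equal(one$shg, tiles[[1]]$shg)
  expect_error(stitch_tiles(tiles, c(2, 2)), "rows \\* cols")
})

test_that("stitch after split reproduces the slide exactly", {
  set.seed(7)
  slide <- make_slide(matrix(runif(48 * 32), 48, 32),
                      matrix(runif(48 * 32), 48, 32))
  tiles <- split_into_tiles(slide, c(16, 16))
  expect_length(tiles, 6)
  back <- stitch_tiles(tiles, c(3, 2))
  expect_identical(back$shg, slide$shg)
  expect_identical(back$tpef, slide$tpef)
})

test_that("parameter tables round-trip losslessly and keep schema order", {
  set.seed(3)
  regions <- uniform_regions(32, 32)
  regions$periportal[, 1:16] <- TRUE
  regions$rps[, 1:16] <- FALSE
  mk <- function(id) {
    f <- rbind(fiber_row("rps", runif(1, 5, 400), runif(1, 4, 50)),
               fiber_row("periportal", runif(1, 5, 400), runif(1, 4, 50)))
    compute_parameters(f, regions, c(periportal = 2, rps = 1),
                       sample_id = id)
  }
  vecs <- lapply(c("a", "b", "c"), mk)
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(vecs, path)
  tab <- read_parameter_table(path)
  expect_equal(nrow(tab), 3)
  expect_equal(ncol(tab), 57)  # sample_id + 56
  expect_identical(names(tab)[-1], parameter_schema())
  for (i in 1:3) {
    expect_equal(unlist(tab[i, -1]), vecs[[i]]$values, tolerance = 1e-12)
  }
  # empty list gives a header-only table
  write_parameter_table(list(), path)
  expect_equal(nrow(read_parameter_table(path)), 0)
})

test_that("manifests validate ids, stages and resolve relative paths", {
  dir <- withr::local_tempdir()
  man <- data.frame(sample_id = c("s1", "s2"), stage_label = c("F1", "F2"),
                    group_label = c("g", "g"),
                    image_path = c("img1.tif", "/abs/img2.tif"),
                    portal_mask_path = c("m1.png", "m2.png"))
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  got <- read_manifest(path)
  expect_match(got$image_path[1], dir, fixed = TRUE)
  expect_equal(got$image_path[2], "/abs/img2.tif")

  man$sample_id <- c("s1", "s1")
  write.csv(man, path, row.names = FALSE)
  expect_error(read_manifest(path), "unique")
  man$sample_id <- c("s1", "s2"); man$stage_label <- c("F9", "F1")
  write.csv(man, path, row.names = FALSE)
  expect_error(read_manifest(path), "stage_label")
})

test_that("binary masks round-trip through PNG", {
  m <- disk_mask(20, 20, 10, 10, 5)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(m, path)
  expect_identical(read_mask(path), m)
})
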