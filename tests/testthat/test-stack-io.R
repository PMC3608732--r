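test_that("stack write/read round trip is pixel-exact with metadata", {
  frames <- array(sample(0:65535, 32 * 24 * 3, replace = TRUE), c(32, 24, 3))
  st <- image_stack(frames, c(0, 20, 40), pixel_size = 1.5,
                    meta = list(scenario = "control", seed = 7))
  path <- file.path(withr::local_tempdir(), "s.tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_equal(back$frames, st$frames)
  expect_equal(back$timestamps, st$timestamps)
  expect_equal(back$pixel_size, 1.5)
  expect_equal(back$meta$scenario, "control")
  # re-write of a read file is stable for pixel data
  path2 <- file.path(withr::local_tempdir(), "s2.tif")
  write_stack(back, path2)
  expect_identical(read_stack(path2)$frames, back$frames)
})

test_that("16-bit extremes survive the round trip", {
  frames <- array(c(0, 65535, 1, 65534), c(2, 2, 1))
  st <- image_stack(frames, 0, 1)
  path <- file.path(withr::local_tempdir(), "x.tif")
  write_stack(st, path)
  expect_equal(read_stack(path)$frames, frames)
})

test_that("metadata problems raise informative errors", {
  path <- file.path(withr::local_tempdir(), "m.tif")
  st <- image_stack(array(0, c(4, 4, 1)), 0, 1)
  write_stack(st, path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  meta$pixel_size <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_stack(path), "pixel_size")
  file.remove(paste0(path, ".json"))
  expect_error(read_stack(path), "sidecar")
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "no such")
})

test_that("stack invariants are enforced at construction", {
  f <- array(0, c(4, 4, 2))
  expect_error(image_stack(f, c(0, 0), 1), "strictly increasing")
  expect_error(image_stack(f, c(0, 1), -1), "pixel_size")
  expect_error(image_stack(f, 0, 1), "timestamps")
  expect_error(image_stack(array(-1, c(2, 2, 1)), 0, 1), "\\[0, 65535\\]")
})

test_that("masks round trip through PNG and TIFF, and reject RGB", {
  mask <- matrix((1:64 + rep(1:8, each = 8)) %% 2 == 0, 8, 8)  # checkerboard
  for (ext in c("png", "tif")) {
    p <- file.path(withr::local_tempdir(), paste0("m.", ext))
    write_mask(mask, p)
    expect_identical(read_mask(p), mask)
  }
  p0 <- file.path(withr::local_tempdir(), "zero.png")
  write_mask(matrix(FALSE, 5, 5), p0)
  expect_identical(read_mask(p0), matrix(FALSE, 5, 5))
  rgbp <- file.path(withr::local_tempdir(), "rgb.png")
  png::writePNG(array(0.5, c(4, 4, 3)), rgbp)
  expect_error(read_mask(rgbp), "multi-channel")
})

test_that("curve tables round trip through CSV", {
  tab <- data.frame(time_s = c(0, 20), L_V_um = c(123.456789, 0),
                    A_V_um2 = c(1e4, 0), A_T_um2 = c(1e6, 1e6),
                    FVD_per_um = c(1.23456789e-4, 0), D_V_um = c(20.1, NA))
  p <- file.path(withr::local_tempdir(), "c.csv")
  write_curves(tab, p)
  back <- read_curves(p)
  expect_equal(names(back), names(tab))
  expect_equal(back$FVD_per_um, tab$FVD_per_um, tolerance = 1e-6)
  # header-only case
  p2 <- file.path(withr::local_tempdir(), "e.csv")
  write_curves(tab[0, ], p2)
  expect_equal(nrow(read_curves(p2)), 0L)
  expect_error(write_curves(data.frame(x = 1), p2), "time_s")
})
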