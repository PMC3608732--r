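test_that("skeletonization reduces shapes to unit-width curves", {
  empty <- matrix(FALSE, 10, 10)
  expect_identical(skeletonize(empty), empty)
  # wide straight bar -> a single 1-px path
  bar <- matrix(FALSE, 60, 240); bar[21:40, 21:220] <- TRUE
  sk <- skeletonize(bar)
  expect_equal(max(ivtrace:::label8(sk)), 1L)
  expect_true(all(colSums(sk[, 50:190]) == 1))
  # two disjoint bars -> two skeleton components
  two <- matrix(FALSE, 60, 240)
  two[5:10, 20:100] <- TRUE; two[40:45, 120:200] <- TRUE
  expect_equal(max(ivtrace:::label8(skeletonize(two))), 2L)
})

test_that("skeleton length weights orthogonal and diagonal steps", {
  expect_equal(skeleton_length(matrix(FALSE, 5, 5)), 0)
  horiz <- matrix(FALSE, 3, 103); horiz[2, 2:102] <- TRUE
  expect_equal(skeleton_length(horiz, 5), 100 * 5)
  diag11 <- matrix(FALSE, 13, 13); diag11[cbind(2:12, 2:12)] <- TRUE
  expect_equal(skeleton_length(diag11, 1), 10 * sqrt(2))
})

test_that("the analytic rectangle yields the expected morphometry", {
  fx <- rectangle_fixture(500, 20, 1000, pixel_size = 2)
  rec <- compute_morphometry(fx$mask, fx$roi, fx$pixel_size, time = 0)
  expect_equal(rec$A_T_um2, 1e6)
  expect_equal(rec$A_V_um2, 10000)
  expect_equal(rec$FVD_per_um, 5e-4, tolerance = 0.05)
  expect_equal(rec$D_V_um, 20, tolerance = 0.05)
})

test_that("a locked tumor reports FVD 0 with missing D_V", {
  roi <- matrix(TRUE, 50, 50)
  rec <- compute_morphometry(matrix(FALSE, 50, 50), roi, 20)
  expect_equal(rec$FVD_per_um, 0)
  expect_true(is.na(rec$D_V_um))
  expect_error(compute_morphometry(matrix(FALSE, 5, 5),
                                   matrix(FALSE, 5, 5), 1), "A_T")
})

test_that("D_V is the length-weighted mean diameter on mixed networks", {
  n <- 600L
  mask <- matrix(FALSE, n, n)
  mask[91:110, 51:550] <- TRUE   # 500 x 20 px, d = 20 um at 1 um/px
  mask[241:250, 51:450] <- TRUE  # 400 x 10 px, d = 10 um
  roi <- matrix(TRUE, n, n)
  rec <- compute_morphometry(mask, roi, 1)
  lw <- (500 * 20 + 400 * 10) / (500 + 400)
  expect_equal(rec$D_V_um, lw, tolerance = 0.05)
})

test_that("FVD is monotone under adding perfused components", {
  base <- matrix(FALSE, 100, 100); base[10:15, 10:90] <- TRUE
  extra <- base; extra[60:65, 10:90] <- TRUE
  roi <- matrix(TRUE, 100, 100)
  f1 <- compute_morphometry(base, roi, 1)$FVD_per_um
  f2 <- compute_morphometry(extra, roi, 1)$FVD_per_um
  expect_gt(f2, f1)
})

test_that("pixel-size bookkeeping scales lengths and areas consistently", {
  fx <- rectangle_fixture(500, 20, 1000, pixel_size = 2)
  r1 <- compute_morphometry(fx$mask, fx$roi, 2)
  r2 <- compute_morphometry(fx$mask, fx$roi, 4)
  expect_equal(r2$L_V_um, 2 * r1$L_V_um)
  expect_equal(r2$A_V_um2, 4 * r1$A_V_um2)
  expect_equal(r2$A_T_um2, 4 * r1$A_T_um2)
  expect_equal(r2$D_V_um, 2 * r1$D_V_um)
  expect_equal(r2$FVD_per_um, r1$FVD_per_um / 2)
})

test_that("morphometry time series follows the perfusion scenario", {
  sc <- small_scene("EP", seed = 11L, noise_off = TRUE)
  st <- align_stack(sc$stack)$stack
  vessel <- sc$truth$vessel_mask_true
  roi <- sc$truth$roi_mask
  bg <- background_stats(st, vessel, roi, frame = 1L)
  m <- morphometry_series(st, vessel, roi, background = bg)
  expect_equal(nrow(m), dim(st)[3L])
  pre <- m$time_s < sc$truth$lock_start_s
  lock <- m$time_s >= sc$truth$lock_start_s &
    m$time_s < sc$truth$first_reperfusion_s
  expect_true(all(m$FVD_per_um[pre] > 0))
  expect_true(all(m$FVD_per_um[lock] == 0))
  after <- m$time_s >= sc$truth$first_reperfusion_s
  expect_true(any(m$FVD_per_um[after] > 0))
})
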