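make_curve <- function(times, values) {
  out <- data.frame(time_s = times, mean_intensity = values)
  class(out) <- c("compartment_curve", "data.frame")
  out
}

test_that("compartment means average the masked pixels per frame", {
  frames <- array(7, c(6, 6, 3))
  st <- image_stack(frames, c(0, 1, 2), 1)
  mask <- matrix(FALSE, 6, 6); mask[2:3, 2:3] <- TRUE
  cv <- compartment_means(st, mask)
  expect_equal(cv$mean_intensity, rep(7, 3))
  one <- matrix(FALSE, 6, 6); one[4, 5] <- TRUE
  st$frames[4, 5, ] <- c(1, 2, 3)
  expect_equal(compartment_means(st, one)$mean_intensity, c(1, 2, 3))
  expect_error(compartment_means(st, matrix(FALSE, 6, 6)), "empty")
})

test_that("intravascular means track the plasma curve in a clean scene", {
  sc <- small_scene("control", seed = 11L)
  al <- align_stack(sc$stack)
  cv <- compartment_means(al$stack, sc$truth$vessel_mask_true)
  model <- plasma_concentration(cv$time_s, tracer_kinetics())
  expect_gt(cor(cv$mean_intensity, model), 0.99)
})

test_that("Imax normalization is exact, bounded and idempotent", {
  cv <- make_curve(c(0, 1, 2), c(1, 2, 4))
  nz <- normalize_to_imax(cv)
  expect_equal(nz$normalized_pct, c(25, 50, 100))
  expect_equal(attr(nz, "Imax"), 4)
  expect_equal(normalize_to_imax(nz)$normalized_pct, nz$normalized_pct)
  expect_equal(max(nz$normalized_pct), 100)
  expect_error(normalize_to_imax(make_curve(0:2, rep(0, 3))), "not positive")
})

test_that("relative variation is measured against the baseline window", {
  cv <- make_curve(0:4, rep(3, 5))
  expect_equal(relative_variation(cv, 1:2)$relative_variation, rep(0, 5))
  cv2 <- make_curve(0:2, c(10, 10, 15))
  expect_equal(relative_variation(cv2, 1:2)$relative_variation[3], 0.5)
  expect_error(relative_variation(make_curve(0:2, c(0, 0, 1)), 1:2),
               "positive")
  expect_error(relative_variation(cv, integer(0)), "empty")
})

test_that("filling time interpolates the threshold crossing", {
  step <- normalize_to_imax(make_curve(c(0, 30, 60, 90), c(0, 0, 100, 100)))
  expect_equal(filling_time(step, 80), 30 + 0.8 * 30)
  expect_equal(filling_time(step, 100), 60)
  truncated <- make_curve(c(0, 10), c(50, 60))
  truncated$normalized_pct <- c(10, 20)   # Imax anchored outside this window
  expect_true(is.na(filling_time(truncated, 99)))
  expect_error(filling_time(step, 0), "fraction")
})

test_that("lock duration handles recovery, censoring and no-lock", {
  t <- seq(0, 1000, by = 100)
  high <- rep(10, length(t))
  expect_equal(lock_duration(t, high, 10, treatment_time = 200)$duration_s, 0)
  locked <- ifelse(t >= 200, 0, 10)
  res <- lock_duration(t, locked, 10, treatment_time = 200)
  expect_equal(res$duration_s, 800)
  expect_true(res$censored)
  recover <- ifelse(t >= 200 & t < 600, 0, 10)
  res2 <- lock_duration(t, recover, 10, f = 0.05, treatment_time = 200)
  # crossing interpolated between 500 (0) and 600 (10) at 0.5
  expect_equal(res2$duration_s, 500 + 100 * 0.05 - 200)
  expect_false(res2$censored)
  expect_error(lock_duration(t, high, 0, treatment_time = 200), "baseline")
  expect_error(lock_duration(t, high, 10, treatment_time = 5000), "outside")
})

test_that("leakage onset requires a persistent excursion", {
  t <- seq(0, 400, by = 20)
  base <- sin(seq_along(t)) * 1e-3
  curve <- make_curve(t, rep(1, length(t)))
  curve$relative_variation <- base
  expect_true(is.na(leakage_onset(curve, 1:5, treatment_time = 100)))
  spike <- base; spike[15] <- 1
  curve$relative_variation <- spike
  expect_true(is.na(leakage_onset(curve, 1:5, treatment_time = 100)))
  ramp <- base; ramp[t >= 240] <- 0.5
  curve$relative_variation <- ramp
  expect_equal(leakage_onset(curve, 1:5, treatment_time = 100), 140)
  expect_error(leakage_onset(curve, 1:30, treatment_time = 100),
               "precede")
})

test_that("leakage is confined to scenes with re-perfused vessels", {
  # ECT: everything locked, no tracer supply, no leakage call
  sc <- small_scene("ECT", seed = 11L)
  al <- align_stack(sc$stack)
  ev <- extravascular_mask(sc$truth$vessel_mask_true, sc$truth$roi_mask)
  cv <- compartment_means(al$stack, ev)
  win <- which(cv$time_s < 130)
  cv <- relative_variation(cv, win)
  expect_true(is.na(leakage_onset(cv, win, treatment_time = 130)))
  expect_true(is.na(sc$truth$true_leakage_onset_s))
  # EP with early re-perfusion: onset recovered within one frame interval
  scl <- small_scene("EP", seed = 11L, variant = "leakage")
  all2 <- align_stack(scl$stack)
  ev2 <- extravascular_mask(scl$truth$vessel_mask_true, scl$truth$roi_mask)
  cv2 <- relative_variation(compartment_means(all2$stack, ev2), win)
  onset <- leakage_onset(cv2, win, treatment_time = 130)
  expect_lt(abs(onset - (scl$truth$true_leakage_onset_s - 130)), 21)
})
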