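test_that("reference projection is the pixelwise maximum over the window", {
  sc <- small_scene("control", seed = 11L)
  st <- sc$stack
  expect_identical(reference_projection(st, 5L), st$frames[, , 5L])
  proj <- reference_projection(st)
  for (i in c(1L, 10L, dim(st)[3L]))
    expect_true(all(proj >= st$frames[, , i]))
  a <- matrix(0, 8, 8); a[2, 2] <- 100
  b <- matrix(0, 8, 8); b[6, 6] <- 50
  two <- image_stack(array(c(a, b), c(8, 8, 2)), c(0, 1), 1)
  expect_equal(reference_projection(two), pmax(a, b))
  expect_error(reference_projection(st, integer(0)), "empty")
  expect_error(reference_projection(st, 999L), "outside")
})

test_that("vessel segmentation recovers the rendered network", {
  sc <- small_scene("control", seed = 11L, noise_off = TRUE)
  al <- align_stack(sc$stack)
  mask <- segment_vessels(reference_projection(al$stack))
  truth_px <- sum(sc$truth$vessel_mask_true)
  expect_lt(abs(sum(mask) - truth_px) / truth_px, 0.05)
  expect_error(segment_vessels(matrix(7, 30, 30)), "degenerate")
})

test_that("small components are removed by the size filter", {
  ref <- matrix(100, 60, 60)
  ref[20:40, 20:40] <- 50000            # big blob stays
  ref[5, 5:6] <- 50000                  # 2-px speck goes
  mask <- segment_vessels(ref, opening_radius_px = 0L, min_component_px = 10L)
  expect_true(all(mask[20:40, 20:40]))
  expect_false(any(mask[5, 5:6]))
})

test_that("hand corrections combine and conflict as specified", {
  mask <- matrix(FALSE, 10, 10); mask[3:5, 3:5] <- TRUE
  expect_identical(apply_corrections(mask), mask)
  full <- matrix(TRUE, 10, 10)
  expect_identical(apply_corrections(mask, add_mask = full), full)
  two <- mask; two[8:9, 8:9] <- TRUE
  rm2 <- matrix(FALSE, 10, 10); rm2[8:9, 8:9] <- TRUE
  corrected <- apply_corrections(two, remove_mask = rm2)
  expect_equal(max(ivtrace:::label8(corrected)),
               max(ivtrace:::label8(two)) - 1L)
  bad <- matrix(FALSE, 10, 10); bad[3, 3] <- TRUE
  expect_error(apply_corrections(mask, add_mask = bad, remove_mask = bad),
               "conflict")
  expect_error(apply_corrections(mask, add_mask = matrix(FALSE, 5, 5)),
               "shape")
})

test_that("compartments partition the tumor ROI", {
  sc <- small_scene("control", seed = 11L)
  roi <- sc$truth$roi_mask
  vessel <- sc$truth$vessel_mask_true
  ev <- extravascular_mask(vessel, roi)
  expect_false(any(ev & vessel))
  expect_identical(ev | (vessel & roi), roi)
  expect_identical(extravascular_mask(matrix(FALSE, 5, 5),
                                      matrix(TRUE, 5, 5)),
                   matrix(TRUE, 5, 5))
  expect_identical(extravascular_mask(matrix(TRUE, 5, 5),
                                      matrix(TRUE, 5, 5)),
                   matrix(FALSE, 5, 5))
})

test_that("perfusion calls match the scenario ground truth", {
  for (scen in c("control", "ECT")) {
    sc <- small_scene(scen, seed = 11L, noise_off = TRUE)
    st <- align_stack(sc$stack)$stack
    vessel <- sc$truth$vessel_mask_true
    roi <- sc$truth$roi_mask
    bg <- background_stats(st, vessel, roi, frame = 1L)
    post <- which(st$timestamps > 140)[1L]
    pm <- perfused_mask_at(st, vessel, post, background = bg)
    if (scen == "control") expect_identical(pm, vessel)
    else expect_false(any(pm))
    expect_true(all(!pm | vessel))  # perfused subset of vessel mask
  }
})

test_that("EP perfusion calls track per-segment reperfusion times", {
  sc <- small_scene("EP", seed = 11L, noise_off = TRUE)
  st <- align_stack(sc$stack)$stack
  vessel <- sc$truth$vessel_mask_true
  bg <- background_stats(st, vessel, sc$truth$roi_mask, frame = 1L)
  for (k_sd in c(2, 5)) {
    for (ti in seq_along(st$timestamps)) {
      t <- st$timestamps[ti]
      pm <- perfused_mask_at(st, vessel, ti, k_sd = k_sd, background = bg)
      truth_state <- t < sc$truth$lock_start_s | t >= sc$truth$reperfusion_time_s
      for (s in seq_along(sc$truth$segment_idx)) {
        px <- sc$truth$segment_idx[[s]]
        expect_equal(all(pm[px]), truth_state[s],
                     info = sprintf("t=%g seg=%d k=%g", t, s, k_sd))
      }
    }
  }
})

test_that("perfusion background rule needs a pre-injection frame or stats", {
  sc <- small_scene("control", seed = 11L)
  st <- sc$stack
  st$meta$injection_time <- -10      # injection precedes acquisition
  expect_error(perfused_mask_at(st, sc$truth$vessel_mask_true, 3L),
               "pre-injection")
})
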