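test_that("network generation is deterministic in the seed", {
  spec <- vessel_network_spec(seed = 3L)
  a <- build_network(spec)
  b <- build_network(spec)
  expect_identical(a$segments, b$segments)
  expect_identical(a$truth$L_V_um, b$truth$L_V_um)
  c <- build_network(vessel_network_spec(seed = 4L))
  expect_false(identical(a$segments, c$segments))
})

test_that("analytic truth of a straight rectangle is exact", {
  spec <- vessel_network_spec(field_height_px = 200L, field_width_px = 600L,
                              pixel_size = 1,
                              tumor_roi = cbind(c(5, 5, 194, 194),
                                                c(5, 594, 594, 5)),
                              n_segments = 1L, seed = 1L)
  segs <- list(list(centerline = cbind(rep(100, 2L), c(50, 550)),
                    diameter = 20, region_tag = "tumor"))
  truth <- ivtrace:::network_truth(segs, spec)
  expect_equal(truth$L_V_um, 500)
  expect_equal(truth$A_V_um2, 10000)
  expect_equal(truth$D_V_um, 20)
  # conservation-of-geometry identities
  expect_equal(truth$FVD_per_um, truth$L_V_um / truth$A_T_um2)
  expect_equal(truth$D_V_um, truth$A_V_um2 / truth$L_V_um)
})

test_that("sampled diameters follow the requested distribution", {
  spec <- vessel_network_spec(field_height_px = 1200L, field_width_px = 1200L,
                              pixel_size = 1.5, n_segments = 60L,
                              peritumoral_fraction = 0,
                              diameter_mean = 20, diameter_sd = 4,
                              calibrate_dv = FALSE, seed = 8L)
  d <- build_network(spec)$truth$segment_diameter_um
  expect_length(d, 60L)
  expect_true(all(d > 2 * spec$pixel_size))
  se <- 4 / sqrt(60)
  expect_lt(abs(mean(d) - 20), 2 * se)
})

test_that("calibrated networks pin the length-weighted tumor diameter", {
  for (s in c(2L, 9L)) {
    truth <- build_network(vessel_network_spec(seed = s))$truth
    expect_equal(truth$D_V_um, 20, tolerance = 1e-10)
    expect_equal(truth$FVD_per_um * truth$A_T_um2, truth$L_V_um)
  }
})

test_that("segments stay on their side of the ROI and do not touch", {
  spec <- vessel_network_spec(seed = 5L)
  net <- build_network(spec)
  raster <- prepare_scene_raster(net, spec, noise_model())
  roi <- net$truth$roi_mask
  for (i in seq_along(net$segments)) {
    px <- raster$segment_idx[[i]]
    if (net$segments[[i]]$region_tag == "tumor")
      expect_true(all(roi[px]))
    else
      expect_true(all(!roi[px]))
  }
  expect_equal(max(ivtrace:::label8(raster$vessel_mask)),
               spec$n_segments)
})

test_that("invalid network specs are rejected", {
  expect_error(vessel_network_spec(n_segments = 0L), "n_segments")
  expect_error(vessel_network_spec(field_height_px = -1L), "field")
  expect_error(vessel_network_spec(diameter_mean = 0), "diameter_mean")
  expect_error(vessel_network_spec(tumor_roi = cbind(c(-5, 5, 5),
                                                     c(5, 5, 50))),
               "inside the field")
})
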