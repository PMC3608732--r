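# Small, fast scene configurations for unit tests, plus memoized full-size
# scenes shared by the acceptance tests. Everything is generated in code
# with fixed seeds.

small_config <- function(scenario = "control", variant = "lock") {
  cfg <- default_config(scenario, variant)
  cfg$scene$field_height_px <- 192L
  cfg$scene$field_width_px <- 192L
  cfg$scene$n_segments <- 4L
  cfg$scene$peritumoral_fraction <- 0.25
  cfg$scene$diameter_mean <- 12
  cfg$scene$diameter_sd <- 2
  cfg$schedule$series <- list(c(0, 20, 120), c(140, 20, 120), c(380, 120, 720))
  cfg
}

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, maker) {
  if (!exists(key, envir = .scene_cache))
    assign(key, maker(), envir = .scene_cache)
  get(key, envir = .scene_cache)
}

small_scene <- function(scenario = "control", seed = 11L, noise_off = FALSE,
                        variant = "lock") {
  key <- paste("small", scenario, variant, seed, noise_off, sep = "_")
  cached_scene(key, function() {
    cfg <- small_config(scenario, variant)
    parts <- ivtrace:::scene_from_config(cfg, seed = seed)
    scene <- simulate_stack(parts$spec, parts$scenario, parts$kinetics,
                            parts$schedule, parts$noise, seed = seed,
                            noise_off = noise_off)
    scene$config <- cfg
    scene
  })
}

# full-size study-condition scenes for acceptance checks (simulated +
# analyzed once, shared across test blocks)
full_run <- function(scenario = "control", variant = "lock", seed = 1L) {
  key <- paste("full", scenario, variant, seed, sep = "_")
  cached_scene(key, function() {
    cfg <- default_config(scenario, variant)
    parts <- ivtrace:::scene_from_config(cfg, seed = seed)
    scene <- simulate_stack(parts$spec, parts$scenario, parts$kinetics,
                            parts$schedule, parts$noise, seed = seed)
    res <- analyze_run(scene$stack, cfg)
    list(scene = scene, res = res, cfg = cfg)
  })
}

# analytic rectangle fixture: a length x width bar (um) inside a square ROI
rectangle_fixture <- function(length_um = 500, width_um = 20,
                              roi_um = 1000, pixel_size = 2) {
  n <- roi_um / pixel_size
  mask <- matrix(FALSE, n, n)
  l_px <- length_um / pixel_size
  w_px <- width_um / pixel_size
  r0 <- round(n / 2 - w_px / 2) + 1L
  c0 <- round(n / 2 - l_px / 2) + 1L
  mask[r0:(r0 + w_px - 1L), c0:(c0 + l_px - 1L)] <- TRUE
  roi <- matrix(TRUE, n, n)
  list(mask = mask, roi = roi, pixel_size = pixel_size)
}
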