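static_texture <- function(noise, height, width) {
  if (noise$texture_sd == 0) return(matrix(0, height, width))
  set.seed(noise$seed + 101L)
  z <- matrix(stats::rnorm(height * width), height, width)
  z <- gaussian_blur(z, noise$texture_scale_px / 2)
  z <- z - mean(z)
  z * (noise$texture_sd / stats::sd(z))
}

# Separable FFT-free Gaussian blur via EBImage (reflective boundary).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sz <- 2L * ceiling(3 * sigma) + 1L
  as.matrix(EBImage::filter2(EBImage::Image(m),
                             EBImage::makeBrush(sz, "gaussian", sigma = sigma)))
}

# Pixel indices covered by a segment: each polyline edge is drawn as a
# butt-ended band (pixel centers within perpendicular distance diameter/2
# of the edge), with disks at interior joints to fill bend wedges. Ends are
# left flat so the rasterized area matches the analytic length x diameter
# ground truth. A segment narrower than one pixel after rasterization is
# drawn 1 px wide (with a warning).
rasterize_segment <- function(segment, height, width, pixel_size) {
  d_px <- segment$diameter / pixel_size
  r <- d_px / 2
  cl <- segment$centerline
  hit <- logical(height * width)
  mark_disk <- function(cy, cx, rad) {
    y0 <- max(0L, floor(cy - rad)); y1 <- min(height - 1L, ceiling(cy + rad))
    x0 <- max(0L, floor(cx - rad)); x1 <- min(width - 1L, ceiling(cx + rad))
    if (y0 > y1 || x0 > x1) return(invisible())
    ys <- y0:y1; xs <- x0:x1
    dy2 <- (ys - cy)^2
    for (x in xs) {
      sel <- dy2 + (x - cx)^2 < rad^2
      if (any(sel)) hit[ys[sel] + 1L + x * height] <<- TRUE
    }
  }
  n <- nrow(cl)
  if (n == 1L) {
    mark_disk(cl[1L, 1L], cl[1L, 2L], max(r, 0.51))
  } else {
    for (i in seq_len(n - 1L)) {
      p <- cl[i, ]; q <- cl[i + 1L, ]
      v <- q - p; L2 <- sum(v^2)
      y0 <- max(0L, floor(min(p[1L], q[1L]) - r - 1))
      y1 <- min(height - 1L, ceiling(max(p[1L], q[1L]) + r + 1))
      x0 <- max(0L, floor(min(p[2L], q[2L]) - r - 1))
      x1 <- min(width - 1L, ceiling(max(p[2L], q[2L]) + r + 1))
      if (y0 > y1 || x0 > x1) next
      ys <- y0:y1; xs <- x0:x1
      Y <- matrix(rep(ys, length(xs)), length(ys))
      X <- matrix(rep(xs, each = length(ys)), length(ys))
      tt <- if (L2 == 0) 0 else ((Y - p[1L]) * v[1L] + (X - p[2L]) * v[2L]) / L2
      dist2 <- (Y - (p[1L] + tt * v[1L]))^2 + (X - (p[2L] + tt * v[2L]))^2
      sel <- tt >= 0 & tt <= 1 & dist2 < r^2
      if (any(sel)) hit[Y[sel] + 1L + X[sel] * height] <- TRUE
    }
    if (n > 2L)
      for (i in 2:(n - 1L)) mark_disk(cl[i, 1L], cl[i, 2L], r)
  }
  idx <- which(hit)
  if (length(idx) == 0L) {
    warning("segment thinner than one pixel after rasterization; drawing 1 px wide")
    # fall back: nearest pixel to each centerline vertex
    py <- pmin(pmax(round(cl[, 1L]), 0L), height - 1L)
    px <- pmin(pmax(round(cl[, 2L]), 0L), width - 1L)
    idx <- unique(py + 1L + px * height)
  }
  idx
}

# Integer-pixel translation with constant fill.
translate_int <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1L & src_r <= h; ok_c <- src_c >= 1L & src_c <= w
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Render one synthetic frame
#'
#' Perfused segments are rasterized as their centerline dilated to their
#' diameter at intensity proportional to the intravascular concentration;
#' unperfused segments sit at background; extravascular tumor-ROI pixels
#' carry the extravascular concentration. Read noise and intensity-scaled
#' shot noise are added, the frame is translated by the injected cumulative
#' drift, and values are clipped to the 16-bit range.
#'
#' @param scene_px precomputed raster (from [prepare_scene_raster]): segment
#'   pixel-index lists, ROI mask and background texture.
#' @param perfused logical per-segment perfusion state.
#' @param C_iv,C_ev intravascular / extravascular intensities (units).
#' @param noise a [noise_model] (`NULL` disables noise; drift still applies
#'   via `shift`).
#' @param shift integer `(dy, dx)` cumulative drift for this frame.
#' @param t frame time (s), used for photobleaching.
#' @return numeric matrix, a 16-bit-range frame.
#' @export
render_frame <- function(scene_px, perfused, C_iv, C_ev, noise = NULL,
                         shift = c(0L, 0L), t = 0) {
  h <- scene_px$height; w <- scene_px$width
  canvas <- matrix(scene_px$background_level, h, w) + scene_px$texture
  ev_idx <- scene_px$extravascular_idx
  if (C_ev > 0) canvas[ev_idx] <- canvas[ev_idx] + C_ev
  if (any(perfused) && C_iv > 0) {
    pix <- unique(unlist(scene_px$segment_idx[perfused]))
    canvas[pix] <- scene_px$background_level +
      scene_px$texture[pix] + C_iv
  }
  if (!is.null(noise) && noise$bleach_rate > 0)
    canvas <- canvas * exp(-noise$bleach_rate * t)
  if (any(shift != 0L))
    canvas <- translate_int(canvas, shift[1L], shift[2L], stats::median(canvas))
  if (!is.null(noise) && (noise$read_noise_sd > 0 || noise$photon_scale > 0)) {
    canvas <- canvas +
      stats::rnorm(h * w, 0, noise$read_noise_sd) +
      stats::rnorm(h * w, 0, 1) * sqrt(noise$photon_scale * pmax(canvas, 0))
  }
  pmin(pmax(round(canvas), 0), 65535)
}

#' Precompute the per-scene raster used by [render_frame]
#'
#' @param network output of [build_network].
#' @param spec the [vessel_network_spec] used to build it.
#' @param noise a [noise_model] (for background level and texture).
#' @return A list with segment pixel indices, the ROI and vessel masks, the
#'   extravascular pixel indices and the static background texture.
#' @export
prepare_scene_raster <- function(network, spec, noise) {
  h <- spec$field_height_px; w <- spec$field_width_px
  seg_idx <- lapply(network$segments, rasterize_segment,
                    height = h, width = w, pixel_size = spec$pixel_size)
  vessel <- matrix(FALSE, h, w)
  vessel[unlist(seg_idx)] <- TRUE
  roi <- network$truth$roi_mask
  list(height = h, width = w, segment_idx = seg_idx,
       vessel_mask = vessel, roi_mask = roi,
       extravascular_idx = which(roi & !vessel),
       background_level = noise$background_level,
       texture = static_texture(noise, h, w))
}

#' Simulate a full window-chamber movie with ground truth
#'
#' Renders one frame per schedule timestamp: the per-segment perfusion state
#' comes from the scenario timeline, the intravascular intensity from the
#' plasma curve, and the extravascular intensity from the gated leakage
#' accumulator evaluated on a fine grid. The result is fully reproducible
#' from the seed.
#'
#' @param spec a [vessel_network_spec].
#' @param scenario a [perfusion_scenario] (or a scenario name, in which case
#'   defaults are used).
#' @param kinetics a [tracer_kinetics].
#' @param schedule an [acquisition_schedule].
#' @param noise a [noise_model]; `noise_off = TRUE` keeps the drift and
#'   background but suppresses the stochastic noise terms.
#' @param seed master seed for the noise stream.
#' @param noise_off logical, render without stochastic noise.
#' @return A list of class `scene` with `stack` (an [image_stack]) and
#'   `truth` (a `scene_truth` augmented with the perfusion timeline, kinetic
#'   constants, injected drift and true readout times).
#' @export
simulate_stack <- function(spec, scenario, kinetics = tracer_kinetics(),
                           schedule = acquisition_schedule(),
                           noise = noise_model(), seed = 1L,
                           noise_off = FALSE) {
  stopifnot(inherits(spec, "vessel_network_spec"),
            inherits(kinetics, "tracer_kinetics"),
            inherits(schedule, "acquisition_schedule"),
            inherits(noise, "noise_model"))
  network <- build_network(spec)
  if (is.character(scenario))
    scenario <- perfusion_scenario(scenario, n_segments = spec$n_segments,
                                   diameters = network$truth$segment_diameter_um,
                                   seed = spec$seed)
  stopifnot(inherits(scenario, "perfusion_scenario"))
  times <- schedule_times(schedule)
  raster <- prepare_scene_raster(network, spec, noise)

  tum <- network$truth$region_tag == "tumor"
  # gated extravascular accumulator on a fine grid
  fine <- sort(unique(c(seq(min(times), max(times), by = 5), times,
                        scenario$lock_start, scenario$reperfusion_time[
                          is.finite(scenario$reperfusion_time)])))
  fine <- fine[fine >= min(times) & fine <= max(times)]
  gate_fine <- vapply(fine, function(t) any(perfused_at(scenario, t)[tum]), TRUE)
  C_ev_fine <- extravascular_concentration(fine, kinetics, gate_fine)
  C_ev <- C_ev_fine[match(times, fine)]
  C_iv <- plasma_concentration(times, kinetics)

  cum_shift <- cbind(round((seq_along(times) - 1L) * noise$drift_per_frame[1L]),
                     round((seq_along(times) - 1L) * noise$drift_per_frame[2L]))
  frames <- array(0, dim = c(spec$field_height_px, spec$field_width_px,
                             length(times)))
  set.seed(seed)
  for (i in seq_along(times)) {
    frames[, , i] <- render_frame(
      raster, perfused_at(scenario, times[i]), C_iv[i], C_ev[i],
      noise = if (noise_off) NULL else noise,
      shift = cum_shift[i, ], t = times[i])
  }

  onset_idx <- which(gate_fine &
                       fine >= kinetics$t0 + kinetics$leakage_onset_delay &
                       kinetics$k_perm > 0)
  truth <- network$truth
  truth$scenario <- scenario$scenario
  truth$treatment_time_s <- scenario$treatment_time
  truth$lock_start_s <- scenario$lock_start
  truth$reperfusion_time_s <- scenario$reperfusion_time
  truth$first_reperfusion_s <- suppressWarnings(min(scenario$reperfusion_time))
  truth$kinetics <- unclass(kinetics)
  truth$true_leakage_onset_s <- if (length(onset_idx)) fine[min(onset_idx)] else NA_real_
  truth$drift_px <- cum_shift
  truth$vessel_mask_true <- raster$vessel_mask
  truth$segment_idx <- raster$segment_idx

  stack <- image_stack(frames, times, spec$pixel_size,
                       meta = list(seed = seed, scenario = scenario$scenario,
                                   injection_time = kinetics$t0,
                                   treatment_time = scenario$treatment_time))
  structure(list(stack = stack, truth = truth, scenario = scenario,
                 spec = spec, kinetics = kinetics, noise = noise),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("synthetic scene: scenario '%s'\n", x$scenario$scenario))
  print(x$stack)
  print(x$truth)
  invisible(x)
}
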