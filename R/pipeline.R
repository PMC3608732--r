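#' Default run configuration
#'
#' Nested configuration for the simulate/analyze/compare pipeline, writable
#' to YAML. Scene, kinetics and noise defaults reproduce the study
#' conditions: a 448 x 448 um field at 1 um/px with a ~20 um calibrated
#' vessel network, mono-exponential filling with `tau = 120/log(5)` s
#' (80% at 2 min), treatment in the 20 s pause between the first two
#' acquisition series (130 s), a 600 s complete EP lock, and leakage
#' beginning 120 s after treatment in re-perfused vessels.
#'
#' @param scenario one of `"control"`, `"bleomycin"`, `"EP"`, `"ECT"`.
#' @param variant `"lock"` (default) or, for EP, `"leakage"` or
#'   `"dv_foldchange"`. The leakage variant reperfuses a fraction of
#'   vessels 60 s after treatment - the rapidly recovering vessels from
#'   which post-EP extravasation originates. The fold-change variant gives
#'   half the tumor segments a 40 um diameter and the other half 12 um and
#'   reperfuses only the large ones, so the perfused-subset true diameter
#'   is exactly twice the 20 um control value.
#' @return nested list of class `ivtrace_config`.
#' @export
default_config <- function(scenario = c("control", "bleomycin", "EP", "ECT"),
                           variant = c("lock", "leakage", "dv_foldchange")) {
  scenario <- match.arg(scenario)
  variant <- match.arg(variant)
  treatment <- 130
  # modest permeability: extravascular signal stays a few percent of the
  # intravascular plateau over the hour, as observed for dextran leakage
  k_perm <- if (scenario %in% c("EP", "ECT")) 1e-5 else 0
  cfg <- list(
    scene = list(field_height_px = 448L, field_width_px = 448L,
                 pixel_size = 1.5, n_segments = 9L,
                 peritumoral_fraction = 1/3,
                 diameter_mean = 20, diameter_sd = 4, tortuosity = 0.15,
                 calibrate_dv = TRUE, seed = 1L),
    scenario = list(name = scenario, treatment_time = treatment,
                    lock_duration = 600, reperfused_fraction = 0.5,
                    stagger = 100, reperfuse_rule = "random",
                    early_reperfusion_fraction =
                      if (scenario == "EP" && variant == "leakage") 0.3 else 0,
                    early_reperfusion_delay = 60,
                    perfused_fraction_late = 0),
    kinetics = list(t0 = -10, tau = 120 / log(5), A = 20000,
                    k_perm = k_perm,
                    leakage_onset_delay = treatment + 120 - (-10)),
    schedule = list(series = list(c(0, 20, 120), c(140, 20, 120),
                                  c(380, 120, 3360))),
    noise = list(read_noise_sd = 4, photon_scale = 0.5,
                 drift_per_frame = c(0.2, -0.15), background_level = 100,
                 texture_sd = 12, texture_scale_px = 12, bleach_rate = 0),
    segmentation = list(opening_radius_px = 1L, min_component_px = 25L,
                        k_sd = 3, extravascular_guard_px = 2L),
    readouts = list(filling_fraction = 80, lock_fraction = 0.05,
                    leakage_k_sd = 2, persistence = 2L,
                    baseline_start = 0),
    stats = list(alpha = 0.05))
  if (scenario == "EP" && variant == "dv_foldchange") {
    n_tum <- cfg$scene$n_segments -
      round(cfg$scene$n_segments * cfg$scene$peritumoral_fraction)
    cfg$scene$diameters <- c(rep_len(c(40, 12), n_tum),
                             rep(20, cfg$scene$n_segments - n_tum))
    cfg$scene$calibrate_dv <- FALSE
    cfg$scenario$reperfuse_rule <- "largest"
    cfg$scenario$reperfused_fraction <- sum(cfg$scene$diameters == 40) /
      cfg$scene$n_segments
  }
  class(cfg) <- c("ivtrace_config", "list")
  cfg
}

#' Read / write a pipeline configuration
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return `read_config` returns an `ivtrace_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file '", path, "'")
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$scenario$name))
    stop("config error: missing scenario name (scenario$name)")
  if (!cfg$scenario$name %in% c("control", "bleomycin", "EP", "ECT"))
    stop("config error: unknown scenario '", cfg$scenario$name, "'")
  base <- default_config(cfg$scenario$name)
  for (sec in names(cfg)) {
    if (!sec %in% names(base)) stop("config error: unknown section '", sec, "'")
    for (key in names(cfg[[sec]])) base[[sec]][[key]] <- cfg[[sec]][[key]]
  }
  if (is.null(base$scenario$name) ||
      !base$scenario$name %in% c("control", "bleomycin", "EP", "ECT"))
    stop("config error: scenario name must be one of control/bleomycin/EP/ECT")
  if (!is.null(base$schedule$series) && is.list(base$schedule$series))
    base$schedule$series <- lapply(base$schedule$series, as.numeric)
  base
}

#' @rdname read_config
#' @param config an `ivtrace_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  # provenance fingerprint: stable serialization of the parameter list
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 251 + 1)) %% .Machine$integer.max)
}

scene_from_config <- function(config, seed = NULL) {
  sc <- config$scene
  if (!is.null(seed)) sc$seed <- seed
  spec <- vessel_network_spec(
    field_height_px = sc$field_height_px, field_width_px = sc$field_width_px,
    pixel_size = sc$pixel_size, n_segments = sc$n_segments,
    peritumoral_fraction = sc$peritumoral_fraction,
    diameter_mean = sc$diameter_mean, diameter_sd = sc$diameter_sd,
    diameters = sc$diameters, calibrate_dv = isTRUE(sc$calibrate_dv),
    tortuosity = sc$tortuosity, seed = sc$seed)
  net_d <- build_network(spec)$truth$segment_diameter_um
  so <- config$scenario
  scenario <- perfusion_scenario(
    so$name, n_segments = spec$n_segments,
    treatment_time = so$treatment_time, lock_duration = so$lock_duration,
    reperfused_fraction = so$reperfused_fraction, stagger = so$stagger,
    reperfuse_rule = so$reperfuse_rule, diameters = net_d,
    early_reperfusion_fraction = so$early_reperfusion_fraction,
    early_reperfusion_delay = so$early_reperfusion_delay,
    perfused_fraction_late = so$perfused_fraction_late, seed = spec$seed)
  ki <- config$kinetics
  kinetics <- tracer_kinetics(t0 = ki$t0, tau = ki$tau, A = ki$A,
                              k_perm = ki$k_perm,
                              leakage_onset_delay = ki$leakage_onset_delay)
  schedule <- acquisition_schedule(config$schedule$series)
  no <- config$noise
  noise <- noise_model(read_noise_sd = no$read_noise_sd,
                       photon_scale = no$photon_scale,
                       drift_per_frame = no$drift_per_frame,
                       background_level = no$background_level,
                       texture_sd = no$texture_sd,
                       texture_scale_px = no$texture_scale_px,
                       bleach_rate = no$bleach_rate,
                       seed = spec$seed)
  list(spec = spec, scenario = scenario, kinetics = kinetics,
       schedule = schedule, noise = noise)
}

#' Simulate a scene from a configuration and write it to disk
#'
#' Writes the 16-bit TIFF stack with its JSON sidecar, the ground truth as
#' JSON, and a run log recording the seed and a configuration fingerprint.
#'
#' @param config an `ivtrace_config` (or path to one).
#' @param seed integer seed controlling network, scenario draws and noise.
#' @param out_dir output directory (created if needed).
#' @param noise_off render without stochastic noise.
#' @return the simulated `scene`, invisibly.
#' @export
simulate_run <- function(config = default_config(), seed = 1L, out_dir,
                         noise_off = FALSE) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  parts <- scene_from_config(config, seed = seed)
  scene <- simulate_stack(parts$spec, parts$scenario, parts$kinetics,
                          parts$schedule, parts$noise, seed = seed,
                          noise_off = noise_off)
  write_stack(scene$stack, file.path(out_dir, "stack.tif"))
  tr <- scene$truth
  tr$roi_mask <- NULL; tr$vessel_mask_true <- NULL; tr$segment_idx <- NULL
  tr$drift_px <- apply(scene$truth$drift_px, 1L, paste, collapse = ",")
  jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(c(sprintf("seed: %d", seed),
               sprintf("scenario: %s", parts$scenario$scenario),
               sprintf("config_hash: %s", config_hash(config))),
             file.path(out_dir, "simulate.log"))
  invisible(scene)
}

boundary_of <- function(mask) {
  er <- EBImage::erode(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                       EBImage::makeBrush(3L, "box")) > 0
  mask & !er
}

write_overlay <- function(reference, vessel_mask, tumor_roi, path) {
  g <- reference / max(reference)
  rgb <- array(rep(g, 3L), dim = c(dim(g), 3L))
  vb <- boundary_of(vessel_mask); rb <- boundary_of(tumor_roi)
  r <- rgb[, , 1L]; gg <- rgb[, , 2L]; b <- rgb[, , 3L]
  r[vb] <- 1; gg[vb] <- 0; b[vb] <- 0       # vessel outline: red
  r[rb] <- 1; gg[rb] <- 1; b[rb] <- 0       # ROI outline: yellow
  rgb[, , 1L] <- r; rgb[, , 2L] <- gg; rgb[, , 3L] <- b
  png::writePNG(rgb, path)
  invisible(path)
}

#' Analyze a window-chamber stack
#'
#' Runs the full analysis: translation alignment, maximum-intensity
#' reference projection, vessel segmentation (with optional hand-correction
#' masks), compartment masks, per-timepoint perfusion calls and
#' morphometry, Imax-normalized compartment curves, and the physiological
#' readouts (filling time, vascular-lock duration, leakage onset). Writes
#' CSV curve tables, a JSON report echoing every parameter, per-frame
#' shifts, and a QC overlay image.
#'
#' @param stack an [image_stack] or path to one (see [read_stack]).
#' @param config an `ivtrace_config` (or path).
#' @param out_dir output directory; `NULL` skips writing files.
#' @param add_mask,remove_mask optional correction masks (logical matrices
#'   or mask file paths).
#' @param tumor_roi optional ROI (logical matrix or mask file path);
#'   default: the polygon implied by the `scene` section of `config`.
#' @return list with `morphometry`, `curves` (intravascular /
#'   extravascular), `readouts`, `shifts`, `vessel_mask`, `tumor_roi`,
#'   `report`.
#' @export
analyze_run <- function(stack, config = default_config(), out_dir = NULL,
                        add_mask = NULL, remove_mask = NULL,
                        tumor_roi = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(add_mask)) add_mask <- read_mask(add_mask)
  if (is.character(remove_mask)) remove_mask <- read_mask(remove_mask)
  if (is.character(tumor_roi)) tumor_roi <- read_mask(tumor_roi)

  al <- align_stack(stack)
  aligned <- al$stack
  ref <- reference_projection(aligned)
  seg <- config$segmentation
  vessel <- segment_vessels(ref, opening_radius_px = seg$opening_radius_px,
                            min_component_px = seg$min_component_px)
  vessel <- apply_corrections(vessel, add_mask, remove_mask)
  if (is.null(tumor_roi)) {
    spec <- scene_from_config(config)$spec
    if (!identical(dim(vessel), c(spec$field_height_px, spec$field_width_px)))
      stop("stack shape does not match the configured scene; pass tumor_roi explicitly")
    tumor_roi <- polygon_mask(spec$tumor_roi, spec$field_height_px,
                              spec$field_width_px)
  }
  # guard zone: the automatic mask sits slightly inside the true vessel
  # boundary, so the extravascular curve excludes a small dilated margin
  # around the vessels (partial-volume pixels carry intravascular signal)
  guard <- seg$extravascular_guard_px
  vessel_guarded <- if (!is.null(guard) && guard > 0) {
    EBImage::dilate(matrix(as.numeric(vessel), nrow(vessel), ncol(vessel)),
                    EBImage::makeBrush(2L * as.integer(guard) + 1L, "disc")) > 0
  } else vessel
  ev <- extravascular_mask(vessel_guarded, tumor_roi)

  t0 <- if (!is.null(stack$meta$injection_time)) stack$meta$injection_time
  else config$kinetics$t0
  treatment <- if (!is.null(stack$meta$treatment_time)) stack$meta$treatment_time
  else config$scenario$treatment_time
  # background from the earliest tracer-free frame (pre-injection if present)
  bg_frame <- if (any(aligned$timestamps <= t0))
    max(which(aligned$timestamps <= t0)) else 1L
  bg <- background_stats(aligned, vessel, tumor_roi, frame = bg_frame)

  morph <- morphometry_series(aligned, vessel, tumor_roi,
                              k_sd = seg$k_sd, background = bg)
  iv <- normalize_to_imax(compartment_means(aligned, vessel, "intravascular"))
  evc <- compartment_means(aligned, ev, "extravascular")

  rd <- config$readouts
  baseline_win <- which(aligned$timestamps >= t0 + rd$baseline_start &
                          aligned$timestamps < treatment)
  if (length(baseline_win) < 2L)
    baseline_win <- which(aligned$timestamps < treatment)
  evc <- relative_variation(evc, baseline_win)

  baseline_fvd <- mean(morph$FVD_per_um[baseline_win])
  lock <- if (baseline_fvd > 0)
    lock_duration(morph$time_s, morph$FVD_per_um, baseline_fvd,
                  f = rd$lock_fraction, treatment_time = treatment)
  else list(duration_s = NA_real_, censored = NA)
  onset <- leakage_onset(evc, baseline_win, treatment,
                         k_sd = rd$leakage_k_sd, persistence = rd$persistence)
  readouts <- list(
    # filling time is reported relative to injection, not acquisition start
    filling_time_s = filling_time(iv, rd$filling_fraction) - t0,
    filling_fraction = rd$filling_fraction,
    baseline_FVD_per_um = baseline_fvd,
    lock_duration_s = lock$duration_s,
    lock_censored = lock$censored,
    leakage_onset_s = onset,
    Imax = attr(iv, "Imax"))

  report <- list(parameters = unclass(config), config_hash = config_hash(config),
                 injection_time = t0, treatment_time = treatment,
                 background = as.list(bg), readouts = readouts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_curves(morph, file.path(out_dir, "morphometry.csv"))
    curves <- data.frame(time_s = iv$time_s,
                         intravascular_mean = iv$mean_intensity,
                         intravascular_pct_imax = iv$normalized_pct,
                         extravascular_mean = evc$mean_intensity,
                         extravascular_relative = evc$relative_variation)
    write_curves(curves, file.path(out_dir, "curves.csv"))
    utils::write.csv(data.frame(frame = seq_len(nrow(al$shifts)),
                                dy = al$shifts[, 1L], dx = al$shifts[, 2L]),
                     file.path(out_dir, "shifts.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_overlay(ref, vessel, tumor_roi, file.path(out_dir, "overlay.png"))
  }
  invisible(list(morphometry = morph,
                 curves = list(intravascular = iv, extravascular = evc),
                 readouts = readouts, shifts = al$shifts,
                 vessel_mask = vessel, tumor_roi = tumor_roi,
                 reference = ref, report = report))
}

#' Compare analyzed runs between experimental groups
#'
#' Gathers a metric from the `morphometry.csv` of each analyzed run and
#' compares the groups with [group_compare], either per timepoint (the
#' default, mirroring the per-timepoint group testing of the study) or on
#' per-run summaries over a time window.
#'
#' @param groups named list; each element is a character vector of analyze
#'   output directories belonging to one group (>= 2 groups).
#' @param metric morphometry column to compare (default `"FVD_per_um"`).
#' @param mode `"per_timepoint"` or `"summary"`.
#' @param time_window numeric `c(from, to)` in seconds for `"summary"`
#'   mode; default all post-treatment timepoints.
#' @param treatment_time used for the default window.
#' @param alpha significance level.
#' @return For `"summary"`: a `group_comparison`. For `"per_timepoint"`:
#'   data.frame with one row per timepoint (global p and minimum adjusted
#'   pairwise p).
#' @export
compare_runs <- function(groups, metric = "FVD_per_um",
                         mode = c("per_timepoint", "summary"),
                         time_window = NULL, treatment_time = 130,
                         alpha = 0.05) {
  mode <- match.arg(mode)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need >= 2 groups of analyze output directories")
  tables <- lapply(groups, function(dirs)
    lapply(dirs, function(d) read_curves(file.path(d, "morphometry.csv"))))
  timebases <- unique(unlist(lapply(tables, function(g)
    vapply(g, function(tb) paste(tb$time_s, collapse = ","), ""))))
  if (mode == "per_timepoint" && length(timebases) != 1L)
    stop("mismatched timebases across runs; re-analyze on a common schedule ",
         "or use mode = 'summary'")
  if (mode == "summary") {
    if (is.null(time_window)) time_window <- c(treatment_time, Inf)
    vals <- lapply(tables, function(g) vapply(g, function(tb) {
      sel <- tb$time_s >= time_window[1L] & tb$time_s <= time_window[2L]
      mean(tb[[metric]][sel], na.rm = TRUE)
    }, 0))
    return(group_compare(vals, alpha = alpha))
  }
  times <- tables[[1L]][[1L]]$time_s
  rows <- lapply(seq_along(times), function(i) {
    vals <- lapply(tables, function(g)
      vapply(g, function(tb) tb[[metric]][i], 0))
    ok <- all(vapply(vals, function(v) sum(is.finite(v)) >= 2L, TRUE))
    if (!ok) return(data.frame(time_s = times[i], p_value = NA_real_,
                               min_p_adjusted = NA_real_, any_reject = NA))
    vals <- lapply(vals, function(v) v[is.finite(v)])
    gc <- group_compare(vals, alpha = alpha)
    data.frame(time_s = times[i], p_value = gc$p_value,
               min_p_adjusted = min(gc$pairwise$p_adjusted),
               any_reject = any(gc$pairwise$reject))
  })
  do.call(rbind, rows)
}
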