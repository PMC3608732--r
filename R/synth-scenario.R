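#' Acquisition schedule
#'
#' A list of frame series, each `(start, interval, duration)` in seconds.
#' The default reproduces the intravital protocol: two 2-minute series at
#' 20-second intervals separated by a 20-second pause (during which the
#' treatment is delivered), then a 58-minute series at 2-minute intervals.
#'
#' @param series a list of numeric vectors `c(start, interval, duration)`.
#' @return An object of class `acquisition_schedule`.
#' @export
acquisition_schedule <- function(series = list(c(0, 20, 120),
                                               c(140, 20, 120),
                                               c(380, 120, 3360))) {
  ts <- schedule_times_impl(series)
  if (length(ts) > 1L && any(diff(ts) <= 0))
    stop("schedule timestamps must be strictly increasing")
  structure(list(series = series), class = "acquisition_schedule")
}

schedule_times_impl <- function(series) {
  unlist(lapply(series, function(s) seq(s[1L], s[1L] + s[3L], by = s[2L])))
}

#' @rdname acquisition_schedule
#' @param schedule an `acquisition_schedule`.
#' @return `schedule_times` returns the vector of frame timestamps (s).
#' @export
schedule_times <- function(schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  schedule_times_impl(schedule$series)
}

#' Perfusion scenario
#'
#' Per-segment binary perfusion timeline for the four experimental arms.
#' Control and bleomycin leave all segments perfused throughout. EP locks
#' every segment at `lock_start` for `lock_duration` seconds, then
#' reperfuses a fraction of segments at staggered times (the first exactly
#' at the end of the complete lock); the remainder stay locked. ECT locks
#' every segment permanently except for `perfused_fraction_late` of them.
#'
#' @param scenario one of `"control"`, `"bleomycin"`, `"EP"`, `"ECT"`.
#' @param n_segments number of vessel segments in the scene.
#' @param treatment_time treatment delivery time (s); default 130 s, the
#'   middle of the pause between the first two acquisition series.
#' @param lock_start lock onset (s); must be >= `treatment_time`; defaults
#'   to `treatment_time` (the lock is immediate).
#' @param lock_duration complete-lock duration for EP (s); default 600.
#' @param reperfused_fraction fraction of segments that reperfuse after the
#'   EP lock (staggered every `stagger` s).
#' @param stagger spacing between successive EP reperfusion times (s).
#' @param reperfuse_rule `"random"` picks the reperfusing segments at
#'   random; `"largest"` picks the largest-diameter segments (requires
#'   `diameters`).
#' @param diameters per-segment diameters (um), needed for
#'   `reperfuse_rule = "largest"`.
#' @param early_reperfusion_fraction fraction of segments that reperfuse
#'   already `early_reperfusion_delay` s after treatment (EP only) - the
#'   rapidly recovering vessels from which post-EP leakage originates.
#' @param early_reperfusion_delay delay of early reperfusion (s).
#' @param perfused_fraction_late fraction of segments reperfused late under
#'   ECT (default 0: permanent complete lock).
#' @param late_reperfusion_delay delay of the late ECT reperfusion (s).
#' @param seed RNG seed for the random segment draws.
#' @return An object of class `perfusion_scenario` with a per-segment
#'   `reperfusion_time` (`Inf` = never) and `lock_start`.
#' @export
perfusion_scenario <- function(scenario = c("control", "bleomycin", "EP", "ECT"),
                               n_segments, treatment_time = 130,
                               lock_start = treatment_time,
                               lock_duration = 600,
                               reperfused_fraction = 0.5, stagger = 100,
                               reperfuse_rule = c("random", "largest"),
                               diameters = NULL,
                               early_reperfusion_fraction = 0,
                               early_reperfusion_delay = 60,
                               perfused_fraction_late = 0,
                               late_reperfusion_delay = 3600,
                               seed = 1L) {
  scenario <- match.arg(scenario)
  reperfuse_rule <- match.arg(reperfuse_rule)
  if (lock_start < treatment_time)
    stop("lock_start must be >= treatment_time")
  rep_t <- rep(Inf, n_segments)
  locked <- scenario %in% c("EP", "ECT")
  if (scenario == "EP") {
    n_rep <- round(reperfused_fraction * n_segments)
    idx <- if (n_rep == 0) integer(0)
    else if (reperfuse_rule == "largest") {
      if (is.null(diameters)) stop("reperfuse_rule = 'largest' needs diameters")
      order(diameters, decreasing = TRUE)[seq_len(n_rep)]
    } else {
      set.seed(seed); sample(n_segments, n_rep)
    }
    if (length(idx))
      rep_t[idx] <- lock_start + lock_duration + stagger * (seq_along(idx) - 1L)
    n_early <- round(early_reperfusion_fraction * n_segments)
    if (n_early > 0) {
      set.seed(seed + 7L)
      early <- sample(n_segments, n_early)
      rep_t[early] <- pmin(rep_t[early], treatment_time + early_reperfusion_delay)
    }
  } else if (scenario == "ECT") {
    n_late <- round(perfused_fraction_late * n_segments)
    if (n_late > 0) {
      set.seed(seed)
      rep_t[sample(n_segments, n_late)] <- treatment_time + late_reperfusion_delay
    }
  }
  if (any(rep_t < lock_start))
    stop("reperfusion_time must be >= lock_start for every segment")
  structure(
    list(scenario = scenario, treatment_time = treatment_time,
         lock_start = if (locked) lock_start else Inf,
         reperfusion_time = rep_t,
         perfused_fraction_late = perfused_fraction_late),
    class = "perfusion_scenario")
}

#' Per-segment perfusion state at a time
#'
#' @param scenario a [perfusion_scenario].
#' @param t time (s), scalar.
#' @return logical vector, one element per segment.
#' @export
perfused_at <- function(scenario, t) {
  stopifnot(inherits(scenario, "perfusion_scenario"))
  t < scenario$lock_start | t >= scenario$reperfusion_time
}

#' Acquisition noise and drift model
#'
#' @param read_noise_sd Gaussian read-noise SD (intensity units).
#' @param photon_scale shot-noise scaling: the photon-noise SD at intensity
#'   `I` is `sqrt(photon_scale * I)`.
#' @param drift_per_frame length-2 numeric, mean stage drift per frame in
#'   pixels `(dy, dx)`; injected as the rounded cumulative sum, i.e. an
#'   integer-pixel translation per frame.
#' @param background_level constant tissue background offset (intensity).
#' @param texture_sd SD of the static autofluorescence texture added to the
#'   background (0 = flat background).
#' @param texture_scale_px correlation length of the texture (px).
#' @param bleach_rate photobleaching rate (1/s); the whole rendered signal
#'   decays as `exp(-bleach_rate * t)`. Default 0.
#' @param seed RNG seed for noise and texture.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(read_noise_sd = 4, photon_scale = 0.5,
                        drift_per_frame = c(0, 0), background_level = 100,
                        texture_sd = 12, texture_scale_px = 12,
                        bleach_rate = 0, seed = 1L) {
  if (read_noise_sd < 0 || photon_scale < 0 || texture_sd < 0 ||
      bleach_rate < 0 || background_level < 0)
    stop("noise model parameters must be nonnegative")
  structure(list(read_noise_sd = read_noise_sd, photon_scale = photon_scale,
                 drift_per_frame = rep_len(drift_per_frame, 2L),
                 background_level = background_level, texture_sd = texture_sd,
                 texture_scale_px = texture_scale_px,
                 bleach_rate = bleach_rate, seed = as.integer(seed)),
            class = "noise_model")
}
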