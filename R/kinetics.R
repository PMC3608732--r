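#' Compartment mean-intensity time course
#'
#' Arithmetic mean of the frame intensities over the mask pixels, per frame.
#'
#' @param stack an aligned [image_stack].
#' @param mask logical compartment mask (nonempty).
#' @param compartment label stored in the result (e.g. "intravascular").
#' @return An object of class `compartment_curve`: a data.frame with
#'   columns `time_s`, `mean_intensity` and attributes `compartment`,
#'   `Imax` (filled by [normalize_to_imax]).
#' @export
compartment_means <- function(stack, mask, compartment = "intravascular") {
  stopifnot(inherits(stack, "image_stack"))
  if (!any(mask)) stop("empty compartment mask")
  if (!identical(dim(mask), dim(stack$frames)[1:2]))
    stop("mask shape does not match the stack frames")
  idx <- which(mask)
  vals <- vapply(seq_len(n_frames(stack)),
                 function(i) mean(stack$frames[, , i][idx]), 0)
  out <- data.frame(time_s = stack$timestamps, mean_intensity = vals)
  attr(out, "compartment") <- compartment
  class(out) <- c("compartment_curve", "data.frame")
  out
}

#' Normalize a curve to its maximum (Imax)
#'
#' Expresses the mean fluorescence intensity as a percentage of the maximum
#' mean intensity (Imax) reached over the observation period; the peak of
#' the normalized series is exactly 100.
#'
#' @param curve a `compartment_curve` (or data.frame with `time_s`,
#'   `mean_intensity`).
#' @return the curve with columns `normalized_pct` and attribute `Imax`
#'   added. Idempotent: normalizing twice equals normalizing once.
#' @export
normalize_to_imax <- function(curve) {
  imax <- max(curve$mean_intensity)
  if (imax <= 0) stop("cannot normalize: maximum intensity is not positive")
  curve$normalized_pct <- 100 * curve$mean_intensity / imax
  attr(curve, "Imax") <- imax
  curve
}

#' Relative variation of a curve against a baseline window
#'
#' `(value - baseline mean) / baseline mean` per timepoint. The baseline
#' window should cover the frames between the end of tracer filling and the
#' treatment (when the vessels are ~80% filled and the extravascular signal
#' is still flat).
#'
#' @param curve a `compartment_curve`.
#' @param baseline_window logical or integer index into the curve rows.
#' @return the curve with column `relative_variation` added and attribute
#'   `baseline_mean` set.
#' @export
relative_variation <- function(curve, baseline_window) {
  base <- curve$mean_intensity[baseline_window]
  if (length(base) == 0L) stop("empty baseline window")
  bm <- mean(base)
  if (bm <= 0) stop("baseline mean must be positive")
  curve$relative_variation <- (curve$mean_intensity - bm) / bm
  attr(curve, "baseline_mean") <- bm
  curve
}

#' Time to reach a fraction of Imax
#'
#' Earliest time at which the Imax-normalized curve reaches `fraction`
#' percent, linearly interpolated between the bracketing frames.
#'
#' @param curve a normalized curve (see [normalize_to_imax]).
#' @param fraction target level in percent, in (0, 100].
#' @return time in seconds, or `NA` if never reached.
#' @export
filling_time <- function(curve, fraction = 80) {
  if (fraction <= 0 || fraction > 100)
    stop("fraction must be in (0, 100]")
  y <- curve$normalized_pct
  if (is.null(y)) stop("curve is not normalized; call normalize_to_imax()")
  t <- curve$time_s
  hit <- which(y >= fraction)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1L]
  if (i == 1L || y[i] == fraction) return(t[i])
  t[i - 1L] + (fraction - y[i - 1L]) * (t[i] - t[i - 1L]) / (y[i] - y[i - 1L])
}

#' Vascular-lock duration from an FVD time series
#'
#' Length of the maximal contiguous run, starting at the treatment time,
#' with `FVD <= f * baseline`. If the FVD recovers within the series, the
#' endpoint is linearly interpolated to the threshold crossing between the
#' last sub-threshold and first supra-threshold frames; if it never
#' recovers, the duration is the remaining observation span and the result
#' is flagged censored.
#'
#' @param times frame times (s).
#' @param fvd FVD values (um^-1), same length.
#' @param baseline_fvd pre-treatment baseline FVD (> 0).
#' @param f lock threshold as a fraction of baseline (default 0.05).
#' @param treatment_time treatment delivery time (s); must lie within the
#'   series span.
#' @return list with `duration_s` and logical `censored`.
#' @export
lock_duration <- function(times, fvd, baseline_fvd, f = 0.05,
                          treatment_time) {
  if (baseline_fvd <= 0) stop("baseline FVD must be positive")
  if (treatment_time < min(times) || treatment_time > max(times))
    stop("treatment time outside the series")
  thr <- f * baseline_fvd
  post <- which(times >= treatment_time)
  if (length(post) == 0L || fvd[post[1L]] > thr)
    return(list(duration_s = 0, censored = FALSE))
  above <- which(fvd > thr & times >= treatment_time)
  if (length(above) == 0L)
    return(list(duration_s = max(times) - treatment_time, censored = TRUE))
  i <- above[1L]
  t_cross <- if (i == post[1L]) times[i] else {
    j <- i - 1L
    times[j] + (thr - fvd[j]) * (times[i] - times[j]) / (fvd[i] - fvd[j])
  }
  list(duration_s = t_cross - treatment_time, censored = FALSE)
}

#' Leakage onset from an extravascular relative-variation series
#'
#' First timestamp at which the relative-variation series exceeds
#' `baseline mean + k_sd * baseline SD` for `persistence` consecutive
#' frames (a persistence filter against single-frame noise spikes),
#' reported relative to the treatment time.
#'
#' @param curve a curve with a `relative_variation` column.
#' @param baseline_window index into the curve rows; must precede the
#'   treatment and contain >= 2 frames.
#' @param treatment_time treatment delivery time (s).
#' @param k_sd threshold in baseline SDs (default 2).
#' @param persistence required consecutive supra-threshold frames
#'   (default 2).
#' @return onset time in seconds after treatment, or `NA` if no qualifying
#'   run exists.
#' @export
leakage_onset <- function(curve, baseline_window, treatment_time,
                          k_sd = 2, persistence = 2L) {
  rv <- curve$relative_variation
  if (is.null(rv)) stop("curve lacks a relative_variation column")
  t <- curve$time_s
  if (is.logical(baseline_window)) baseline_window <- which(baseline_window)
  baseline_window <- baseline_window[baseline_window >= 1L &
                                       baseline_window <= length(t)]
  base <- rv[baseline_window]
  if (length(base) < 2L) stop("baseline window must contain >= 2 frames")
  if (max(t[baseline_window]) >= treatment_time)
    stop("baseline window must precede the treatment")
  thr <- mean(base) + k_sd * stats::sd(base)
  over <- rv > thr & t >= treatment_time
  run <- rle(over)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & run$lengths >= persistence)
  if (length(ok) == 0L) return(NA_real_)
  t[starts[ok[1L]]] - treatment_time
}
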