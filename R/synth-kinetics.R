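#' Tracer kinetics parameters
#'
#' Phenomenological single-compartment model of dextran tracer dynamics: a
#' mono-exponential plasma filling curve and a one-way, gated leakage flux
#' into the extravascular tissue.
#'
#' The default filling time constant is `tau = 120 / log(5)` s, so the
#' plasma curve reaches exactly 80% of its plateau 2 minutes after
#' injection. `leakage_onset_delay` is measured from the injection time
#' `t0`; before it elapses (and whenever no supplying vessel is perfused)
#' the permeability is forced to zero.
#'
#' The default injection time is `t0 = -10` s: the first acquired frame
#' (t = 0) follows the injection by about 10 seconds, so tracer is already
#' faintly visible in it (and the acquisition series can be registered to
#' that first frame).
#'
#' @param t0 injection time (s).
#' @param tau filling time constant (s), > 0.
#' @param A plateau intensity (arbitrary 16-bit units), > 0.
#' @param k_perm permeability rate constant (1/s), >= 0.
#' @param leakage_onset_delay delay from `t0` until leakage can begin (s).
#' @return An object of class `tracer_kinetics`.
#' @export
tracer_kinetics <- function(t0 = -10, tau = 120 / log(5), A = 20000,
                            k_perm = 0, leakage_onset_delay = 0) {
  if (tau <= 0) stop("tau must be > 0")
  if (A <= 0) stop("A must be > 0")
  if (k_perm < 0) stop("k_perm must be >= 0")
  if (leakage_onset_delay < 0) stop("leakage_onset_delay must be >= 0")
  structure(list(t0 = t0, tau = tau, A = A, k_perm = k_perm,
                 leakage_onset_delay = leakage_onset_delay),
            class = "tracer_kinetics")
}

#' Intravascular plasma concentration
#'
#' `0` before injection and `A * (1 - exp(-(t - t0)/tau))` afterwards;
#' monotone nondecreasing.
#'
#' @param t time(s) in seconds (vectorized).
#' @param kinetics a [tracer_kinetics].
#' @return concentration(s) in `[0, A]`.
#' @export
plasma_concentration <- function(t, kinetics) {
  stopifnot(inherits(kinetics, "tracer_kinetics"))
  ifelse(t < kinetics$t0, 0,
         kinetics$A * (1 - exp(-(t - kinetics$t0) / kinetics$tau)))
}

#' Extravascular tracer accumulation
#'
#' One-way gated accumulation `dC_ev/dt = k_perm * C_iv(t)`, integrated by
#' forward Euler on a fine internal grid (5 s substeps, so gate and delay
#' transitions between widely spaced late frames are resolved). The
#' permeability is forced to zero before `t0 + leakage_onset_delay` and
#' whenever `gate` is `FALSE` (no perfused vessel means no intravascular
#' tracer, hence no efflux). There is no backflux, so the result is
#' monotone nondecreasing.
#'
#' @param times strictly increasing sample times (s).
#' @param kinetics a [tracer_kinetics].
#' @param gate logical vector, one element per entry of `times` (recycled if
#'   length 1): whether a perfused supplying vessel is present over the
#'   interval starting at that time.
#' @param substep_s internal Euler step (s).
#' @return numeric vector of extravascular concentrations at `times`.
#' @export
extravascular_concentration <- function(times, kinetics, gate = TRUE,
                                        substep_s = 5) {
  stopifnot(inherits(kinetics, "tracer_kinetics"))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  gate <- rep_len(as.logical(gate), length(times))
  onset <- kinetics$t0 + kinetics$leakage_onset_delay
  C <- numeric(length(times))
  acc <- 0
  for (i in seq_len(length(times))) {
    if (i > 1L) {
      lo <- times[i - 1L]; hi <- times[i]
      grid <- unique(c(seq(lo, hi, by = substep_s), hi))
      dt <- diff(grid)
      tl <- grid[-length(grid)]
      k_eff <- ifelse(tl >= onset & gate[i - 1L], kinetics$k_perm, 0)
      acc <- acc + sum(k_eff * plasma_concentration(tl, kinetics) * dt)
    }
    C[i] <- acc
  }
  C
}
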