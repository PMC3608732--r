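#' Estimate the integer translation between two frames
#'
#' Finds the integer `(dy, dx)` maximizing the cross-correlation of the
#' mean-subtracted frames (computed in the Fourier domain), searched over
#' at least +/- 10% of the frame size. The returned shift satisfies
#' `moving ~ translate(reference, dy, dx)`.
#'
#' @param reference,moving numeric matrices of equal size.
#' @param max_shift maximum absolute shift searched (px); default 10% of
#'   the smaller frame dimension, at least 10 px.
#' @return integer vector `c(dy, dx)`.
#' @export
estimate_translation <- function(reference, moving, max_shift = NULL) {
  if (!identical(dim(reference), dim(moving)))
    stop("frames must have equal shapes")
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stop("degenerate input: constant (zero-variance) frame")
  h <- nrow(reference); w <- ncol(reference)
  if (is.null(max_shift)) max_shift <- max(10L, ceiling(0.1 * min(h, w)))
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  # cc[dy+1, dx+1] (circular) is the correlation at shift (dy, dx)
  dy_axis <- c(0:(h - 1L)); dy_axis[dy_axis > h / 2] <- dy_axis[dy_axis > h / 2] - h
  dx_axis <- c(0:(w - 1L)); dx_axis[dx_axis > w / 2] <- dx_axis[dx_axis > w / 2] - w
  ok_y <- abs(dy_axis) <= max_shift
  ok_x <- abs(dx_axis) <= max_shift
  sub <- cc[ok_y, ok_x, drop = FALSE]
  best <- arrayInd(which.max(sub), dim(sub))
  c(dy = dy_axis[ok_y][best[1L]], dx = dx_axis[ok_x][best[2L]])
}

#' Align a time-lapse stack by translation
#'
#' Registers every frame to the first frame (the pre-treatment baseline),
#' filling out-of-field pixels with the frame's background median, and
#' reports the per-frame shifts for audit.
#'
#' @param stack an [image_stack].
#' @param max_shift passed to [estimate_translation].
#' @return A list with `stack` (the aligned [image_stack]) and `shifts`
#'   (a `T x 2` integer matrix of the estimated `(dy, dx)` per frame).
#' @export
align_stack <- function(stack, max_shift = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  T <- n_frames(stack)
  shifts <- matrix(0L, T, 2L, dimnames = list(NULL, c("dy", "dx")))
  if (T == 1L) return(list(stack = stack, shifts = shifts))
  ref <- stack$frames[, , 1L]
  aligned <- stack$frames
  for (i in 2:T) {
    sh <- tryCatch(estimate_translation(ref, stack$frames[, , i], max_shift),
                   error = function(e)
                     stop("frame ", i, ": ", conditionMessage(e)))
    shifts[i, ] <- sh
    if (any(sh != 0L)) {
      fr <- stack$frames[, , i]
      aligned[, , i] <- translate_int(fr, -sh[1L], -sh[2L], stats::median(fr))
    }
  }
  out <- image_stack(aligned, stack$timestamps, stack$pixel_size, stack$meta)
  list(stack = out, shifts = shifts)
}
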