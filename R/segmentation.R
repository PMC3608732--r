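#' Maximum-intensity reference projection
#'
#' Per-pixel maximum over a window of frames, capturing every vessel that
#' carried tracer at any covered time. The vessel mask is segmented on this
#' projection and then reused for all timepoints.
#'
#' @param stack an (aligned) [image_stack].
#' @param window integer frame indices; default all frames.
#' @return numeric matrix, the projection.
#' @export
reference_projection <- function(stack, window = seq_len(n_frames(stack))) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(window) == 0L) stop("empty projection window")
  if (any(window < 1L | window > n_frames(stack)))
    stop("projection window outside the stack")
  apply(stack$frames[, , window, drop = FALSE], c(1L, 2L), max)
}

# 8-connected labeling: EBImage::bwlabel (4-connected) plus a union-find
# merge of diagonally touching labels.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  h <- nrow(lab); w <- ncol(lab)
  a <- lab[-h, -w]; b <- lab[-1, -1]            # NW-SE diagonal pairs
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) for (k in which(sel)) union(a[k], b[k])
  a <- lab[-1, -w]; b <- lab[-h, -1]            # SW-NE diagonal pairs
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) for (k in which(sel)) union(a[k], b[k])
  roots <- vapply(seq_len(n), find, 1L)
  relab <- match(roots, unique(roots))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Segment the vessel network from a reference projection
#'
#' Global Otsu threshold (the threshold maximizing between-class variance of
#' the intensity histogram), morphological opening with a disk, then removal
#' of small 8-connected components.
#'
#' @param reference numeric matrix (e.g. from [reference_projection]).
#' @param opening_radius_px disk radius of the morphological opening.
#' @param min_component_px minimum component size kept (px).
#' @param threshold optional explicit global threshold; default Otsu.
#' @return logical vessel mask.
#' @export
segment_vessels <- function(reference, opening_radius_px = 1L,
                            min_component_px = 25L, threshold = NULL) {
  if (stats::sd(reference) == 0)
    stop("degenerate input: constant reference image")
  if (is.null(threshold)) {
    img <- EBImage::Image(reference / 65535)
    threshold <- EBImage::otsu(img, range = c(0, 1), levels = 65536) * 65535
  }
  mask <- reference > threshold
  if (opening_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * opening_radius_px + 1L, "disc")
    mask <- EBImage::opening(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                             brush) > 0
  }
  mask <- matrix(as.logical(mask), nrow(reference), ncol(reference))
  if (min_component_px > 0 && any(mask)) {
    lab <- label8(mask)
    sz <- tabulate(lab[lab > 0L])
    keep <- which(sz >= min_component_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Apply hand-drawn mask corrections
#'
#' Mirrors the workflow step where the automatic mask is corrected in an
#' external editor: `(mask | add) & !remove`. Add and remove masks must be
#' disjoint.
#'
#' @param mask,add_mask,remove_mask logical matrices of equal shape;
#'   `add_mask`/`remove_mask` may be `NULL`.
#' @return corrected logical mask.
#' @export
apply_corrections <- function(mask, add_mask = NULL, remove_mask = NULL) {
  if (is.null(add_mask)) add_mask <- matrix(FALSE, nrow(mask), ncol(mask))
  if (is.null(remove_mask)) remove_mask <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!identical(dim(mask), dim(add_mask)) ||
      !identical(dim(mask), dim(remove_mask)))
    stop("mask, add_mask and remove_mask must share the same shape")
  if (any(add_mask & remove_mask))
    stop("conflict: add and remove masks overlap")
  (mask | add_mask) & !remove_mask
}

#' Extravascular compartment mask
#'
#' The tumor tissue outside the vessels: `tumor_roi & !vessel`. Together
#' with `tumor_roi & vessel` it partitions the ROI.
#'
#' @param vessel_mask,tumor_roi logical matrices of equal shape.
#' @return logical extravascular mask.
#' @export
extravascular_mask <- function(vessel_mask, tumor_roi) {
  if (!identical(dim(vessel_mask), dim(tumor_roi)))
    stop("vessel mask and ROI must share the same shape")
  tumor_roi & !vessel_mask
}

#' Background intensity statistics for perfusion calls
#'
#' Mean and SD of the extravascular pixels of a tracer-free frame
#' (a pre-injection frame, or the earliest frame when the extravascular
#' tissue is still tracer-free).
#'
#' @param stack an aligned [image_stack].
#' @param vessel_mask logical vessel mask.
#' @param tumor_roi logical ROI mask.
#' @param frame index of the background frame (default 1).
#' @return named numeric `c(mean, sd)`.
#' @export
background_stats <- function(stack, vessel_mask, tumor_roi, frame = 1L) {
  ev <- extravascular_mask(vessel_mask, tumor_roi)
  px <- stack$frames[, , frame][ev]
  if (length(px) < 2L) stop("too few extravascular pixels for background stats")
  c(mean = mean(px), sd = stats::sd(px))
}

#' Perfused-vessel mask at one timepoint
#'
#' A vessel component counts as perfused when tracer fluorescence is
#' detected in it: its median intensity at time `t` exceeds
#' `background mean + k_sd * background SD`. Components are kept or dropped
#' whole, so speckle noise cannot fragment vessels.
#'
#' @param stack an aligned [image_stack].
#' @param vessel_mask logical vessel mask (segmented + corrected).
#' @param t frame index.
#' @param k_sd detection threshold in background SDs (default 3).
#' @param background either `NULL` (use the extravascular pixels of a
#'   pre-injection frame; requires `injection_time` in `stack$meta` and a
#'   frame at or before it), a frame index, or explicit `c(mean, sd)`.
#' @param tumor_roi ROI mask, needed when background stats are derived from
#'   a frame.
#' @return logical perfused mask (a subset of `vessel_mask`).
#' @export
perfused_mask_at <- function(stack, vessel_mask, t, k_sd = 3,
                             background = NULL, tumor_roi = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (t < 1L || t > n_frames(stack)) stop("frame index out of range")
  if (is.null(background)) {
    t0 <- stack$meta$injection_time
    if (is.null(t0) || !any(stack$timestamps <= t0))
      stop("no pre-injection frame available; pass explicit background stats")
    background <- max(which(stack$timestamps <= t0))
  }
  if (length(background) == 1L) {
    if (is.null(tumor_roi))
      stop("tumor_roi is required to derive background stats from a frame")
    background <- background_stats(stack, vessel_mask, tumor_roi, background)
  }
  thr <- background[[1L]] + k_sd * background[[2L]]
  lab <- label8(vessel_mask)
  frame <- stack$frames[, , t]
  keep <- logical(max(lab))
  if (max(lab) > 0L) {
    med <- vapply(split(frame[lab > 0L], lab[lab > 0L]), stats::median, 0)
    keep[as.integer(names(med))] <- med > thr
  }
  out <- matrix(FALSE, nrow(vessel_mask), ncol(vessel_mask))
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}
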