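#' Specify a synthetic vessel network
#'
#' Describes the simulated window-chamber field: its size, the tumor region
#' of interest, and the statistics of the vessel segments laid into and
#' around it. Tumor segments are generated strictly inside the ROI and
#' peritumoral segments strictly outside it (with a clearance of one vessel
#' radius), so ROI-restricted morphometry ground truth is exact.
#'
#' @param field_height_px,field_width_px field size in pixels.
#' @param pixel_size um per pixel.
#' @param tumor_roi closed polygon, a 2-column matrix of (row, col) pixel
#'   coordinates (0-based, row-major convention; even-odd fill). Default: a
#'   centered octagon covering roughly a third of the field.
#' @param n_segments total number of vessel segments.
#' @param peritumoral_fraction fraction of segments placed outside the ROI.
#' @param diameter_mean,diameter_sd diameter distribution (um); samples are
#'   clipped to be resolvable (> 2 pixels).
#' @param diameters optional explicit per-segment diameters (um), recycled;
#'   overrides sampling and disables calibration.
#' @param calibrate_dv if `TRUE` (default), tumor-segment diameters are
#'   rescaled so their length-weighted mean equals `diameter_mean` exactly,
#'   pinning the ground-truth D_V of the scene.
#' @param tortuosity nonnegative angular jitter (radians SD per step) of the
#'   random-walk centerlines; 0 gives straight segments.
#' @param seed RNG seed; the same spec yields an identical network.
#' @return An object of class `vessel_network_spec`.
#' @export
vessel_network_spec <- function(field_height_px = 448L, field_width_px = 448L,
                                pixel_size = 1.5, tumor_roi = NULL,
                                n_segments = 9L, peritumoral_fraction = 1/3,
                                diameter_mean = 20, diameter_sd = 4,
                                diameters = NULL, calibrate_dv = TRUE,
                                tortuosity = 0.15, seed = 1L) {
  if (n_segments <= 0) stop("invalid spec: n_segments must be positive")
  if (field_height_px <= 0 || field_width_px <= 0)
    stop("invalid spec: field dimensions must be positive")
  if (diameter_mean <= 0) stop("invalid spec: diameter_mean must be positive")
  if (pixel_size <= 0) stop("invalid spec: pixel_size must be positive")
  if (tortuosity < 0) stop("invalid spec: tortuosity must be >= 0")
  if (is.null(tumor_roi)) {
    cy <- field_height_px / 2; cx <- field_width_px / 2
    r <- 0.38 * min(field_height_px, field_width_px)
    a <- seq(0, 2 * pi, length.out = 9L)[-9L] + pi / 8
    tumor_roi <- cbind(cy + r * sin(a), cx + r * cos(a))
  }
  tumor_roi <- as.matrix(tumor_roi)
  if (ncol(tumor_roi) != 2L || nrow(tumor_roi) < 3L)
    stop("invalid spec: tumor_roi must be a polygon with >= 3 (row, col) vertices")
  if (any(tumor_roi[, 1L] < 0 | tumor_roi[, 1L] > field_height_px - 1 |
          tumor_roi[, 2L] < 0 | tumor_roi[, 2L] > field_width_px - 1))
    stop("invalid spec: tumor_roi must lie inside the field")
  structure(
    list(field_height_px = as.integer(field_height_px),
         field_width_px = as.integer(field_width_px),
         pixel_size = pixel_size, tumor_roi = tumor_roi,
         n_segments = as.integer(n_segments),
         peritumoral_fraction = peritumoral_fraction,
         diameter_mean = diameter_mean, diameter_sd = diameter_sd,
         diameters = diameters, calibrate_dv = isTRUE(calibrate_dv),
         tortuosity = tortuosity, seed = as.integer(seed)),
    class = "vessel_network_spec")
}

# Even-odd (crossing number) polygon fill over the whole pixel grid.
# Vertices and pixel centers are 0-based (row, col).
polygon_mask <- function(poly, height, width) {
  ys <- matrix(rep(0:(height - 1L), width), height, width)
  xs <- matrix(rep(0:(width - 1L), each = height), height, width)
  inside <- matrix(FALSE, height, width)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1L]; xi <- poly[i, 2L]
    yj <- poly[j, 1L]; xj <- poly[j, 2L]
    crosses <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1L]; xi <- poly[i, 2L]
    yj <- poly[j, 1L]; xj <- poly[j, 2L]
    crosses <- ((yi > pts[, 1L]) != (yj > pts[, 1L])) &
      (pts[, 2L] < (xj - xi) * (pts[, 1L] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polyline_length_px <- function(centerline) {
  if (nrow(centerline) < 2L) return(0)
  sum(sqrt(rowSums(diff(centerline)^2)))
}

dist_to_polygon <- function(p, poly) {
  n <- nrow(poly)
  d2 <- Inf
  j <- n
  for (i in seq_len(n)) {
    a <- poly[j, ]; b <- poly[i, ]
    v <- b - a; L2 <- sum(v^2)
    tt <- if (L2 == 0) 0 else min(max(sum((p - a) * v) / L2, 0), 1)
    d2 <- min(d2, sum((p - a - tt * v)^2))
    j <- i
  }
  sqrt(d2)
}

# Random-walk centerline that stays within the field margin, on the
# required side of the ROI polygon ("in" for tumor, "out" for peritumoral)
# with one vessel radius of clearance from the ROI boundary, and clear of
# previously placed vessels (so rasterized vessels never touch - perfusion
# calls are made per connected component, which must map to one vessel).
walk_centerline <- function(spec, side, margin, obstacles, obstacle_sep,
                            step_px = 12, n_steps) {
  h <- spec$field_height_px; w <- spec$field_width_px
  ok_side <- function(p) {
    inr <- point_in_polygon(matrix(p, 1L), spec$tumor_roi)
    (if (side == "in") inr else !inr) &&
      dist_to_polygon(p, spec$tumor_roi) >= margin
  }
  clear_of_obstacles <- function(p) {
    is.null(obstacles) ||
      all(sqrt((obstacles[, 1L] - p[1L])^2 +
                 (obstacles[, 2L] - p[2L])^2) >= obstacle_sep)
  }
  ok <- function(p) {
    p[1L] >= margin && p[1L] <= h - 1 - margin &&
      p[2L] >= margin && p[2L] <= w - 1 - margin &&
      ok_side(p) && clear_of_obstacles(p)
  }
  p <- NULL
  for (i in 1:1000) {
    cand <- c(stats::runif(1, margin, h - 1 - margin),
              stats::runif(1, margin, w - 1 - margin))
    if (ok(cand)) { p <- cand; break }
  }
  if (is.null(p)) stop("could not place a vessel segment; the field is too ",
                       "crowded for the requested network")
  theta <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(p, 1L, 2L)
  for (s in seq_len(n_steps)) {
    placed <- FALSE
    for (try in 1:24) {
      cand_theta <- theta + stats::rnorm(1, 0, spec$tortuosity) +
        if (try > 1) stats::runif(1, -pi, pi) * (try / 24) else 0
      cand <- p + step_px * c(sin(cand_theta), cos(cand_theta))
      if (ok(cand)) { p <- cand; theta <- cand_theta; placed <- TRUE; break }
    }
    if (!placed) break
    pts <- rbind(pts, p)
  }
  pts
}

# Resample a polyline so consecutive points are at most `by` px apart
# (used for the obstacle cloud in the separation test).
densify_polyline <- function(pts, by = 4) {
  if (nrow(pts) < 2L) return(pts)
  out <- list(pts[1L, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    n <- max(1L, ceiling(sqrt(sum((b - a)^2)) / by))
    tt <- seq_len(n) / n
    out[[i + 1L]] <- cbind(a[1L] + tt * (b[1L] - a[1L]),
                           a[2L] + tt * (b[2L] - a[2L]))
  }
  do.call(rbind, out)
}

#' Generate a vessel network and its analytic ground truth
#'
#' Lays `n_segments` random-walk centerlines into the field, samples their
#' diameters, and computes the geometric ground truth analytically from the
#' polylines: per-segment length `l_i` (polyline length x pixel size), area
#' `l_i * d_i`, and the ROI-restricted totals `L_V`, `A_V`, `A_T`, with
#' `FVD = L_V / A_T` and the length-weighted diameter `D_V = A_V / L_V`.
#'
#' @param spec a [vessel_network_spec].
#' @return A list with `segments` (list of per-segment lists with
#'   `centerline` (pixel coords), `diameter` (um), `region_tag`) and `truth`
#'   (class `scene_truth`).
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "vessel_network_spec"))
  n_peri <- round(spec$n_segments * spec$peritumoral_fraction)
  n_tum <- spec$n_segments - n_peri
  min_d <- 2 * spec$pixel_size
  if (!is.null(spec$diameters)) {
    d <- rep_len(spec$diameters, spec$n_segments)
    if (any(d <= 0)) stop("invalid spec: explicit diameters must be positive")
    d <- pmax(d, min_d + 1e-9)
  } else {
    set.seed(spec$seed + 1L)
    d <- pmax(stats::rnorm(spec$n_segments, spec$diameter_mean,
                           spec$diameter_sd), min_d + 1e-9)
  }
  set.seed(spec$seed)
  segs <- vector("list", spec$n_segments)
  obstacles <- NULL
  obstacle_r <- numeric(0)          # radius (px) of each obstacle point
  for (i in seq_len(spec$n_segments)) {
    side <- if (i <= n_tum) "in" else "out"
    r_px <- d[i] / spec$pixel_size / 2
    margin_px <- r_px + 3
    # +6 px: walk points are 12 px apart, so an edge can sag ~6 px closer
    # to an obstacle than its endpoints do
    sep <- if (is.null(obstacles)) NULL else obstacle_r + r_px + 6
    cl <- walk_centerline(spec, side, margin_px, obstacles, sep,
                          n_steps = sample(10:18, 1L))
    segs[[i]] <- list(centerline = cl, diameter = d[i],
                      region_tag = if (side == "in") "tumor" else "peritumoral")
    dens <- densify_polyline(cl)
    obstacles <- rbind(obstacles, dens)
    obstacle_r <- c(obstacle_r, rep(r_px, nrow(dens)))
  }
  if (is.null(spec$diameters) && spec$calibrate_dv) {
    # pin the length-weighted tumor D_V to diameter_mean exactly
    len <- vapply(segs, function(s) polyline_length_px(s$centerline), 0)
    tum <- vapply(segs, function(s) s$region_tag == "tumor", TRUE)
    lw <- sum(len[tum] * d[tum]) / sum(len[tum])
    d[tum] <- pmax(d[tum] * spec$diameter_mean / lw, min_d + 1e-9)
    lw2 <- sum(len[tum] * d[tum]) / sum(len[tum])
    d[tum] <- d[tum] * spec$diameter_mean / lw2
    for (i in seq_len(spec$n_segments)) segs[[i]]$diameter <- d[i]
  }
  truth <- network_truth(segs, spec)
  list(segments = segs, truth = truth)
}

network_truth <- function(segments, spec) {
  len_um <- vapply(segments, function(s)
    polyline_length_px(s$centerline) * spec$pixel_size, 0)
  d <- vapply(segments, `[[`, 0, "diameter")
  tags <- vapply(segments, `[[`, "", "region_tag")
  tum <- tags == "tumor"
  roi_mask <- polygon_mask(spec$tumor_roi, spec$field_height_px, spec$field_width_px)
  A_T <- sum(roi_mask) * spec$pixel_size^2
  L_V <- sum(len_um[tum])
  A_V <- sum(len_um[tum] * d[tum])
  structure(
    list(segment_length_um = len_um, segment_diameter_um = d,
         region_tag = tags,
         L_V_um = L_V, A_V_um2 = A_V, A_T_um2 = A_T,
         FVD_per_um = L_V / A_T,
         D_V_um = if (L_V > 0) A_V / L_V else NA_real_,
         roi_mask = roi_mask),
    class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("scene_truth:\n")
  cat(sprintf("  segments: %d (%d tumor)\n", length(x$segment_diameter_um),
              sum(x$region_tag == "tumor")))
  cat(sprintf("  L_V = %.0f um, A_V = %.0f um^2, A_T = %.0f um^2\n",
              x$L_V_um, x$A_V_um2, x$A_T_um2))
  cat(sprintf("  FVD = %.3g um^-1, D_V = %.3g um\n", x$FVD_per_um, x$D_V_um))
  if (!is.null(x$lock_start_s))
    cat(sprintf("  lock at %.0f s; first reperfusion %s\n", x$lock_start_s,
                if (is.finite(x$first_reperfusion_s))
                  sprintf("%.0f s", x$first_reperfusion_s) else "never"))
  invisible(x)
}

# Length-weighted mean diameter of a subset of segments (truth-side D_V).
length_weighted_dv <- function(truth, which_segments) {
  l <- truth$segment_length_um[which_segments]
  d <- truth$segment_diameter_um[which_segments]
  if (sum(l) == 0) return(NA_real_)
  sum(l * d) / sum(l)
}
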