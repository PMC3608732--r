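#' Construct an image stack
#'
#' The universal carrier between pipeline stages: a set of same-sized 16-bit
#' frames with per-frame acquisition timestamps and a physical pixel size.
#'
#' @param frames numeric array `H x W x T` (or a single `H x W` matrix) of
#'   nonnegative intensities in the 16-bit range `[0, 65535]`.
#' @param timestamps numeric vector of length `T`, acquisition times in
#'   seconds, strictly increasing.
#' @param pixel_size physical pixel size in micrometres per pixel (> 0).
#' @param meta optional named list of additional metadata (seed, scenario,
#'   treatment time, ...) carried through I/O round trips.
#'
#' @return An object of class `image_stack` with elements `frames`,
#'   `timestamps`, `pixel_size`, `meta`.
#' @export
image_stack <- function(frames, timestamps, pixel_size, meta = list()) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array")
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != dim(frames)[3L])
    stop("length(timestamps) must equal the number of frames")
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/px)")
  if (min(frames) < 0 || max(frames) > 65535)
    stop("frame intensities must lie in [0, 65535]")
  structure(
    list(frames = frames, timestamps = timestamps,
         pixel_size = pixel_size, meta = meta),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px (%.3g um/px)\n",
              d[3L], d[1L], d[2L], x$pixel_size))
  cat(sprintf("  time span %.0f .. %.0f s\n",
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3L]

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' Pixel data are written losslessly as 16-bit grayscale TIFF pages; the
#' timestamps, pixel size and any extra metadata go to `<path>.json` (vendor
#' TIFF tag dialects vary, so the sidecar is authoritative).
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(n_frames(stack)), function(i) {
    round(stack$frames[, , i]) / 65535
  })
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write TIFF stack to '", path, "': ", attr(ok, "condition")$message)
  meta <- c(list(timestamps = stack$timestamps, pixel_size = stack$pixel_size),
            stack$meta)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack]
#'
#' @param path TIFF path; `<path>.json` must hold `timestamps` and
#'   `pixel_size`.
#' @return An [image_stack].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such stack file: '", path, "'")
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar metadata '", sc, "' for stack '", path, "'")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$timestamps))
    stop("sidecar '", sc, "' lacks required field 'timestamps'")
  if (is.null(meta$pixel_size))
    stop("sidecar '", sc, "' lacks required field 'pixel_size'")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent page shapes in '", path, "': ", paste(unique(shapes), collapse = ", "))
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, TRUE)))
    stop("stack '", path, "' has multi-channel pages; expected grayscale")
  frames <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- round(pages[[i]] * 65535)
  extra <- meta[setdiff(names(meta), c("timestamps", "pixel_size"))]
  image_stack(frames, meta$timestamps, meta$pixel_size, meta = extra)
}

#' Read and write binary compartment masks
#'
#' Masks are exchanged with external editors (the hand-correction step of the
#' workflow) as single-channel PNG or TIFF images; any nonzero pixel is set.
#'
#' @param mask logical matrix.
#' @param path PNG or TIFF file path (chosen by extension).
#' @return `read_mask` returns a logical matrix; `write_mask` returns `path`
#'   invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 8L, compression = "none")
  } else {
    png::writePNG(m, path)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such mask file: '", path, "'")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) > 2L)
    stop("mask '", path, "' is multi-channel; expected a single-channel binary image")
  img != 0
}

#' Write time-indexed curve/morphometry tables to CSV
#'
#' One row per timepoint; "." decimal separator, UTF-8, Unix newlines. The
#' first column is always `time_s`.
#'
#' @param table a data.frame whose first column is `time_s` (an empty
#'   data.frame with the right columns yields a header-only file).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (ncol(table) == 0L || names(table)[1L] != "time_s")
    stop("curve tables must have 'time_s' as their first column")
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
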