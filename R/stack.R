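#' Time-lapse image stack container
#'
#' A minimal container for a grayscale time-lapse recording: an ordered list
#' of 2D intensity matrices (rows = y, columns = x, arbitrary units) together
#' with the two acquisition parameters the analysis needs, the pixel size
#' (µm/px) and the frame interval (s).
#'
#' Pixel `(row i, col j)` has its center at physical coordinates
#' `x = (j - 0.5) * pixel_size_um`, `y = (i - 0.5) * pixel_size_um`, with the
#' origin at the top-left corner, x rightward and y downward.
#'
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param pixel_size_um pixel size in µm per pixel, `> 0`.
#' @param frame_interval_s frame interval in seconds, `> 0`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval_s) {
  assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  assert_scalar_num(frame_interval_s, "frame_interval_s", positive = TRUE)
  if (!is.list(frames) || length(frames) == 0L ||
      !all(vapply(frames, is.matrix, logical(1)))) {
    stop_caflow("`frames` must be a non-empty list of matrices",
                "caflow_parameter_error")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_caflow("all frames must share the same dimensions",
                "caflow_parameter_error")
  }
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<image_stack> %d frames of %d x %d px, %.4g um/px, %.4g s/frame (%.4g s total)\n",
    length(x$frames), d[1], d[2], x$pixel_size_um, x$frame_interval_s,
    (length(x$frames) - 1) * x$frame_interval_s))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an [image_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Frame acquisition times
#' @param stack an [image_stack()].
#' @return numeric vector of frame times in seconds (first frame at 0).
#' @export
frame_times <- function(stack) {
  (seq_len(n_frames(stack)) - 1) * stack$frame_interval_s
}

#' Write a stack as a multi-page 16-bit TIFF plus a JSON metadata sidecar
#'
#' Intensities are linearly mapped onto the 16-bit range using `max_value`
#' (a.u. that maps to 65535).  The sidecar (same path with extension
#' `.json`) records `pixel_size_um`, `frame_interval_s`, `n_frames` and
#' `max_value_au` so the stack can be read back on its original scale.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param max_value intensity (a.u.) mapped to the top of the 16-bit range;
#'   default: smallest power of two not below the stack maximum.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, max_value = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(max_value)) {
    mx <- max(vapply(stack$frames, max, numeric(1)), 1)
    max_value <- 2^ceiling(log2(mx))
  }
  pages <- lapply(stack$frames, function(f) {
    f <- pmin(pmax(f / max_value, 0), 1)
    ## quantize to 16-bit levels so a write/read round trip is exact
    round(f * 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_interval_s = stack$frame_interval_s,
               n_frames = length(stack$frames),
               max_value_au = max_value)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_stack()]
#'
#' @param path TIFF path; the JSON sidecar is looked up next to it unless
#'   `meta` is given.
#' @param meta optional path to the metadata JSON.
#' @return An [image_stack()] with intensities restored to a.u.
#' @export
read_stack <- function(path, meta = NULL) {
  meta <- meta %||% sidecar_path(path)
  if (!file.exists(meta)) {
    stop_caflow(sprintf("metadata sidecar not found: %s", meta),
                "caflow_io_error")
  }
  m <- jsonlite::read_json(meta, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) p * m$max_value_au)
  image_stack(frames, m$pixel_size_um, m$frame_interval_s)
}

#' @noRd
sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
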