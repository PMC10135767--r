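#' Detection settings for [detect_cells()]
#'
#' The detector is deliberately simple and fully deterministic: optional
#' Gaussian smoothing, a global threshold, connected components, an area
#' filter, intensity-weighted centroids.
#'
#' Two threshold methods are available.  `"median_mad"` (default) sets the
#' threshold at `median + max(k * 1.4826 * MAD, floor_frac * median)`; because cell
#' pixels are a minority of the frame, the median and MAD track the
#' background level and background noise even when bright cells are present,
#' and the floor keeps the threshold above the background on
#' noiseless frames where the MAD collapses to zero.  `"mean_sd"`
#' (`mean + k * SD`) is provided for comparison but is biased upward by the
#' cells themselves on densely populated frames.
#'
#' @param method `"median_mad"` or `"mean_sd"`.
#' @param k threshold multiplier (default 3).
#' @param floor_frac minimum threshold offset above the background estimate,
#'   as a fraction of the frame median (used by `"median_mad"`; the
#'   fractional form keeps detection invariant under illumination
#'   rescaling).
#' @param blur_sigma_px Gaussian pre-smoothing sd in pixels; 0 disables.
#' @param min_area_um2,max_area_um2 component area bounds in µm².
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(method = c("median_mad", "mean_sd"), k = 3,
                             floor_frac = 0.2, blur_sigma_px = 0,
                             min_area_um2 = 20, max_area_um2 = 2000) {
  method <- match.arg(method)
  assert_scalar_num(k, "k", positive = TRUE)
  assert_scalar_num(floor_frac, "floor_frac", nonneg = TRUE)
  assert_scalar_num(blur_sigma_px, "blur_sigma_px", nonneg = TRUE)
  assert_scalar_num(min_area_um2, "min_area_um2", positive = TRUE)
  assert_scalar_num(max_area_um2, "max_area_um2", positive = TRUE)
  structure(list(method = method, k = k, floor_frac = floor_frac,
                 blur_sigma_px = blur_sigma_px, min_area_um2 = min_area_um2,
                 max_area_um2 = max_area_um2),
            class = "detection_config")
}

#' Detect cells in a single frame
#'
#' Smoothing (optional) then global threshold then connected components then
#' an area filter, returning intensity-weighted centroids in µm and the
#' pixel-index mask of each detection.  A frame with no component surviving
#' the filters yields zero detections (not an error).
#'
#' @param frame numeric matrix (rows = y, cols = x), a.u.
#' @param pixel_size_um µm per pixel.
#' @param config a [detection_config()].
#' @return A list with `centroids` (data.frame: `det`, `x_um`, `y_um`,
#'   `area_um2`, `mean_intensity`) and `masks` (list of integer pixel-index
#'   vectors into `frame`).
#' @export
detect_cells <- function(frame, pixel_size_um, config = detection_config()) {
  stopifnot(is.matrix(frame))
  if (!all(is.finite(frame))) {
    stop_caflow("`frame` contains non-finite values", "caflow_parameter_error")
  }
  assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  work <- frame
  if (config$blur_sigma_px > 0) {
    work <- EBImage::gblur(frame, sigma = config$blur_sigma_px)
  }
  thr <- switch(config$method,
    median_mad = {
      med <- stats::median(work)
      med + max(config$k * stats::mad(work, center = med),
                config$floor_frac * med)
    },
    mean_sd = mean(work) + config$k * stats::sd(work)
  )
  bw <- work > thr
  empty <- list(centroids = data.frame(det = integer(0), x_um = numeric(0),
                                       y_um = numeric(0), area_um2 = numeric(0),
                                       mean_intensity = numeric(0)),
                masks = list())
  if (!any(bw)) return(empty)
  lab <- EBImage::bwlabel(bw)
  labv <- as.integer(lab)
  idx_all <- which(labv > 0L)
  labs <- labv[idx_all]
  area_px <- tabulate(labs)
  px_area <- pixel_size_um^2
  keep <- which(area_px * px_area >= config$min_area_um2 &
                area_px * px_area <= config$max_area_um2)
  if (!length(keep)) return(empty)

  H <- nrow(frame)
  sel <- labs %in% keep
  idx <- idx_all[sel]
  g <- match(labs[sel], keep)
  ## intensity-weighted centroids on background-subtracted weights
  bgl <- stats::median(work)
  wts <- pmax(frame[idx] - bgl, 0)
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  wsum <- vapply(split(wts, g), sum, numeric(1))
  ## fall back to unweighted centroids for degenerate flat components
  flat <- wsum <= 0
  if (any(flat)) {
    wts[g %in% which(flat)] <- 1
    wsum <- vapply(split(wts, g), sum, numeric(1))
  }
  cx <- vapply(split(wts * (cols - 0.5), g), sum, numeric(1)) / wsum
  cy <- vapply(split(wts * (rows - 0.5), g), sum, numeric(1)) / wsum
  mi <- vapply(split(frame[idx], g), mean, numeric(1))
  ord <- seq_along(keep)
  list(
    centroids = data.frame(det = ord,
                           x_um = cx * pixel_size_um,
                           y_um = cy * pixel_size_um,
                           area_um2 = area_px[keep] * px_area,
                           mean_intensity = mi),
    masks = split(idx, g)
  )
}
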