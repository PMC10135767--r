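#' Mean fluorescence intensity of a cell region
#'
#' @param frame numeric matrix, a.u.
#' @param mask integer vector of pixel indices into `frame` (as produced by
#'   [detect_cells()]).
#' @return Arithmetic mean of the masked pixel intensities (a.u.).
#' @export
cell_intensity <- function(frame, mask) {
  stopifnot(is.matrix(frame))
  if (length(mask) == 0L) {
    stop_caflow("empty cell mask", "caflow_qc_error")
  }
  mean(frame[mask])
}

#' Local background intensity from four symmetric circular domains
#'
#' The background around a cell is estimated as the mean of the mean
#' intensities of four equidistant round domains (area `36 * pi` µm², i.e.
#' radius 6 µm) centered at `distance_um` (24 µm by default) from the cell
#' centroid, at 0, 90, 180 and 270 degrees from the image x axis.  A domain
#' that sticks out of the frame or overlaps any pixel of `exclusion_masks`
#' (typically the masks of all detected cells) is dropped; at least
#' `min_domains` usable domains are required, otherwise the estimate is
#' flagged unreliable (`F_IB = NA`).
#'
#' The symmetric placement makes the estimate first-order exact under a
#' linear illumination gradient: the four domain means average to the
#' background value at the centroid.
#'
#' @param frame numeric matrix, a.u.
#' @param centroid_um numeric `c(x, y)` in µm.
#' @param pixel_size_um µm per pixel.
#' @param distance_um centroid-to-domain-center distance (default 24 µm).
#' @param domain_area_um2 area of each domain (default `36 * pi` µm²).
#' @param exclusion_masks integer vector (or list of vectors) of pixel
#'   indices a domain must not touch.
#' @param min_domains minimum usable domains (default 2).
#' @param angles_deg domain bearings in degrees (default `c(0, 90, 180, 270)`).
#' @return A list: `F_IB` (a.u., `NA` if unreliable), `n_domains` (usable
#'   count), `domain_means`, `reliable` (logical).
#' @export
background_intensity <- function(frame, centroid_um, pixel_size_um,
                                 distance_um = 24, domain_area_um2 = 36 * pi,
                                 exclusion_masks = NULL, min_domains = 2,
                                 angles_deg = c(0, 90, 180, 270)) {
  stopifnot(is.matrix(frame), length(centroid_um) == 2L)
  assert_scalar_num(distance_um, "distance_um", positive = TRUE)
  assert_scalar_num(domain_area_um2, "domain_area_um2", positive = TRUE)
  r_um <- sqrt(domain_area_um2 / pi)
  H <- nrow(frame); W <- ncol(frame)
  W_um <- W * pixel_size_um; H_um <- H * pixel_size_um
  excl <- if (is.list(exclusion_masks)) unlist(exclusion_masks) else exclusion_masks
  th <- angles_deg * pi / 180
  means <- rep(NA_real_, length(th))
  for (i in seq_along(th)) {
    cx <- centroid_um[1] + distance_um * cos(th[i])
    cy <- centroid_um[2] + distance_um * sin(th[i])
    ## domain must lie fully inside the frame
    if (cx - r_um < 0 || cx + r_um > W_um || cy - r_um < 0 || cy + r_um > H_um) next
    dp <- disk_pixels(cx, cy, r_um, pixel_size_um, H, W, profile = "flat")
    if (length(dp$idx) == 0L) next
    if (!is.null(excl) && any(dp$idx %in% excl)) next
    means[i] <- mean(frame[dp$idx])
  }
  usable <- sum(!is.na(means))
  reliable <- usable >= min_domains
  list(F_IB = if (reliable) mean(means, na.rm = TRUE) else NA_real_,
       n_domains = usable, domain_means = means, reliable = reliable)
}

#' Normalized fluorescence intensity
#'
#' The dimensionless normalized intensity of a firmly adherent cell,
#' `F_IN = (F_IC - F_IB) / F_IB`, where `F_IC` is the mean cell fluorescence
#' and `F_IB` the local background.  The ratio is invariant under a common
#' rescaling of both inputs (illumination scale invariance).
#'
#' @param F_IC mean cell fluorescence intensity, a.u. (vectorized).
#' @param F_IB background fluorescence intensity, a.u., `> 0` (vectorized).
#' @return `(F_IC - F_IB) / F_IB`, dimensionless.
#' @examples
#' normalize_intensity(300, 100)  # 2
#' @export
normalize_intensity <- function(F_IC, F_IB) {
  if (!is.numeric(F_IC) || !is.numeric(F_IB)) {
    stop_caflow("F_IC and F_IB must be numeric", "caflow_parameter_error")
  }
  if (any(!is.na(F_IB) & F_IB <= 0)) {
    stop_caflow("F_IB must be > 0 (non-positive background signals a corrupt estimate)",
                "caflow_domain_error")
  }
  (F_IC - F_IB) / F_IB
}
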