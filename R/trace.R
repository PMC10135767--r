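#' Construct a calcium trace table
#'
#' A calcium trace holds, for one firmly adhered cell, the per-frame mean
#' cell fluorescence `F_IC`, the local background `F_IB` and the normalized
#' intensity `F_IN = (F_IC - F_IB)/F_IB`, indexed by time relative to arrest
#' onset (`t_rel_s`, 0 at onset).  `F_IN` is recomputed from `F_IC` and
#' `F_IB` so the row-wise identity holds to machine precision by
#' construction.
#'
#' @param t_rel_s strictly increasing time from arrest onset, seconds.
#' @param F_IC mean cell fluorescence, a.u.
#' @param F_IB background fluorescence, a.u. (`NA` marks QC-failed frames).
#' @param track_id identifier carried through to the features table.
#' @param qc optional list of QC flags.
#' @return A data.frame of class `calcium_trace` with columns `t_rel_s`,
#'   `F_IC`, `F_IB`, `F_IN` and attributes `track_id` and `qc`.
#' @export
calcium_trace <- function(t_rel_s, F_IC, F_IB, track_id = NA, qc = list()) {
  n <- length(t_rel_s)
  stopifnot(length(F_IC) == n, length(F_IB) == n)
  if (is.unsorted(t_rel_s, strictly = TRUE)) {
    stop_caflow("`t_rel_s` must be strictly increasing", "caflow_parameter_error")
  }
  ok <- !is.na(F_IB)
  if (any(F_IB[ok] <= 0)) {
    stop_caflow("F_IB must be > 0 on all non-QC-failed frames", "caflow_domain_error")
  }
  F_IN <- rep(NA_real_, n)
  F_IN[ok] <- normalize_intensity(F_IC[ok], F_IB[ok])
  structure(
    data.frame(t_rel_s = t_rel_s, F_IC = F_IC, F_IB = F_IB, F_IN = F_IN),
    class = c("calcium_trace", "data.frame"),
    track_id = track_id, qc = qc
  )
}

#' Extract the calcium trace of one firmly adhered cell from a stack
#'
#' The cell mask and the four background domains are frozen at the arrest
#' onset frame: the cell is stationary from onset onward, and a frozen mask
#' avoids the brightness-dependent segmentation bias a per-frame mask would
#' introduce into the peak/plateau ratio.  At the onset frame the function
#' re-detects all cells, picks the detection nearest the track's position at
#' onset, uses its pixel mask for `F_IC`, and places the background domains
#' around its centroid, excluding any domain that touches another detected
#' cell or the frame edge (at least `min_domains` must survive).
#'
#' Frames whose background is unusable are marked QC-failed (`F_IN = NA`);
#' the trace as a whole is flagged (`attr(x, "qc")$fail`) when more than
#' `max_bad_frac` of its frames fail.
#'
#' @param stack an [image_stack()].
#' @param track per-track data.frame (`frame`, `t_s`, `x_um`, `y_um`).
#' @param adhesion an `adhesion_event` for this track
#'   ([classify_firm_adhesion()]); must be firm.
#' @param config a [detection_config()] used to re-detect at the onset frame.
#' @param distance_um,domain_area_um2,min_domains background-domain geometry,
#'   see [background_intensity()].
#' @param match_dist_um maximum distance between the track position at onset
#'   and the chosen detection.
#' @return A [calcium_trace()] covering the frames from arrest onset to the
#'   end of the stack.
#' @export
extract_trace <- function(stack, track, adhesion,
                          config = detection_config(),
                          distance_um = 24, domain_area_um2 = 36 * pi,
                          min_domains = 2, match_dist_um = 10,
                          max_bad_frac = 0.2) {
  stopifnot(inherits(stack, "image_stack"))
  if (!inherits(adhesion, "adhesion_event") || !isTRUE(adhesion$firm)) {
    stop_caflow("`adhesion` must be a firm adhesion_event (the trace is defined only for firmly adhered cells)",
                "caflow_precondition_error")
  }
  dt <- stack$frame_interval_s
  onset <- adhesion$onset_time_s
  j0 <- as.integer(round(onset / dt)) + 1L
  nf <- n_frames(stack)
  if (j0 < 1L || j0 > nf) {
    stop_caflow("arrest onset lies outside the stack", "caflow_parameter_error")
  }
  frame0 <- stack$frames[[j0]]
  det <- detect_cells(frame0, stack$pixel_size_um, config)
  if (nrow(det$centroids) == 0L) {
    stop_caflow("no detections at the onset frame", "caflow_qc_error")
  }
  ## track position at (or nearest to) onset
  i_tr <- which.min(abs(track$t_s - onset))
  d <- sqrt((det$centroids$x_um - track$x_um[i_tr])^2 +
            (det$centroids$y_um - track$y_um[i_tr])^2)
  sel <- which.min(d)
  if (d[sel] > match_dist_um) {
    stop_caflow("no detection within match_dist_um of the track at onset",
                "caflow_qc_error")
  }
  mask <- det$masks[[sel]]
  centroid <- c(det$centroids$x_um[sel], det$centroids$y_um[sel])
  other_masks <- unlist(det$masks[-sel])
  ## cells can arrive after this cell's onset; exclude space occupied by any
  ## cell detected at the end of the recording as well, so a background
  ## domain is never placed where a later-arriving cell will sit
  if (nf > j0) {
    det_end <- detect_cells(stack$frames[[nf]], stack$pixel_size_um, config)
    if (nrow(det_end$centroids)) {
      d_end <- sqrt((det_end$centroids$x_um - centroid[1])^2 +
                    (det_end$centroids$y_um - centroid[2])^2)
      keep_end <- which(d_end > match_dist_um)
      other_masks <- unique(c(other_masks, unlist(det_end$masks[keep_end])))
    }
  }

  ## freeze the background-domain pixel sets at the onset geometry
  bg0 <- background_intensity(frame0, centroid, stack$pixel_size_um,
                              distance_um = distance_um,
                              domain_area_um2 = domain_area_um2,
                              exclusion_masks = other_masks,
                              min_domains = min_domains)
  r_um <- sqrt(domain_area_um2 / pi)
  th <- c(0, 90, 180, 270) * pi / 180
  dom_idx <- lapply(which(!is.na(bg0$domain_means)), function(i) {
    disk_pixels(centroid[1] + distance_um * cos(th[i]),
                centroid[2] + distance_um * sin(th[i]),
                r_um, stack$pixel_size_um, nrow(frame0), ncol(frame0),
                profile = "flat")$idx
  })
  usable <- length(dom_idx) >= min_domains

  js <- j0:nf
  F_IC <- vapply(js, function(j) mean(stack$frames[[j]][mask]), numeric(1))
  F_IB <- if (usable) {
    vapply(js, function(j) {
      f <- stack$frames[[j]]
      mean(vapply(dom_idx, function(ix) mean(f[ix]), numeric(1)))
    }, numeric(1))
  } else rep(NA_real_, length(js))
  bad <- is.na(F_IB) | F_IB <= 0
  F_IB[bad] <- NA_real_
  frac_bad <- mean(bad)
  qc <- list(fail = frac_bad > max_bad_frac, frac_bad_frames = frac_bad,
             n_domains = bg0$n_domains, onset_frame = j0,
             match_dist_um = d[sel])
  calcium_trace((js - 1) * dt - onset, F_IC, F_IB,
                track_id = track$track_id[1] %||% NA, qc = qc)
}
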