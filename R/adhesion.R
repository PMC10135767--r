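#' Classify a track as firmly adherent
#'
#' A cell is called firmly adherent when its travel displacement over a
#' sliding window of `window_s` seconds (1 min by default) is strictly less
#' than `threshold_um` (10 µm by default).  The window slides at frame
#' resolution; for each start frame the window end is the last sample within
#' `window_s` of the start, and only windows fully covered by the track
#' (start time + `window_s` does not run past the last sample) are
#' considered.  "Travel displacement" defaults to the net Euclidean distance
#' between the first and the last position of the window (`mode = "net"`);
#' the cumulative path length over the window is available with
#' `mode = "path"`.  The earliest qualifying window defines the arrest onset,
#' which is the `t = 0` reference for the cell's calcium trace.
#'
#' A track spanning less than `window_s` cannot qualify and is returned as
#' not firm with the `insufficient_span` flag set.
#'
#' @param track data.frame with columns `t_s`, `x_um`, `y_um` (one row per
#'   observation, time strictly increasing), e.g. one element of
#'   [split_tracks()].
#' @param window_s window duration in seconds (default 60).
#' @param threshold_um displacement threshold in µm (default 10, strict
#'   inequality).
#' @param mode `"net"` (endpoint displacement, default) or `"path"`
#'   (cumulative step length).
#' @return A list of class `adhesion_event`: `track_id` (if present in
#'   `track`), `firm` (logical), `onset_time_s` (start of the earliest
#'   qualifying window; `NA` when not firm), `qualifying_window`
#'   (`c(start, end)` in seconds, `NA` when not firm), and
#'   `insufficient_span`.
#' @export
classify_firm_adhesion <- function(track, window_s = 60, threshold_um = 10,
                                   mode = c("net", "path")) {
  mode <- match.arg(mode)
  assert_scalar_num(window_s, "window_s", positive = TRUE)
  assert_scalar_num(threshold_um, "threshold_um", positive = TRUE)
  stopifnot(is.data.frame(track), all(c("t_s", "x_um", "y_um") %in% names(track)))
  t <- track$t_s
  n <- length(t)
  if (is.unsorted(t, strictly = TRUE)) {
    stop_caflow("`track$t_s` must be strictly increasing", "caflow_parameter_error")
  }
  out <- function(firm, onset, win, short) {
    structure(list(track_id = track$track_id[1] %||% NA,
                   firm = firm, onset_time_s = onset,
                   qualifying_window = win, insufficient_span = short),
              class = "adhesion_event")
  }
  if (n < 2L || t[n] - t[1] < window_s) {
    return(out(FALSE, NA_real_, c(NA_real_, NA_real_), TRUE))
  }
  ## window end index for each admissible start: last sample with
  ## t <= t_start + window_s (tolerance guards float noise on regular grids)
  eps <- 1e-9 * window_s
  starts <- which(t + window_s <= t[n] + eps)
  ends <- findInterval(t[starts] + window_s + eps, t)
  disp <- if (mode == "net") {
    sqrt((track$x_um[ends] - track$x_um[starts])^2 +
         (track$y_um[ends] - track$y_um[starts])^2)
  } else {
    step <- c(0, cumsum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)))
    step[ends] - step[starts]
  }
  ok <- disp < threshold_um
  if (!any(ok)) return(out(FALSE, NA_real_, c(NA_real_, NA_real_), FALSE))
  i <- starts[which(ok)[1]]
  out(TRUE, t[i], c(t[i], t[findInterval(t[i] + window_s + eps, t)]), FALSE)
}

#' @export
print.adhesion_event <- function(x, ...) {
  cat(sprintf("<adhesion_event> track %s: %s%s\n",
              as.character(x$track_id),
              if (x$firm) sprintf("firm, onset %.3g s", x$onset_time_s) else "not firm",
              if (x$insufficient_span) " (insufficient span)" else ""))
  invisible(x)
}

#' Classify every track in a track table
#'
#' @param tracks a `cell_tracks` object or track data.frame.
#' @inheritParams classify_firm_adhesion
#' @return data.frame: `track_id`, `firm`, `onset_time_s`,
#'   `insufficient_span`.
#' @export
classify_all_tracks <- function(tracks, window_s = 60, threshold_um = 10,
                                mode = c("net", "path")) {
  mode <- match.arg(mode)
  per <- split_tracks(tracks)
  ev <- lapply(per, classify_firm_adhesion, window_s = window_s,
               threshold_um = threshold_um, mode = mode)
  data.frame(
    track_id = vapply(per, function(d) d$track_id[1], numeric(1)),
    firm = vapply(ev, `[[`, logical(1), "firm"),
    onset_time_s = vapply(ev, `[[`, numeric(1), "onset_time_s"),
    insufficient_span = vapply(ev, `[[`, logical(1), "insufficient_span"),
    row.names = NULL
  )
}

#' Count firmly adherent cells within the assay window
#'
#' The adhesion assay readout: the number of distinct tracks classified firm
#' whose arrest onset falls within the assay duration (7 min by default).
#'
#' @param adhesion data.frame from [classify_all_tracks()], or a list of
#'   `adhesion_event` objects.
#' @param assay_duration_s assay window in seconds (default 420).
#' @return Integer count.
#' @export
count_firm_adherent <- function(adhesion, assay_duration_s = 420) {
  assert_scalar_num(assay_duration_s, "assay_duration_s", positive = TRUE)
  if (!is.data.frame(adhesion)) {
    adhesion <- data.frame(
      firm = vapply(adhesion, `[[`, logical(1), "firm"),
      onset_time_s = vapply(adhesion, `[[`, numeric(1), "onset_time_s"))
  }
  sum(adhesion$firm & adhesion$onset_time_s <= assay_duration_s, na.rm = TRUE)
}
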