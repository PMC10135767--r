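#' Link per-frame detections into cell tracks
#'
#' Greedy nearest-neighbour linking: at each frame transition, candidate
#' (open track, detection) pairs with distance at most `max_step_um` are
#' sorted by (distance, track id, detection index) and assigned first-come,
#' which makes the result deterministic.  Unmatched detections start new
#' tracks; a track unmatched for more than `max_gap` consecutive frames is
#' closed.  Pathological crowding yields short tracks rather than errors;
#' the QC summary reports track lengths and the short-track count.
#'
#' @param detections list with one element per frame, each as returned by
#'   [detect_cells()] (only `centroids` is used), or a list of data.frames
#'   with columns `x_um`, `y_um`.
#' @param frame_interval_s seconds between frames.
#' @param max_step_um maximum per-transition displacement for a link.
#' @param max_gap maximum number of consecutive missed frames before a track
#'   is closed (0 = no gaps allowed).
#' @return A list of class `cell_tracks`: `tracks` (data.frame `track_id`,
#'   `frame`, `t_s`, `x_um`, `y_um`, `det`) and `qc` (list: `n_tracks`,
#'   `track_lengths`, `short_tracks`).
#' @export
link_tracks <- function(detections, frame_interval_s, max_step_um = 10,
                        max_gap = 2) {
  assert_scalar_num(frame_interval_s, "frame_interval_s", positive = TRUE)
  assert_scalar_num(max_step_um, "max_step_um", positive = TRUE)
  assert_scalar_num(max_gap, "max_gap", nonneg = TRUE)
  get_cent <- function(d) if (is.data.frame(d)) d else d$centroids
  nf <- length(detections)
  ## every detection yields exactly one output row: preallocate
  total <- sum(vapply(detections, function(d) {
    cen <- get_cent(d); if (is.null(cen)) 0L else nrow(cen)
  }, integer(1)))
  o_tid <- integer(total); o_frame <- integer(total)
  o_x <- numeric(total); o_y <- numeric(total); o_det <- integer(total)
  cur <- 0L
  push <- function(tid, frame, x, y, det) {
    cur <<- cur + 1L
    o_tid[cur] <<- tid; o_frame[cur] <<- frame
    o_x[cur] <<- x; o_y[cur] <<- y; o_det[cur] <<- det
  }
  ## open tracks: id, last position, frames since last match
  open_id <- integer(0); open_x <- numeric(0); open_y <- numeric(0)
  open_miss <- integer(0)
  next_id <- 1L
  for (j in seq_len(nf)) {
    cen <- get_cent(detections[[j]])
    nd <- if (is.null(cen)) 0L else nrow(cen)
    used_d <- logical(nd)
    if (nd > 0L && length(open_id) > 0L) {
      dx <- outer(open_x, cen$x_um, `-`)
      dy <- outer(open_y, cen$y_um, `-`)
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= max_step_um, arr.ind = TRUE)
      used_t <- logical(length(open_id))
      if (nrow(cand)) {
        ord <- order(dist[cand], open_id[cand[, 1]], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          ti <- cand[r, 1]; di <- cand[r, 2]
          if (!used_t[ti] && !used_d[di]) {
            used_t[ti] <- TRUE; used_d[di] <- TRUE
            open_x[ti] <- cen$x_um[di]; open_y[ti] <- cen$y_um[di]
            open_miss[ti] <- 0L
            push(open_id[ti], j, cen$x_um[di], cen$y_um[di], di)
          }
        }
      }
      open_miss[!used_t] <- open_miss[!used_t] + 1L
    } else if (length(open_id) > 0L) {
      open_miss <- open_miss + 1L
    }
    ## close stale tracks
    stale <- open_miss > max_gap
    if (any(stale)) {
      open_id <- open_id[!stale]; open_x <- open_x[!stale]
      open_y <- open_y[!stale]; open_miss <- open_miss[!stale]
    }
    ## new tracks from unmatched detections
    if (nd > 0L && any(!used_d)) {
      for (di in which(!used_d)) {
        open_id <- c(open_id, next_id)
        open_x <- c(open_x, cen$x_um[di]); open_y <- c(open_y, cen$y_um[di])
        open_miss <- c(open_miss, 0L)
        push(next_id, j, cen$x_um[di], cen$y_um[di], di)
        next_id <- next_id + 1L
      }
    }
  }
  tracks <- data.frame(track_id = o_tid, frame = o_frame,
                       t_s = (o_frame - 1) * frame_interval_s,
                       x_um = o_x, y_um = o_y, det = o_det)
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  lens <- if (nrow(tracks)) as.integer(table(tracks$track_id)) else integer(0)
  structure(list(tracks = tracks,
                 qc = list(n_tracks = length(lens), track_lengths = lens,
                           short_tracks = sum(lens < 5L))),
            class = "cell_tracks")
}

#' Split a track table into per-track data.frames
#' @param tracks a `cell_tracks` object or its `tracks` data.frame.
#' @return Named list of per-track data.frames, ordered by frame.
#' @export
split_tracks <- function(tracks) {
  df <- if (inherits(tracks, "cell_tracks")) tracks$tracks else tracks
  split(df, df$track_id)
}

#' Track a full stack: per-frame detection plus linking
#'
#' @param stack an [image_stack()].
#' @param config a [detection_config()].
#' @param max_step_um,max_gap linking parameters, see [link_tracks()].
#' @return A `cell_tracks` object (see [link_tracks()]).
#' @export
track_stack <- function(stack, config = detection_config(), max_step_um = 10,
                        max_gap = 2) {
  stopifnot(inherits(stack, "image_stack"))
  dets <- lapply(stack$frames, detect_cells,
                 pixel_size_um = stack$pixel_size_um, config = config)
  link_tracks(dets, stack$frame_interval_s, max_step_um, max_gap)
}
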