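#' Settings for onset detection and transient feature extraction
#'
#' @param k plateau-SD multiplier for the onset trigger (default 3).
#' @param m number of consecutive supra-threshold frames required (default 5).
#' @param floor_fin absolute minimum rise above the plateau mean for the
#'   trigger, in F_IN units (default 0.1); keeps the trigger meaningful on
#'   near-noiseless traces where the plateau SD collapses.
#' @param min_plateau_s minimum plateau data before a candidate onset,
#'   seconds (default 2).
#' @param trigger_smooth_s width (s) of the centered moving average applied
#'   to the trace for the trigger scan only (default 1; 0 disables).  The
#'   averaging lets the trigger fire early on the rise, before the running
#'   plateau statistics absorb the ramp; feature values are never read off
#'   the smoothed trace.
#' @param refine logical; refine the triggered onset by a two-segment
#'   (constant plateau + continuous linear rise) least-squares changepoint
#'   fit with sub-frame backcasting (default `TRUE`).  Without refinement
#'   the onset is the first trigger crossing, which is systematically late
#'   for a ramp.
#' @param peak_smooth_s width (s) of the moving average used only to get a
#'   first peak locality under noise (default 2).  The peak itself is then
#'   fitted as the intersection of a rise line and a decay line (broken-line
#'   least squares) around that locality, so the reported peak time carries
#'   no smoothing shift.
#' @param peak_halfwidth_s half-width (s) of the raw-trace window used to
#'   read the peak value when the line fit is degenerate (default 0.25).
#' @param activation_threshold minimum I_P for the activated call
#'   (default 1.5, `>=` convention).
#' @param ip_mode `"raw-ratio"` (default): `I_P = (1 + F_IN_peak) /
#'   (1 + F_IN_plateau)`, the ratio of the raw peak fluorescence to the raw
#'   mean fluorescence during the delay period under a stable background;
#'   `"normalized-ratio"`: the literal ratio of normalized intensities
#'   `F_IN_peak / F_IN_plateau`, which is unstable when the plateau F_IN is
#'   near zero.
#' @return A list of class `features_config`.
#' @export
features_config <- function(k = 3, m = 5, floor_fin = 0.1, min_plateau_s = 2,
                            trigger_smooth_s = 1, refine = TRUE,
                            peak_smooth_s = 2, peak_halfwidth_s = 0.25,
                            activation_threshold = 1.5,
                            ip_mode = c("raw-ratio", "normalized-ratio")) {
  ip_mode <- match.arg(ip_mode)
  assert_scalar_num(k, "k", positive = TRUE)
  assert_scalar_num(m, "m", positive = TRUE)
  assert_scalar_num(floor_fin, "floor_fin", nonneg = TRUE)
  assert_scalar_num(min_plateau_s, "min_plateau_s", positive = TRUE)
  assert_scalar_num(trigger_smooth_s, "trigger_smooth_s", nonneg = TRUE)
  assert_scalar_num(peak_smooth_s, "peak_smooth_s", nonneg = TRUE)
  assert_scalar_num(peak_halfwidth_s, "peak_halfwidth_s", nonneg = TRUE)
  assert_scalar_num(activation_threshold, "activation_threshold", positive = TRUE)
  structure(list(k = k, m = as.integer(m), floor_fin = floor_fin,
                 min_plateau_s = min_plateau_s,
                 trigger_smooth_s = trigger_smooth_s, refine = isTRUE(refine),
                 peak_smooth_s = peak_smooth_s,
                 peak_halfwidth_s = peak_halfwidth_s,
                 activation_threshold = activation_threshold,
                 ip_mode = ip_mode),
            class = "features_config")
}

## cumulative sums for O(1) least-squares lines on index ranges
#' @noRd
ls_cums <- function(y, t) {
  list(Sy = cumsum(y), Syy = cumsum(y^2), St = cumsum(t),
       Stt = cumsum(t^2), Syt = cumsum(y * t))
}

## vectorized simple-regression SSE (and coefficients) of y ~ t over the
## index ranges (lo, hi]; lo, hi equal-length integer vectors, hi - lo >= 2
#' @noRd
ls_line_range <- function(cs, lo, hi) {
  n <- hi - lo
  Sy <- cs$Sy[hi] - cs$Sy[lo]
  Syy <- cs$Syy[hi] - cs$Syy[lo]
  St <- cs$St[hi] - cs$St[lo]
  Stt <- cs$Stt[hi] - cs$Stt[lo]
  Syt <- cs$Syt[hi] - cs$Syt[lo]
  Sxx <- Stt - St^2 / n
  Sxy <- Syt - St * Sy / n
  b <- ifelse(Sxx > 0, Sxy / Sxx, 0)
  a <- (Sy - b * St) / n
  sse <- pmax(Syy - Sy^2 / n - ifelse(Sxx > 0, Sxy^2 / Sxx, 0), 0)
  list(intercept = a, slope = b, sse = sse)
}

## two-segment least-squares changepoint: constant plateau over [1, o],
## continuous linear rise over (o, p].  Returns the knot index minimizing
## the total SSE (earliest on ties).  O(p) via cumulative sums.
#' @noRd
changepoint_knot <- function(y, t, o_min, p) {
  if (p - o_min < 2L) return(o_min)
  S1 <- cumsum(y); S2 <- cumsum(y^2)
  St <- cumsum(t); Stt <- cumsum(t^2); Syt <- cumsum(y * t)
  os <- o_min:(p - 2L)
  cc <- S1[os] / os
  sse1 <- S2[os] - os * cc^2
  m2 <- p - os
  A <- S1[p] - S1[os]
  B <- S2[p] - S2[os]
  C <- St[p] - St[os]
  E <- Syt[p] - Syt[os]
  D <- Stt[p] - Stt[os]
  t_o <- t[os]
  Su2 <- D - 2 * t_o * C + m2 * t_o^2
  Syu <- (E - t_o * A) - cc * (C - m2 * t_o)
  b <- pmax(Syu / Su2, 0)
  sse2 <- (B - 2 * cc * A + m2 * cc^2) - 2 * b * Syu + b^2 * Su2
  os[which.min(sse1 + sse2)]
}

#' Detect the onset of the calcium rise in a normalized trace
#'
#' Operationalizes the "sharp increase" of the normalized fluorescence
#' trace.  Two stages:
#'
#' 1. *Trigger*: a running plateau estimate (mean and SD of the trace from
#'    `t_rel = 0` up to the candidate) is scanned, on a lightly smoothed
#'    copy of the trace, for the first time at which the trace exceeds
#'    `plateau_mean + max(k * plateau_SD, floor_fin)` for `m` consecutive
#'    frames.  No crossing means no onset (the non-activated path).
#' 2. *Refinement* (default): the onset is relocated by a two-segment
#'    least-squares fit — constant plateau followed by a linear rise,
#'    continuous at the knot — over the frames up to the rise top, then
#'    backcast to sub-frame resolution by intersecting a line fitted to the
#'    lower part of the rise with the plateau level.  On a noiseless ramp
#'    this recovers the true onset exactly; the trigger alone is late by
#'    `floor_fin / slope`.
#'
#' @param trace a [calcium_trace()] (or data.frame with `t_rel_s`, `F_IN`).
#' @param config a [features_config()].
#' @return `NULL` when no onset is found, otherwise a list: `onset_time_rel`
#'   (s), `knot_index`, `trigger_index`, `plateau_mean`, `plateau_sd`,
#'   `rise_top_index`.
#' @export
detect_onset <- function(trace, config = features_config()) {
  y_all <- trace$F_IN
  t_all <- trace$t_rel_s
  keep <- t_all >= 0 & !is.na(y_all)
  y <- y_all[keep]; t <- t_all[keep]
  n <- length(y)
  dt <- stats::median(diff(t))
  min_frames <- max(as.integer(ceiling(config$min_plateau_s / dt)), 3L)
  if (n < min_frames + config$m + 2L) {
    stop_caflow("trace too short for onset detection (needs the minimum plateau plus m frames)",
                "caflow_precondition_error")
  }
  w_trig <- max(1L, as.integer(round(config$trigger_smooth_s / dt)))
  y_det <- moving_average(y, w_trig)

  ## stage 1: trigger on the running plateau estimate of the smoothed trace
  cs <- cumsum(y_det); cs2 <- cumsum(y_det^2)
  i_seq <- (min_frames + 1L):n
  mu <- cs[i_seq - 1L] / (i_seq - 1L)
  vv <- pmax((cs2[i_seq - 1L] - (i_seq - 1L) * mu^2) / (i_seq - 2L), 0)
  thr <- mu + pmax(config$k * sqrt(vv), config$floor_fin)
  above <- y_det[i_seq] > thr
  run <- 0L; trig <- NA_integer_
  for (ii in seq_along(above)) {
    run <- if (above[ii]) run + 1L else 0L
    if (run >= config$m) { trig <- i_seq[ii] - config$m + 1L; break }
  }
  if (is.na(trig)) return(NULL)

  ## rise top: smoothed argmax after the trigger, pulled back by half the
  ## smoothing window so the changepoint fit sees (almost) pure rise
  w_pk <- max(1L, as.integer(round(config$peak_smooth_s / dt)))
  ys <- moving_average(y, w_pk)
  i_max <- trig - 1L + which.max(ys[trig:n])
  p <- max(min(i_max - (w_pk %/% 2L), n), min_frames + 2L)

  if (!config$refine) {
    o <- max(trig - 1L, min_frames)
    return(list(onset_time_rel = t[trig], knot_index = o, trigger_index = trig,
                plateau_mean = mean(y[1:o]), plateau_sd = stats::sd(y[1:o]),
                rise_top_index = i_max))
  }
  o <- changepoint_knot(y, t, min_frames, p)
  plateau_mean <- mean(y[1:o])
  plateau_sd <- stats::sd(y[1:o])
  ## sub-frame backcast: line over the lower 80% of the rise (the top is
  ## excluded so curvature near the peak cannot tilt the fit), intersected
  ## with the plateau level; clamped near the knot
  onset <- t[min(o + 1L, n)]
  hi <- o + max(as.integer(floor(0.8 * (p - o))), 3L)
  hi <- min(hi, p)
  if (hi - o >= 3L) {
    idx <- (o + 1L):hi
    fit <- stats::lm.fit(cbind(1, t[idx]), y[idx])
    b <- fit$coefficients[2]
    if (is.finite(b) && b > 0) {
      t_cross <- (plateau_mean - fit$coefficients[1]) / b
      onset <- min(max(t_cross, t[o] - 2 * dt, 0), t[o] + 2 * dt)
    }
  }
  list(onset_time_rel = onset, knot_index = o, trigger_index = trig,
       plateau_mean = plateau_mean, plateau_sd = plateau_sd,
       rise_top_index = i_max)
}

## peak location and value as the intersection of a rise line and a decay
## line.  The smoothed argmax gives the peak locality; the rise line is
## fitted on frames ending one smoothing window before it and the decay
## line on frames starting one window after it, so both segments are clean
## of the kink even when the argmax jitters under noise.  The intersection
## is exact for a noiseless linear-rise/slow-decay kink and carries no
## smoothing lag; when the geometry is degenerate (slopes do not cross,
## trace ends at the peak) the raw-trace window mean around the argmax is
## used instead.
#' @noRd
peak_fit <- function(y, t, o, config) {
  n <- length(y)
  dt <- stats::median(diff(t))
  w <- max(1L, as.integer(round(config$peak_smooth_s / dt)))
  ys <- moving_average(y, w)
  seg <- (o + 1L):n
  i0 <- seg[which.max(ys[seg])]
  fallback <- function() {
    hw <- config$peak_halfwidth_s
    win <- which(t >= t[i0] - hw & t <= t[i0] + hw & t > t[o])
    if (!length(win)) win <- i0
    list(t_peak = t[i0], peak_fin = mean(y[win]))
  }
  ## decay-fit length: long under noise (variance-limited), short when the
  ## plateau is quiet (the linear fit of the convex decay is bias-limited)
  sdp <- stats::sd(y[seq_len(o)])
  amp_est <- ys[i0] - mean(y[seq_len(o)])
  d_mult <- if (is.finite(sdp) && amp_est > 0 && sdp <= 0.03 * amp_est) 1L else 6L
  rise_hi <- i0 - w
  dec_lo <- min(i0 + w, n)
  dec_hi <- min(dec_lo + d_mult * w, n)
  if (rise_hi - o < 3L || dec_hi - dec_lo < 2L) return(fallback())
  ri <- (o + 1L):rise_hi
  di <- dec_lo:dec_hi
  f1 <- stats::lm.fit(cbind(1, t[ri]), y[ri])$coefficients
  f2 <- stats::lm.fit(cbind(1, t[di]), y[di])$coefficients
  a1 <- f1[2]; c1 <- f1[1]; a2 <- f2[2]; c2 <- f2[1]
  if (!is.finite(a1) || !is.finite(a2) || a1 <= 0 || a1 <= a2) return(fallback())
  t_int <- (c2 - c1) / (a1 - a2)
  w_s <- 3 * w * dt
  if (!is.finite(t_int) || t_int < t[i0] - w_s || t_int > t[i0] + w_s) {
    return(fallback())
  }
  list(t_peak = t_int, peak_fin = c1 + a1 * t_int)
}

#' Extract the transient characteristics of a calcium trace
#'
#' Computes the three per-cell characteristics of a calcium burst:
#'
#' * delay time `T_D`: time from arrest onset (`t_rel = 0`) to the onset of
#'   the sharp rise, as located by [detect_onset()];
#' * peak time `T_P`: duration of the rise, i.e. the time of the trace
#'   maximum minus the rise onset;
#' * peak calcium intensity `I_P`: the ratio of the peak fluorescence to the
#'   mean fluorescence during the delay plateau, by default on the raw
#'   intensity scale, `I_P = (1 + F_IN_peak)/(1 + F_IN_plateau)` (see
#'   [features_config()] for the alternative literal normalized ratio).
#'
#' A cell is called activated when an onset is found *and* `I_P` reaches the
#' activation threshold (`>=` convention); otherwise the features are
#' returned as `NA` and `activated = FALSE`.
#'
#' @param trace a [calcium_trace()] (or data.frame with `t_rel_s`, `F_IN`).
#' @param onset result of [detect_onset()]; computed when `NULL`; pass
#'   `NA` to force the non-activated path.
#' @param config a [features_config()].
#' @return A one-row data.frame: `track_id`, `activated`, `T_D_s`, `T_P_s`,
#'   `I_P`, `plateau_mean`, `onset_time_rel_s`, `peak_time_rel_s`, `qc_fail`.
#' @export
transient_features <- function(trace, onset = NULL, config = features_config()) {
  track_id <- attr(trace, "track_id") %||% NA
  qc <- attr(trace, "qc") %||% list()
  qc_fail <- isTRUE(qc$fail)
  none <- function(fail = qc_fail) data.frame(
    track_id = track_id, activated = FALSE, T_D_s = NA_real_,
    T_P_s = NA_real_, I_P = NA_real_, plateau_mean = NA_real_,
    onset_time_rel_s = NA_real_, peak_time_rel_s = NA_real_, qc_fail = fail)

  if (is.null(onset)) onset <- detect_onset(trace, config)
  if (is.null(onset) || (!is.list(onset) && is.na(onset))) return(none())

  keep <- trace$t_rel_s >= 0 & !is.na(trace$F_IN)
  y <- trace$F_IN[keep]; t <- trace$t_rel_s[keep]
  o <- onset$knot_index
  plateau_mean <- onset$plateau_mean
  pk <- peak_fit(y, t, o, config)
  dtv <- stats::median(diff(t))
  t_peak <- max(pk$t_peak, onset$onset_time_rel + dtv)
  peak_fin <- pk$peak_fin

  I_P <- if (config$ip_mode == "raw-ratio") {
    (1 + peak_fin) / (1 + plateau_mean)
  } else {
    if (plateau_mean <= 0) return(none(fail = TRUE))
    peak_fin / plateau_mean
  }
  if (!is.finite(I_P) || I_P < config$activation_threshold) return(none())
  data.frame(track_id = track_id, activated = TRUE,
             T_D_s = onset$onset_time_rel,
             T_P_s = t_peak - onset$onset_time_rel,
             I_P = I_P, plateau_mean = plateau_mean,
             onset_time_rel_s = onset$onset_time_rel,
             peak_time_rel_s = t_peak, qc_fail = qc_fail)
}

#' Activated / non-activated call
#'
#' A cell is activated when an onset was detected and its peak calcium
#' intensity reaches the activation threshold (`>=` convention).
#'
#' @param features one-row data.frame from [transient_features()].
#' @return logical.
#' @export
classify_activated <- function(features) isTRUE(features$activated)

#' Quantify a set of bare traces
#'
#' Convenience wrapper for trace-table input (no imaging): runs
#' [detect_onset()] and [transient_features()] on every cell of a long
#' table.
#'
#' @param traces data.frame with columns `cell_id`, `t_rel_s`, `F_IC`,
#'   `F_IB` and optionally `condition`.
#' @param config a [features_config()].
#' @return data.frame with one row per cell (see [transient_features()]),
#'   plus `condition` when present in the input.
#' @export
quantify_traces <- function(traces, config = features_config()) {
  need <- c("cell_id", "t_rel_s", "F_IC", "F_IB")
  if (!all(need %in% names(traces))) {
    stop_caflow(paste("`traces` must contain columns:", paste(need, collapse = ", ")),
                "caflow_parameter_error")
  }
  has_cond <- "condition" %in% names(traces)
  parts <- split(traces, traces$cell_id)
  rows <- lapply(parts, function(d) {
    tr <- calcium_trace(d$t_rel_s, d$F_IC, d$F_IB, track_id = d$cell_id[1])
    ft <- transient_features(tr, config = config)
    if (has_cond) ft$condition <- d$condition[1]
    ft
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
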