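#' Condition designs for synthetic cohorts
#'
#' Each design is a list of per-condition transient-parameter distributions.
#' Delay time, peak time, peak intensity and plateau level are drawn from
#' lognormal distributions (median + log-scale SD), truncated away from
#' degenerate values; a fraction `p_nonactivated` of cells stays flat.  The
#' built-in designs encode the qualitative effect directions of the assay:
#'
#' * `cohort_design_shear()`: wall shear stresses 0.15 / 0.30 / 0.60 dyn/cm²;
#'   higher shear shortens the delay and peak times and raises the peak
#'   intensity.
#' * `cohort_design_concentration()`: ligand densities 2 / 20 µg/mL; higher
#'   density sharply shortens the delay, slightly shortens the peak time and
#'   slightly raises the peak intensity.
#' * `cohort_design_inhibitor()`: DMSO vehicle vs the ER-channel inhibitor
#'   (no effect) vs the membrane-channel inhibitor (longer delay and peak
#'   time, weaker peak intensity).
#' * `cohort_design_knockdown()`: wild type vs adaptor knockdown (longer
#'   delay and peak time, weaker peak intensity).
#' * `cohort_design_null(n_groups)`: identical distributions in every group,
#'   for calibration studies.
#'
#' Distribution medians and spreads are generator choices (the assay's
#' published per-condition values are graphical only); they are fixed here
#' and documented in the package vignette.
#'
#' @param n_groups number of identical groups in the null design.
#' @param scale `"standard"` (delay tens of seconds, as in the assay) or
#'   `"fast"` (shorter transients for large simulation studies).
#' @return A named list of per-condition parameter lists (class
#'   `cohort_design`); names are the condition labels.
#' @name cohort_designs
NULL

#' @noRd
default_effects <- function() {
  list(T_D_med = 40, T_D_sdlog = 0.30, T_D_min = 5,
       T_P_med = 20, T_P_sdlog = 0.25, T_P_min = 2,
       I_P_med = 3.0, I_P_sdlog = 0.15, I_P_min = 1.6,
       plateau_med = 300, plateau_sdlog = 0.10,
       tau_s = 60, p_nonactivated = 0.2, background = 100)
}

#' @noRd
make_design <- function(per_condition) {
  structure(lapply(per_condition, function(x) {
    utils::modifyList(default_effects(), x)
  }), class = "cohort_design")
}

#' @rdname cohort_designs
#' @export
cohort_design_shear <- function() {
  make_design(list(
    "0.15" = list(T_D_med = 60, T_P_med = 30, I_P_med = 2.2),
    "0.30" = list(T_D_med = 40, T_P_med = 20, I_P_med = 3.0),
    "0.60" = list(T_D_med = 25, T_P_med = 12, I_P_med = 4.0)
  ))
}

#' @rdname cohort_designs
#' @export
cohort_design_concentration <- function() {
  make_design(list(
    "2"  = list(T_D_med = 70, T_P_med = 24, I_P_med = 2.7),
    "20" = list(T_D_med = 35, T_P_med = 20, I_P_med = 3.0)
  ))
}

#' @rdname cohort_designs
#' @export
cohort_design_inhibitor <- function() {
  make_design(list(
    DMSO    = list(),
    "2-APB" = list(),
    LaCl3   = list(T_D_med = 70, T_P_med = 32, I_P_med = 2.0)
  ))
}

#' @rdname cohort_designs
#' @export
cohort_design_knockdown <- function() {
  make_design(list(
    WT          = list(),
    shKindlin3  = list(T_D_med = 60, T_P_med = 30, I_P_med = 2.2)
  ))
}

#' @rdname cohort_designs
#' @export
cohort_design_null <- function(n_groups = 2, scale = c("standard", "fast")) {
  scale <- match.arg(scale)
  base <- if (scale == "fast") {
    list(T_D_med = 10, T_D_sdlog = 0.30, T_D_min = 3,
         T_P_med = 5, T_P_sdlog = 0.25, T_P_min = 1.5,
         tau_s = 15, p_nonactivated = 0)
  } else list(p_nonactivated = 0)
  d <- stats::setNames(rep(list(base), n_groups),
                       paste0("group", seq_len(n_groups)))
  make_design(d)
}

## draw per-cell transient parameters for one condition
#' @noRd
draw_params <- function(eff, n) {
  act <- stats::runif(n) >= eff$p_nonactivated
  data.frame(
    T_D = pmax(stats::rlnorm(n, log(eff$T_D_med), eff$T_D_sdlog), eff$T_D_min),
    T_P = pmax(stats::rlnorm(n, log(eff$T_P_med), eff$T_P_sdlog), eff$T_P_min),
    I_P = ifelse(act,
                 pmax(stats::rlnorm(n, log(eff$I_P_med), eff$I_P_sdlog), eff$I_P_min),
                 1),
    plateau = stats::rlnorm(n, log(eff$plateau_med), eff$plateau_sdlog),
    tau = rep(eff$tau_s, n),
    activated = act
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-cell transient parameters from a [cohort_designs] design and
#' produces either bare fluorescence traces (`mode = "traces"`) or fully
#' rendered image stacks (`mode = "stack"`), together with the ground truth
#' needed to score the analysis.
#'
#' In traces mode each cell yields an arrest-relative trace (`t_rel_s` from
#' 0): `F_IC` is the sampled transient plus per-frame Gaussian noise, `F_IB`
#' the constant background.  The noise SD of an activated cell is its
#' noiseless peak rise amplitude divided by `snr` (`snr = Inf` gives
#' noiseless traces); non-activated cells receive the noise of the
#' condition's median amplitude.
#'
#' In stack mode the cells of each condition are placed on a jittered grid,
#' wide enough apart that detection and background domains do not collide,
#' and arrest at frame-aligned times drawn uniformly from
#' `[0, arrest_max_s]`; a cell enters the field (the imaging focal plane) at
#' its arrest time.  The recording is long enough to cover every cell's
#' transient (`max(arrest + T_D + T_P) + tail_s`).
#'
#' @param design a [cohort_designs] design (or any named list of effect
#'   lists accepted by it).
#' @param n_per_condition cells per condition, `>= 1`.
#' @param mode `"traces"` or `"stack"`.
#' @param frame_rate_hz acquisition rate (default 20 fps, the calcium-assay
#'   rate).
#' @param snr peak signal-to-noise ratio (rise amplitude / per-frame noise
#'   SD); `Inf` for noiseless.
#' @param duration_s recording length; `NULL` sizes it automatically.
#' @param seed integer seed; the cohort is fully reproducible.
#' @param pixel_size_um,arrest_max_s,tail_s,radius_um,spacing_um stack-mode
#'   geometry.
#' @return A list of class `cohort`: `mode`, `ground_truth` (one row per
#'   cell: `cell_id`, `condition`, `arrest_time_s`, `T_D_s`, `T_P_s`, `I_P`,
#'   `activated`, `plateau`, `noise_sd`), and either `traces` (long
#'   data.frame `cell_id`, `condition`, `t_rel_s`, `F_IC`, `F_IB`) or
#'   `stacks` (named list per condition of [render_stack()] results).
#' @export
generate_cohort <- function(design, n_per_condition = 20,
                            mode = c("traces", "stack"),
                            frame_rate_hz = 20, snr = 10, duration_s = NULL,
                            seed = 1L, pixel_size_um = 2, arrest_max_s = 2,
                            tail_s = 20, radius_um = 7.5, spacing_um = 40) {
  mode <- match.arg(mode)
  if (!is.list(design) || is.null(names(design)) || any(names(design) == "")) {
    stop_caflow("`design` must be a named list of per-condition effect lists",
                "caflow_config_error")
  }
  if (!is.numeric(n_per_condition) || n_per_condition < 1) {
    stop_caflow("`n_per_condition` must be >= 1", "caflow_config_error")
  }
  n_per_condition <- as.integer(n_per_condition)
  assert_scalar_num(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  if (!(is.numeric(snr) && length(snr) == 1L && (is.infinite(snr) || snr > 0))) {
    stop_caflow("`snr` must be a positive number or Inf", "caflow_config_error")
  }
  design <- make_design(design)
  conds <- names(design)
  dt <- 1 / frame_rate_hz

  set.seed(as.integer(seed))
  gt <- list(); traces <- list(); stacks <- list()
  cell_counter <- 0L
  for (ci in seq_along(conds)) {
    eff <- design[[ci]]
    pp <- draw_params(eff, n_per_condition)
    pp$cell_id <- cell_counter + seq_len(n_per_condition)
    cell_counter <- cell_counter + n_per_condition
    amp <- pp$plateau * (pp$I_P - 1)
    med_amp <- eff$plateau_med * (eff$I_P_med - 1)
    noise_sd <- if (is.infinite(snr)) rep(0, nrow(pp)) else
      ifelse(pp$activated, amp, med_amp) / snr

    if (mode == "traces") {
      dur <- duration_s %||% (max(pp$T_D + pp$T_P) + tail_s)
      arrest <- rep(0, nrow(pp))
      tr <- lapply(seq_len(nrow(pp)), function(i) {
        par <- transient_params(pp$plateau[i], pp$T_D[i], pp$T_P[i],
                                pp$I_P[i], pp$tau[i],
                                activated = pp$activated[i])
        s <- simulate_trace(par, dt, dur, noise_sd = noise_sd[i])
        data.frame(cell_id = pp$cell_id[i], condition = conds[ci],
                   t_rel_s = s$t_s, F_IC = s$intensity,
                   F_IB = eff$background)
      })
      traces[[ci]] <- do.call(rbind, tr)
    } else {
      arrest <- round(stats::runif(nrow(pp), 0, arrest_max_s) / dt) * dt
      dur <- duration_s %||% (max(arrest + pp$T_D + pp$T_P) + tail_s)
      ncol_g <- ceiling(sqrt(nrow(pp)))
      nrow_g <- ceiling(nrow(pp) / ncol_g)
      margin <- 32
      gx <- margin + ((seq_len(nrow(pp)) - 1L) %% ncol_g) * spacing_um
      gy <- margin + ((seq_len(nrow(pp)) - 1L) %/% ncol_g) * spacing_um
      gx <- gx + stats::runif(nrow(pp), -2, 2)
      gy <- gy + stats::runif(nrow(pp), -2, 2)
      W_um <- 2 * margin + (ncol_g - 1) * spacing_um
      H_um <- 2 * margin + (nrow_g - 1) * spacing_um
      cells <- data.frame(
        cell_id = pp$cell_id, x0_um = gx, y0_um = gy,
        vx_um_s = 0, vy_um_s = 0, entry_s = arrest, arrest_s = arrest,
        radius_um = radius_um, plateau = pp$plateau, T_D = pp$T_D,
        T_P = pp$T_P, I_P = pp$I_P, tau = pp$tau, activated = pp$activated)
      scene <- scene_spec(
        width_px = ceiling(W_um / pixel_size_um),
        height_px = ceiling(H_um / pixel_size_um),
        pixel_size_um = pixel_size_um, frame_interval_s = dt,
        duration_s = dur, cells = cells, background_level = eff$background,
        noise_sd = if (is.infinite(snr)) 0 else stats::median(noise_sd),
        seed = sample.int(.Machine$integer.max, 1L))
      stacks[[conds[ci]]] <- render_stack(scene)
    }
    gt[[ci]] <- data.frame(
      cell_id = pp$cell_id, condition = conds[ci], arrest_time_s = arrest,
      T_D_s = ifelse(pp$activated, pp$T_D, NA_real_),
      T_P_s = ifelse(pp$activated, pp$T_P, NA_real_),
      I_P = ifelse(pp$activated, pp$I_P, NA_real_),
      activated = pp$activated, plateau = pp$plateau, noise_sd = noise_sd)
  }
  structure(list(
    mode = mode,
    conditions = conds,
    ground_truth = do.call(rbind, gt),
    traces = if (mode == "traces") do.call(rbind, traces) else NULL,
    stacks = if (mode == "stack") stacks else NULL
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s mode, %d conditions, %d cells (%d activated)\n",
              x$mode, length(x$conditions), nrow(x$ground_truth),
              sum(x$ground_truth$activated)))
  invisible(x)
}
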