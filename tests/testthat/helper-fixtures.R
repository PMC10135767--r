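## shared fixture builders and independent oracles

## brute-force firm-adhesion oracle: enumerate every window start, walk the
## window end forward explicitly, compare endpoint displacement against the
## threshold.  Written independently of classify_firm_adhesion().
oracle_firm <- function(track, window_s = 60, threshold_um = 10) {
  t <- track$t_s
  n <- length(t)
  if (n < 2 || t[n] - t[1] < window_s) {
    return(list(firm = FALSE, onset = NA_real_))
  }
  for (i in seq_len(n)) {
    if (t[i] + window_s > t[n] + 1e-9 * window_s) break
    j <- i
    while (j < n && t[j + 1] <= t[i] + window_s + 1e-9 * window_s) j <- j + 1
    disp <- sqrt((track$x_um[j] - track$x_um[i])^2 +
                 (track$y_um[j] - track$y_um[i])^2)
    if (disp < threshold_um) {
      return(list(firm = TRUE, onset = t[i]))
    }
  }
  list(firm = FALSE, onset = NA_real_)
}

## seeded 2D random-walk track with per-step SD `step_um` (µm)
random_walk_track <- function(n, dt = 1, step_um = 1, x0 = 0, y0 = 0) {
  data.frame(
    track_id = 1L,
    t_s = (seq_len(n) - 1) * dt,
    x_um = x0 + cumsum(c(0, rnorm(n - 1, sd = step_um))),
    y_um = y0 + cumsum(c(0, rnorm(n - 1, sd = step_um)))
  )
}

## single-cell scene builder
one_cell_scene <- function(x0 = 64, y0 = 96, vx = 0, vy = 0, entry = 0,
                           arrest = 0, plateau = 300, T_D = 10, T_P = 5,
                           I_P = 3, tau = 30, activated = TRUE,
                           duration = 30, noise_sd = 0, dt = 0.1,
                           width_px = 100, height_px = 100,
                           pixel_size_um = 2, seed = 1, ...) {
  cells <- data.frame(cell_id = 1L, x0_um = x0, y0_um = y0, vx_um_s = vx,
                      vy_um_s = vy, entry_s = entry, arrest_s = arrest,
                      radius_um = 7.5, plateau = plateau, T_D = T_D,
                      T_P = T_P, I_P = I_P, tau = tau, activated = activated)
  scene_spec(width_px, height_px, pixel_size_um, dt, duration, cells,
             noise_sd = noise_sd, seed = seed, ...)
}

## synthetic noiseless trace table for quantify_traces-style input
trace_df <- function(plateau = 300, T_D = 40, T_P = 20, I_P = 3, tau = 60,
                     bg = 100, dt = 0.05, duration = T_D + T_P + 30,
                     noise_sd = 0, seed = NULL, activated = TRUE,
                     cell_id = 1L) {
  p <- transient_params(plateau, T_D, T_P, I_P, tau, activated = activated)
  s <- simulate_trace(p, dt, duration, noise_sd = noise_sd, seed = seed)
  data.frame(cell_id = cell_id, t_rel_s = s$t_s, F_IC = s$intensity, F_IB = bg)
}
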