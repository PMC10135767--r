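#' Ground-truth parameters of a single-cell calcium transient
#'
#' A cell firmly arrested on the substrate shows a fluorescence time course
#' with a low plateau, a latent delay, a swift rise to a peak and a gradual
#' relaxation back to the original level.  `transient_params()` bundles the
#' generator's ground-truth description of that curve:
#'
#' * `plateau_level`: resting mean cell fluorescence (a.u.), background
#'   included, i.e. the value an observer would measure over the cell mask
#'   before the burst;
#' * `delay_T_D`: delay time (s) between arrest onset and the start of the
#'   rise;
#' * `rise_T_P`: peak time (s), the duration of the rise from plateau to peak;
#' * `peak_ratio_I_P`: peak calcium intensity, the dimensionless ratio of the
#'   peak fluorescence to the plateau fluorescence (`>= 1`; `1` for a
#'   non-activated, flat trace);
#' * `decay_tau`: time constant (s) of the exponential relaxation after the
#'   peak;
#' * `activated`: logical; non-activated cells stay at the plateau throughout.
#'
#' @param plateau_level resting fluorescence level, a.u., `> 0`.
#' @param delay_T_D delay time in seconds, `>= 0`.
#' @param rise_T_P rise (peak) time in seconds, `> 0`.
#' @param peak_ratio_I_P peak/plateau intensity ratio, `>= 1`.
#' @param decay_tau decay time constant in seconds, `> 0`.
#' @param activated logical.
#'
#' @return An object of class `transient_params`.
#' @examples
#' transient_params(100, 40, 20, 3, 60)
#' @export
transient_params <- function(plateau_level, delay_T_D = 0, rise_T_P = 1,
                             peak_ratio_I_P = 1, decay_tau = 60,
                             activated = peak_ratio_I_P > 1) {
  assert_scalar_num(plateau_level, "plateau_level", positive = TRUE)
  assert_scalar_num(delay_T_D, "delay_T_D", nonneg = TRUE)
  assert_scalar_num(rise_T_P, "rise_T_P", positive = TRUE)
  assert_scalar_num(peak_ratio_I_P, "peak_ratio_I_P")
  assert_scalar_num(decay_tau, "decay_tau", positive = TRUE)
  if (peak_ratio_I_P < 1) {
    stop_caflow("`peak_ratio_I_P` must be >= 1 (1 means a flat, non-activated trace)",
                "caflow_parameter_error")
  }
  if (!is.logical(activated) || length(activated) != 1L || is.na(activated)) {
    stop_caflow("`activated` must be TRUE or FALSE", "caflow_parameter_error")
  }
  structure(
    list(plateau_level = plateau_level, delay_T_D = delay_T_D,
         rise_T_P = rise_T_P, peak_ratio_I_P = peak_ratio_I_P,
         decay_tau = decay_tau, activated = activated),
    class = "transient_params"
  )
}

#' @export
print.transient_params <- function(x, ...) {
  cat(sprintf(
    "<transient_params> %s: plateau %.4g a.u., T_D %.4g s, T_P %.4g s, I_P %.4g, tau %.4g s\n",
    if (x$activated) "activated" else "non-activated",
    x$plateau_level, x$delay_T_D, x$rise_T_P, x$peak_ratio_I_P, x$decay_tau))
  invisible(x)
}

## noiseless transient value at arbitrary times (t relative to arrest onset).
## Piecewise: plateau for t < T_D; rise over [T_D, T_D + T_P] reaching
## plateau * I_P; exponential relaxation toward the plateau afterwards.
## rise_shape "linear" is the default; "sigmoid" uses the smoothstep
## polynomial 3u^2 - 2u^3 so the peak is still reached exactly at T_D + T_P.
#' @noRd
transient_value <- function(params, t, rise_shape = c("linear", "sigmoid")) {
  rise_shape <- match.arg(rise_shape)
  L <- params$plateau_level
  if (!params$activated || params$peak_ratio_I_P == 1) {
    return(rep(L, length(t)))
  }
  A <- L * (params$peak_ratio_I_P - 1)   # rise amplitude above plateau
  t0 <- params$delay_T_D
  t1 <- t0 + params$rise_T_P
  u <- (t - t0) / params$rise_T_P
  rise <- if (rise_shape == "linear") u else u * u * (3 - 2 * u)
  val <- rep(L, length(t))
  on_rise <- t >= t0 & t <= t1
  val[on_rise] <- L + A * rise[on_rise]
  after <- t > t1
  val[after] <- L + A * exp(-(t[after] - t1) / params$decay_tau)
  val
}

#' Simulate a single-cell fluorescence trace
#'
#' Samples the noiseless transient described by a [transient_params()] object
#' on a regular time grid and adds optional Gaussian measurement noise.
#' Time is measured from arrest onset (`t = 0` at the first sample).
#'
#' With zero noise the maximum of an activated trace equals
#' `plateau_level * peak_ratio_I_P` exactly, reached at `delay_T_D + rise_T_P`;
#' afterwards the trace relaxes as
#' `plateau + plateau * (I_P - 1) * exp(-(t - T_D - T_P)/decay_tau)`.
#'
#' @param params a [transient_params()] object.
#' @param frame_interval sampling interval in seconds, `> 0`.
#' @param duration total duration in seconds; must exceed
#'   `delay_T_D + rise_T_P` for an activated cell.
#' @param noise_sd standard deviation of additive Gaussian noise, a.u.
#' @param seed optional integer; when given the noise is reproducible and the
#'   caller's RNG state is left untouched.
#' @param rise_shape `"linear"` (default) or `"sigmoid"` (smoothstep).
#'
#' @return A data.frame with columns `t_s` (seconds from arrest onset) and
#'   `intensity` (a.u.).
#' @examples
#' tr <- simulate_trace(transient_params(100, 40, 20, 3, 60),
#'                      frame_interval = 0.05, duration = 120)
#' max(tr$intensity)  # 300 exactly
#' @export
simulate_trace <- function(params, frame_interval, duration, noise_sd = 0,
                           seed = NULL, rise_shape = c("linear", "sigmoid")) {
  if (!inherits(params, "transient_params")) {
    stop_caflow("`params` must be created with transient_params()",
                "caflow_parameter_error")
  }
  rise_shape <- match.arg(rise_shape)
  assert_scalar_num(frame_interval, "frame_interval", positive = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  if (params$activated && duration <= params$delay_T_D + params$rise_T_P) {
    stop_caflow("`duration` must exceed delay_T_D + rise_T_P for an activated cell",
                "caflow_parameter_error")
  }
  t <- seq(0, duration, by = frame_interval)
  y <- transient_value(params, t, rise_shape)
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(t), sd = noise_sd))
    y <- y + noise
  }
  data.frame(t_s = t, intensity = y)
}

## run `expr` under a temporary seed (NULL = use current RNG stream)
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
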