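#' Declarative specification of a synthetic flow-chamber scene
#'
#' Describes a field of cells under flow as seen by the camera: some cells
#' translate across the field (rolling/sliding) and never arrest, others
#' arrest and — if activated — fire a calcium transient.  The scene is the
#' generator's contract with the analysis: rendering it yields an
#' [image_stack()] together with the exact ground truth (per-frame centroids,
#' arrest times, transient parameters), so every downstream stage can be
#' scored without any real recording.
#'
#' `cells` is a data.frame with one row per cell and columns:
#' `cell_id`, `x0_um`, `y0_um` (position at entry), `vx_um_s`, `vy_um_s`
#' (pre-arrest velocity), `entry_s`, `arrest_s` (`NA` = never arrests),
#' `radius_um`, `plateau`, `T_D`, `T_P`, `I_P`, `tau`, `activated`.
#' Transient time parameters are relative to `arrest_s`.
#'
#' Cells are rendered as radially symmetric disks whose mask-mean intensity
#' follows the cell's ground-truth trace exactly (see [render_stack()]).
#'
#' @param width_px,height_px field size in pixels.
#' @param pixel_size_um µm per pixel.
#' @param frame_interval_s seconds between frames.
#' @param duration_s total recorded time (first frame at t = 0).
#' @param cells cell table, see Details.
#' @param background_level uniform background intensity, a.u.
#' @param noise_sd per-pixel additive Gaussian noise SD, a.u.
#' @param poisson logical; apply Poisson shot noise to pixel values.
#' @param profile radial intensity profile: `"gaussian"` (sd = radius/2,
#'   truncated at the radius) or `"flat"` (top-hat disk).
#' @param rise_shape rise shape passed to the transient model.
#' @param seed integer RNG seed for rendering noise.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_px, height_px, pixel_size_um, frame_interval_s,
                       duration_s, cells, background_level = 100,
                       noise_sd = 0, poisson = FALSE,
                       profile = c("gaussian", "flat"),
                       rise_shape = c("linear", "sigmoid"), seed = 1L) {
  profile <- match.arg(profile)
  rise_shape <- match.arg(rise_shape)
  assert_scalar_num(width_px, "width_px", positive = TRUE)
  assert_scalar_num(height_px, "height_px", positive = TRUE)
  assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  assert_scalar_num(frame_interval_s, "frame_interval_s", positive = TRUE)
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  assert_scalar_num(background_level, "background_level", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  need <- c("cell_id", "x0_um", "y0_um", "vx_um_s", "vy_um_s", "entry_s",
            "arrest_s", "radius_um", "plateau", "T_D", "T_P", "I_P", "tau",
            "activated")
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    stop_caflow(paste("`cells` must contain columns:", paste(need, collapse = ", ")),
                "caflow_parameter_error")
  }
  if (anyDuplicated(cells$cell_id)) {
    stop_caflow("`cells$cell_id` must be unique", "caflow_parameter_error")
  }
  arr <- !is.na(cells$arrest_s)
  if (any(arr & (cells$arrest_s < 0 | cells$arrest_s > duration_s))) {
    stop_caflow("arrest times must lie within [0, duration_s]",
                "caflow_parameter_error")
  }
  need_t <- cells$arrest_s + cells$T_D + cells$T_P
  bad <- arr & cells$activated & need_t >= duration_s
  if (any(bad)) {
    stop_caflow(sprintf(
      "duration_s (%g) must exceed arrest + T_D + T_P for every activated cell (max needed %g)",
      duration_s, max(need_t[arr & cells$activated])), "caflow_parameter_error")
  }
  ## cells whose disk never intersects the field are a spec error; cells that
  ## travel out of the field are allowed but flagged as edge-exiting
  W <- width_px * pixel_size_um; H <- height_px * pixel_size_um
  inside <- function(x, y, r) x + r > 0 & x - r < W & y + r > 0 & y - r < H
  ever_in <- inside(cells$x0_um, cells$y0_um, cells$radius_um)
  if (any(!ever_in)) {
    stop_caflow(sprintf("cell(s) %s lie entirely outside the field at entry",
                        paste(cells$cell_id[!ever_in], collapse = ", ")),
                "caflow_parameter_error")
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
         duration_s = duration_s, cells = cells,
         background_level = background_level, noise_sd = noise_sd,
         poisson = isTRUE(poisson), profile = profile,
         rise_shape = rise_shape, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

## pixel set of a disk: linear indices into a height x width matrix of all
## pixels whose center lies within `radius_um` of (cx, cy), plus the radial
## weight profile used for rendering
#' @noRd
disk_pixels <- function(cx_um, cy_um, radius_um, pixel_size_um,
                        height_px, width_px, profile = "flat") {
  p <- pixel_size_um
  cmin <- max(1L, ceiling(cx_um / p - radius_um / p))
  cmax <- min(width_px, floor(cx_um / p + radius_um / p + 1))
  rmin <- max(1L, ceiling(cy_um / p - radius_um / p))
  rmax <- min(height_px, floor(cy_um / p + radius_um / p + 1))
  if (cmin > cmax || rmin > rmax) {
    return(list(idx = integer(0), w = numeric(0)))
  }
  cols <- cmin:cmax; rows <- rmin:rmax
  xs <- (cols - 0.5) * p; ys <- (rows - 0.5) * p
  d2 <- outer((ys - cy_um)^2, (xs - cx_um)^2, `+`)
  keep <- d2 <= radius_um^2
  if (!any(keep)) return(list(idx = integer(0), w = numeric(0)))
  idx <- outer(rows, (cols - 1L) * height_px, `+`)[keep]
  w <- if (profile == "gaussian") {
    sigma <- radius_um / 2
    exp(-d2[keep] / (2 * sigma^2))
  } else rep(1, sum(keep))
  list(idx = idx, w = w)
}

## position of each cell at time t (matrix of x, y in um) and whether it is
## rendered at all (entered the field, not exited)
#' @noRd
cell_state_at <- function(cells, t) {
  entered <- t >= cells$entry_s
  t_move <- pmin(t, ifelse(is.na(cells$arrest_s), t, cells$arrest_s))
  dt <- pmax(t_move - cells$entry_s, 0)
  data.frame(
    x_um = cells$x0_um + cells$vx_um_s * dt,
    y_um = cells$y0_um + cells$vy_um_s * dt,
    entered = entered,
    arrested = entered & !is.na(cells$arrest_s) & t >= cells$arrest_s
  )
}

#' Render a synthetic scene into an image stack with ground truth
#'
#' Each cell is drawn as a radially symmetric disk (Gaussian profile by
#' default) added on top of the uniform background.  The profile is scaled
#' per frame so that the mean intensity over the cell's pixel set equals the
#' cell's ground-truth raw fluorescence trace: the plateau level before and
#' during the delay, the transient model of [simulate_trace()] after arrest.
#' Translating cells move at their stated velocity until arrest and are
#' clipped (and flagged `edge_exit`) if they leave the field.  Rendering is
#' bit-reproducible for a fixed scene (the scene's `seed` drives all noise).
#'
#' @param scene a [scene_spec()].
#' @return A list with components `stack` (an [image_stack()]) and
#'   `ground_truth`: a list with `cells` (one row per cell: `cell_id`,
#'   `arrest_time_s`, `T_D_s`, `T_P_s`, `I_P`, `activated`, `plateau`,
#'   `edge_exit`) and `centroids` (`cell_id`, `frame`, `t_s`, `x_um`,
#'   `y_um` for every rendered cell-frame).
#' @export
render_stack <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  cells <- scene$cells
  H <- scene$height_px; W <- scene$width_px
  p <- scene$pixel_size_um
  times <- seq(0, scene$duration_s, by = scene$frame_interval_s)
  nf <- length(times)
  nc <- nrow(cells)

  params <- lapply(seq_len(nc), function(i) {
    transient_params(cells$plateau[i], cells$T_D[i], cells$T_P[i],
                     cells$I_P[i], cells$tau[i],
                     activated = isTRUE(cells$activated[i]))
  })

  frames <- vector("list", nf)
  cent <- vector("list", nf)
  edge_exit <- rep(FALSE, nc)
  W_um <- W * p; H_um <- H * p

  set.seed(scene$seed)
  for (j in seq_len(nf)) {
    t <- times[j]
    f <- matrix(scene$background_level, H, W)
    st <- cell_state_at(cells, t)
    vis <- st$entered &
      st$x_um + cells$radius_um > 0 & st$x_um - cells$radius_um < W_um &
      st$y_um + cells$radius_um > 0 & st$y_um - cells$radius_um < H_um
    edge_exit <- edge_exit | (st$entered & !vis)
    for (i in which(vis)) {
      val <- if (st$arrested[i]) {
        transient_value(params[[i]], t - cells$arrest_s[i], scene$rise_shape)
      } else cells$plateau[i]
      excess <- val - scene$background_level
      dp <- disk_pixels(st$x_um[i], st$y_um[i], cells$radius_um[i], p, H, W,
                        scene$profile)
      if (length(dp$idx)) {
        f[dp$idx] <- f[dp$idx] + excess * dp$w / mean(dp$w)
      }
    }
    if (scene$noise_sd > 0) f <- f + matrix(stats::rnorm(H * W, sd = scene$noise_sd), H, W)
    if (scene$poisson) f <- matrix(stats::rpois(H * W, pmax(f, 0)), H, W)
    frames[[j]] <- f
    if (any(vis)) {
      cent[[j]] <- data.frame(cell_id = cells$cell_id[vis], frame = j,
                              t_s = t, x_um = st$x_um[vis], y_um = st$y_um[vis])
    }
  }

  gt_cells <- data.frame(
    cell_id = cells$cell_id,
    arrest_time_s = cells$arrest_s,
    T_D_s = ifelse(cells$activated, cells$T_D, NA_real_),
    T_P_s = ifelse(cells$activated, cells$T_P, NA_real_),
    I_P = ifelse(cells$activated, cells$I_P, NA_real_),
    activated = cells$activated,
    plateau = cells$plateau,
    edge_exit = edge_exit
  )
  list(
    stack = image_stack(frames, p, scene$frame_interval_s),
    ground_truth = list(cells = gt_cells, centroids = do.call(rbind, cent))
  )
}
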