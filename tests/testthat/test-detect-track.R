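test_that("detector finds a single noiseless spot at its true centroid", {
  sc <- one_cell_scene(x0 = 32, y0 = 48, activated = FALSE, duration = 0.5,
                       dt = 0.5, width_px = 60, height_px = 60)
  st <- render_stack(sc)$stack
  det <- detect_cells(st$frames[[1]], st$pixel_size_um)
  expect_equal(nrow(det$centroids), 1L)
  expect_lt(abs(det$centroids$x_um - 32), 0.5 * st$pixel_size_um)
  expect_lt(abs(det$centroids$y_um - 48), 0.5 * st$pixel_size_um)
  ## the mask covers the rendered disk area
  expect_gt(det$centroids$area_um2, 0.8 * pi * 7.5^2)
})

test_that("pure background yields no detections", {
  f <- matrix(100, 50, 50)
  det <- detect_cells(f, 2)
  expect_equal(nrow(det$centroids), 0L)
  f2 <- f + matrix(rnorm(2500, sd = 3), 50, 50)
  det2 <- detect_cells(f2, 2)
  expect_equal(nrow(det2$centroids), 0L)
})

test_that("two well-separated spots are both found and paired to truth", {
  cells <- data.frame(cell_id = 1:2, x0_um = c(40, 120), y0_um = c(50, 90),
                      vx_um_s = 0, vy_um_s = 0, entry_s = 0, arrest_s = 0,
                      radius_um = 7.5, plateau = c(250, 400), T_D = 5,
                      T_P = 3, I_P = 1, tau = 20, activated = FALSE)
  sc <- scene_spec(90, 70, 2, 0.5, 1, cells)
  st <- render_stack(sc)$stack
  det <- detect_cells(st$frames[[1]], 2)
  expect_equal(nrow(det$centroids), 2L)
  ord <- order(det$centroids$x_um)
  expect_lt(abs(det$centroids$x_um[ord[1]] - 40), 1)
  expect_lt(abs(det$centroids$x_um[ord[2]] - 120), 1)
  expect_lt(abs(det$centroids$y_um[ord[1]] - 50), 1)
  expect_lt(abs(det$centroids$y_um[ord[2]] - 90), 1)
})

test_that("a frame with non-finite values is rejected", {
  f <- matrix(100, 20, 20); f[5, 5] <- NA
  expect_error(detect_cells(f, 2), class = "caflow_parameter_error")
})

test_that("a single moving cell links into one track; two stationary cells never swap", {
  ## moving cell: 1 µm per frame
  dets <- lapply(0:20, function(i) {
    data.frame(x_um = 10 + i, y_um = 25)
  })
  trk <- link_tracks(dets, frame_interval_s = 0.5, max_step_um = 5)
  expect_equal(trk$qc$n_tracks, 1L)
  expect_equal(nrow(trk$tracks), 21L)
  expect_equal(trk$tracks$x_um, 10 + 0:20)

  ## two stationary cells with small jitter
  set.seed(5)
  dets2 <- lapply(1:40, function(i) {
    data.frame(x_um = c(10, 60) + rnorm(2, sd = 0.2),
               y_um = c(20, 20) + rnorm(2, sd = 0.2))
  })
  trk2 <- link_tracks(dets2, 0.5, max_step_um = 5)
  expect_equal(trk2$qc$n_tracks, 2L)
  per <- split_tracks(trk2)
  for (d in per) {
    expect_lt(max(d$x_um) - min(d$x_um), 2)  # no identity swap
  }
})

test_that("tracks closed after max_gap and reopened as new ids", {
  dets <- lapply(1:10, function(i) {
    if (i %in% 4:7) data.frame(x_um = numeric(0), y_um = numeric(0))
    else data.frame(x_um = 30, y_um = 30)
  })
  trk <- link_tracks(dets, 1, max_step_um = 5, max_gap = 2)
  expect_equal(trk$qc$n_tracks, 2L)
})

test_that("cohort-scale tracking recovers ground-truth assignments", {
  ## 30-cell rendered scene at generator default density, mild noise,
  ## including translating cells that arrest mid-recording
  set.seed(77)
  n <- 30
  gx <- 40 + ((seq_len(n) - 1) %% 6) * 40
  gy <- 40 + ((seq_len(n) - 1) %/% 6) * 40
  mover <- rep(c(TRUE, FALSE), length.out = n)
  cells <- data.frame(
    cell_id = seq_len(n),
    x0_um = ifelse(mover, gx - 15, gx), y0_um = gy,
    vx_um_s = ifelse(mover, 3, 0), vy_um_s = 0,
    entry_s = 0, arrest_s = ifelse(mover, 5, 0),
    radius_um = 7.5, plateau = runif(n, 250, 350),
    T_D = 3, T_P = 2, I_P = 1, tau = 20, activated = FALSE)
  sc <- scene_spec(140, 120, 2, 0.25, 10, cells, noise_sd = 5, seed = 12)
  out <- render_stack(sc)
  trk <- track_stack(out$stack, max_step_um = 6)
  cen <- out$ground_truth$centroids

  ## score (cell, frame) recovery: a ground-truth entry is recovered when a
  ## track detection lies within 3 µm at that frame, with a consistent
  ## track <-> cell majority mapping
  tt <- trk$tracks
  hits <- 0L
  map <- list()
  for (k in seq_len(nrow(cen))) {
    cand <- tt[tt$frame == cen$frame[k], ]
    d <- sqrt((cand$x_um - cen$x_um[k])^2 + (cand$y_um - cen$y_um[k])^2)
    if (length(d) && min(d) < 3) {
      map[[length(map) + 1L]] <- data.frame(cell = cen$cell_id[k],
                                            track = cand$track_id[which.min(d)])
      hits <- hits + 1L
    }
  }
  expect_gte(hits / nrow(cen), 0.95)
  ## the track <-> cell mapping is one-to-one (no switches)
  mp <- do.call(rbind, map)
  tab <- table(mp$cell, mp$track)
  expect_true(all(rowSums(tab > 0) == 1))
})
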