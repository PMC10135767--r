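test_that("stationary track is firm with onset at track start", {
  tr <- data.frame(track_id = 1, t_s = 0:120, x_um = 50, y_um = 50)
  ev <- classify_firm_adhesion(tr)
  expect_true(ev$firm)
  expect_equal(ev$onset_time_s, 0)
  expect_false(ev$insufficient_span)
})

test_that("track translating at 1 um/s is not firm (60 um per window)", {
  tr <- data.frame(track_id = 1, t_s = 0:180, x_um = 0:180, y_um = 0)
  ev <- classify_firm_adhesion(tr)
  expect_false(ev$firm)
})

test_that("displacement of exactly 10 um in every window is not firm (strict <)", {
  ## samples every 60 s: each full window's endpoint displacement is 10.0
  tr <- data.frame(track_id = 1, t_s = c(0, 60, 120, 180),
                   x_um = c(0, 10, 20, 30), y_um = 0)
  ev <- classify_firm_adhesion(tr)
  expect_false(ev$firm)
  ## a hair under the threshold qualifies
  tr2 <- tr; tr2$x_um <- c(0, 10 - 1e-9, 20, 30)
  expect_true(classify_firm_adhesion(tr2)$firm)
})

test_that("track shorter than the window is flagged insufficient span", {
  tr <- data.frame(track_id = 1, t_s = 0:30, x_um = 0, y_um = 0)
  ev <- classify_firm_adhesion(tr)
  expect_false(ev$firm)
  expect_true(ev$insufficient_span)
})

test_that("classifier matches the exhaustive-window oracle on 200 random walks", {
  set.seed(2024)
  mismatches <- 0L
  for (r in 1:200) {
    step <- sample(c(0.05, 0.2, 0.5, 1, 1.5, 3), 1)
    n <- sample(70:200, 1)
    tr <- random_walk_track(n, dt = 1, step_um = step)
    got <- classify_firm_adhesion(tr)
    want <- oracle_firm(tr)
    if (!identical(got$firm, want$firm)) mismatches <- mismatches + 1L
    if (got$firm && !isTRUE(all.equal(got$onset_time_s, want$onset))) {
      mismatches <- mismatches + 1L
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("classifier matches the oracle on exact-threshold boundary tracks", {
  ## linear drift tuned so window displacements straddle 10 um exactly
  for (speed in c(10 / 60, 10 / 60 - 1e-6, 10 / 60 + 1e-6)) {
    tr <- data.frame(track_id = 1, t_s = 0:150, x_um = speed * (0:150), y_um = 0)
    got <- classify_firm_adhesion(tr)
    want <- oracle_firm(tr)
    expect_identical(got$firm, want$firm)
  }
})

test_that("path-length mode is never more permissive than net displacement", {
  set.seed(88)
  n_path <- 0L; n_net <- 0L; violations <- 0L
  for (r in 1:40) {
    tr <- random_walk_track(120, dt = 1, step_um = runif(1, 0.02, 0.4))
    net <- classify_firm_adhesion(tr, mode = "net")
    path <- classify_firm_adhesion(tr, mode = "path")
    n_net <- n_net + net$firm; n_path <- n_path + path$firm
    if (path$firm && !net$firm) violations <- violations + 1L
  }
  expect_identical(violations, 0L)
  ## the sample exercises both modes in both directions
  expect_gt(n_path, 0L)
  expect_gt(n_net, n_path)
})

test_that("inflating every step never turns a non-firm track firm", {
  set.seed(13)
  for (r in 1:30) {
    tr <- random_walk_track(100, dt = 1, step_um = runif(1, 0.2, 1))
    for (s in c(1.5, 3, 10)) {
      big <- tr
      big$x_um <- tr$x_um[1] + s * (tr$x_um - tr$x_um[1])
      big$y_um <- tr$y_um[1] + s * (tr$y_um - tr$y_um[1])
      if (!classify_firm_adhesion(tr)$firm) {
        expect_false(classify_firm_adhesion(big)$firm)
      }
    }
  }
})

test_that("the decision is invariant to resampling a noiseless track", {
  ## linear motion then full stop: refine the sampling 4-fold
  pos <- function(t) pmin(t, 30) * 0.8
  t1 <- seq(0, 150, by = 1)
  t2 <- seq(0, 150, by = 0.25)
  tr1 <- data.frame(track_id = 1, t_s = t1, x_um = pos(t1), y_um = 0)
  tr2 <- data.frame(track_id = 1, t_s = t2, x_um = pos(t2), y_um = 0)
  e1 <- classify_firm_adhesion(tr1)
  e2 <- classify_firm_adhesion(tr2)
  expect_identical(e1$firm, e2$firm)
  expect_equal(e1$onset_time_s, e2$onset_time_s, tolerance = 1)
})

test_that("firm-adherent count equals firm events with onset in the assay window", {
  set.seed(31)
  tracks <- list()
  for (i in 1:12) {   # arrested from the start
    tracks[[i]] <- data.frame(track_id = i, t_s = 0:500,
                              x_um = 10 * i + rnorm(501, sd = 0.3),
                              y_um = 10 + rnorm(501, sd = 0.3))
  }
  for (i in 13:20) {  # translating throughout
    tracks[[i]] <- data.frame(track_id = i, t_s = 0:500,
                              x_um = 0.9 * (0:500), y_um = 30 * i)
  }
  df <- do.call(rbind, tracks)
  ad <- classify_all_tracks(df)
  expect_equal(count_firm_adherent(ad, 420),
               sum(ad$firm & ad$onset_time_s <= 420))
  expect_equal(count_firm_adherent(ad, 420), 12L)
  ## no arrests
  ad0 <- ad[13:20, ]
  expect_equal(count_firm_adherent(ad0), 0L)
  ## late onset excluded: a cell stopping only after the assay window
  late <- data.frame(track_id = 99, t_s = 0:600,
                     x_um = pmin(0:600, 430) * 1, y_um = 0)
  evl <- classify_firm_adhesion(late)
  expect_true(evl$firm)
  expect_gt(evl$onset_time_s, 420)
  adl <- classify_all_tracks(late)
  expect_equal(count_firm_adherent(adl, 420), 0L)
})
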