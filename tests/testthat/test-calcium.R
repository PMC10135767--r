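test_that("background from four symmetric domains recovers constant and linear fields", {
  px <- 2
  f <- matrix(100, 60, 60)
  bg <- background_intensity(f, c(60, 60), px)
  expect_equal(bg$F_IB, 100)
  expect_equal(bg$n_domains, 4L)

  ## cell disk does not touch the domains: estimate still pure background
  f2 <- f
  dp <- caflow:::disk_pixels(60, 60, 7.5, px, 60, 60)
  f2[dp$idx] <- 500
  expect_equal(background_intensity(f2, c(60, 60), px)$F_IB, 100)

  ## linear gradient: symmetric placement averages to the centroid value
  cols <- matrix(rep(1:60, each = 60), 60, 60)
  rows <- matrix(rep(1:60, times = 60), 60, 60)
  g <- 50 + 1.5 * ((cols - 0.5) * px) + 0.75 * ((rows - 0.5) * px)
  bg_g <- background_intensity(g, c(60, 60), px)
  expect_equal(bg_g$F_IB, 50 + 1.5 * 60 + 0.75 * 60, tolerance = 1e-9)
})

test_that("domains blocked by other cells or the frame edge are dropped", {
  px <- 2
  f <- matrix(100, 60, 60)
  ## centroid near the left edge: the 180-degree domain falls outside
  bg <- background_intensity(f, c(26, 60), px)
  expect_equal(bg$n_domains, 3L)
  expect_true(bg$reliable)
  ## exclusion mask occupying two domains: 2 remain (still reliable)
  d1 <- caflow:::disk_pixels(60 + 24, 60, 6, px, 60, 60)$idx
  d2 <- caflow:::disk_pixels(60, 60 + 24, 6, px, 60, 60)$idx
  bg2 <- background_intensity(f, c(60, 60), px,
                              exclusion_masks = c(d1[1], d2[1]))
  expect_equal(bg2$n_domains, 2L)
  expect_true(bg2$reliable)
  ## three blocked: unreliable
  d3 <- caflow:::disk_pixels(60 - 24, 60, 6, px, 60, 60)$idx
  bg3 <- background_intensity(f, c(60, 60), px,
                              exclusion_masks = c(d1[1], d2[1], d3[1]))
  expect_false(bg3$reliable)
  expect_true(is.na(bg3$F_IB))
})

test_that("cell intensity is the arithmetic mask mean", {
  f <- matrix(0, 20, 20)
  idx <- 1:100
  f[idx] <- 300
  expect_equal(cell_intensity(f, idx), 300)
  f[idx[1:50]] <- 200; f[idx[51:100]] <- 400
  expect_equal(cell_intensity(f, idx), 300)
  expect_error(cell_intensity(f, integer(0)), class = "caflow_qc_error")
})

test_that("normalization follows (F_IC - F_IB)/F_IB and rejects bad backgrounds", {
  expect_equal(normalize_intensity(150, 150), 0)
  expect_equal(normalize_intensity(300, 150), 1)
  expect_error(normalize_intensity(100, 0), class = "caflow_domain_error")
  expect_error(normalize_intensity(100, -5), class = "caflow_domain_error")
  ## power-of-two rescaling is exact in floating point
  f_ic <- c(312.5, 100.25, 7); f_ib <- c(125, 80.5, 3.5)
  expect_identical(normalize_intensity(f_ic * 8, f_ib * 8),
                   normalize_intensity(f_ic, f_ib))
})

test_that("extract_trace reproduces the cell's trace from a rendered stack", {
  sc <- one_cell_scene(T_D = 8, T_P = 4, I_P = 3, tau = 15, duration = 100,
                       dt = 0.2, width_px = 100, height_px = 100)
  out <- render_stack(sc)
  st <- out$stack
  trk <- track_stack(st)
  per <- split_tracks(trk)
  expect_length(per, 1L)
  ev <- classify_firm_adhesion(per[[1]])
  expect_true(ev$firm)
  tr <- extract_trace(st, per[[1]], ev)
  ## row-wise identity F_IN = (F_IC - F_IB)/F_IB
  expect_lt(max(abs(tr$F_IN - (tr$F_IC - tr$F_IB) / tr$F_IB), na.rm = TRUE),
            1e-12)
  ## noiseless: F_IN maximum at the ground-truth peak frame
  i_max <- which.max(tr$F_IN)
  expect_lt(abs(tr$t_rel_s[i_max] - (8 + 4)), 0.2 + 1e-9)
  ## plateau region flat to machine precision
  plat <- tr$F_IN[tr$t_rel_s >= 0 & tr$t_rel_s < 8 - 1e-9]
  expect_lt(max(plat) - min(plat), 1e-6)
  ## F_IC equals the analytic transient (the rendered disk mean is exact)
  p <- transient_params(300, 8, 4, 3, 15)
  expect_equal(tr$F_IC, caflow:::transient_value(p, tr$t_rel_s),
               tolerance = 1e-9)
})

test_that("extract_trace for a non-activated cell is constant and a non-firm track errors", {
  sc <- one_cell_scene(activated = FALSE, duration = 70, dt = 0.5)
  out <- render_stack(sc)
  trk <- track_stack(out$stack)
  per <- split_tracks(trk)
  ev <- classify_firm_adhesion(per[[1]])
  tr <- extract_trace(out$stack, per[[1]], ev)
  expect_lt(max(tr$F_IN) - min(tr$F_IN), 1e-6)

  fake <- ev; fake$firm <- FALSE
  expect_error(extract_trace(out$stack, per[[1]], fake),
               class = "caflow_precondition_error")
})

test_that("all traces and features are invariant under illumination rescaling", {
  sc <- one_cell_scene(T_D = 8, T_P = 4, I_P = 3, tau = 15, duration = 100,
                       dt = 0.2, noise_sd = 4, seed = 6)
  out <- render_stack(sc)
  st <- out$stack
  st2 <- st
  st2$frames <- lapply(st$frames, function(f) f * 4)  # a > 0, exact in fp

  get_feats <- function(stack) {
    trk <- track_stack(stack)
    per <- split_tracks(trk)
    ev <- classify_firm_adhesion(per[[1]])
    tr <- extract_trace(stack, per[[1]], ev)
    list(tr = tr, ft = transient_features(tr))
  }
  a <- get_feats(st)
  b <- get_feats(st2)
  expect_equal(a$tr$F_IN, b$tr$F_IN, tolerance = 1e-12)
  expect_equal(a$ft$T_D_s, b$ft$T_D_s, tolerance = 1e-9)
  expect_equal(a$ft$T_P_s, b$ft$T_P_s, tolerance = 1e-9)
  expect_equal(a$ft$I_P, b$ft$I_P, tolerance = 1e-9)
})

test_that("calcium_trace enforces its invariants", {
  expect_error(calcium_trace(c(0, 1, 1), c(1, 2, 3), c(1, 1, 1)),
               class = "caflow_parameter_error")  # non-increasing time
  expect_error(calcium_trace(0:2, c(1, 2, 3), c(1, 0, 1)),
               class = "caflow_domain_error")     # F_IB <= 0
  tr <- calcium_trace(0:2, c(100, 150, 200), c(100, NA, 100))
  expect_true(is.na(tr$F_IN[2]))
  expect_equal(tr$F_IN[c(1, 3)], c(0, 1))
})
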