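test_that("find_peaks applies threshold, strictness and the plateau rule", {
  expect_identical(find_peaks(c(0.2, 0.9, 0.3), 0.5), 2L)
  expect_identical(find_peaks(c(0.2, 0.4, 0.3), 0.5), integer(0))
  expect_identical(find_peaks(c(0.2, 0.9, 0.9, 0.3), 0.5), 2L)
  expect_identical(find_peaks(c(0.9, 0.2, 0.9), 0.5), integer(0)) # endpoints
  expect_identical(find_peaks(c(0.1, 0.8, 0.2, 0.9, 0.1), 0.5), c(2L, 4L))
  expect_error(find_peaks(c(0.1, 0.9, 0.1), 1), "lbound")
})

test_that("parabola vertex matches the closed-form three-point fit", {
  expect_equal(parabola_vertex(0, 1, 0, 10), 10)
  expect_equal(parabola_vertex(0, 1, 0.5, 10), 10 + 1 / 6, tolerance = 1e-12)
  expect_equal(parabola_vertex(0.5, 0.5, 0.5, 10), 10)  # collinear
  # against a quadratic regression oracle
  set.seed(23)
  for (i in 1:20) {
    y <- sort(runif(3)); y <- c(y[1], y[3], y[2])  # a genuine peak
    x <- sample(5:50, 1)
    fit <- lm(yy ~ xx + I(xx^2),
              data = data.frame(xx = (x - 1):(x + 1), yy = y))
    vertex <- -coef(fit)[2] / (2 * coef(fit)[3])
    expect_equal(parabola_vertex(y[1], y[2], y[3], x), unname(vertex),
                 tolerance = 1e-8)
  }
})

test_that("cycle speeds implement n = 60 f / interval with mean over cycles", {
  sp <- cycle_speeds(c(10, 25), 15)
  expect_equal(sp$speeds_rpm, 60)
  expect_equal(sp$mean_rpm, 60)
  # nine equal intervals of 900/54.76 frames at 15 fps average 54.76 rpm
  v <- cumsum(c(5, rep(900 / 54.76, 9)))
  sp <- cycle_speeds(v, 15)
  expect_length(sp$speeds_rpm, 9L)
  expect_equal(sp$mean_rpm, 54.76, tolerance = 1e-10)
  # degenerate: fewer than two vertices means no complete cycle
  sp0 <- cycle_speeds(7.3, 15)
  expect_false(sp0$complete_cycle)
  expect_length(sp0$speeds_rpm, 0L)
  expect_true(is.na(sp0$mean_rpm))
  expect_error(cycle_speeds(c(5, 5), 15), "strictly increasing")
  expect_error(cycle_speeds(c(5, 9), 0), "positive")
})

test_that("correlation trace is 1 at the reference and bounded elsewhere", {
  sc <- one_cell_scene(60, n_frames = 50, seed = 24)
  rect <- region_rect(60, 60, ROI_HALF, ROI_HALF)
  tr <- track(sc$seq, rect, N_bg = 40)
  ref <- select_reference(sc$seq, tr, rect)
  trace <- correlation_trace(sc$seq, tr, ref)
  expect_equal(trace$C[ref$T], 1, tolerance = 1e-9)
  expect_equal(trace$centers[ref$T, ], ref$center, ignore_attr = TRUE)
  expect_true(all(trace$C >= -1 & trace$C <= 1 + 1e-12))
  # noise-free periodic construction: maxima recur at multiples of the period
  sc0 <- one_cell_scene(60, n_frames = 46, noise_sd = 0, seed = 24)
  tr0 <- track(sc0$seq, rect, N_bg = 45)
  ref0 <- select_reference(sc0$seq, tr0, rect, N = 45)
  t0 <- correlation_trace(sc0$seq, tr0, ref0)
  recur <- ref0$T + 15 * (-3:3)
  recur <- recur[recur >= 1 & recur <= 46]
  expect_true(all(t0$C[recur] >= 0.99))
})

test_that("trajectory returns matched centres at the peak frames", {
  trace <- structure(list(C = c(0.2, 0.9, 0.3, 0.95, 0.2),
                          centers = cbind(u = 11:15, v = 21:25), T = 4L),
                     class = "correlation_trace")
  expect_equal(nrow(trajectory(trace, integer(0))), 0L)
  tj <- trajectory(trace, c(2L, 4L))
  expect_equal(tj[, "u"], c(12L, 14L), ignore_attr = TRUE)
  expect_equal(tj[, "v"], c(22L, 24L), ignore_attr = TRUE)
})

test_that("speeds are invariant to a global intensity gain and offset", {
  sc <- one_cell_scene(60, n_frames = 70, seed = 25)
  rect <- c(60, 60, ROI_HALF, ROI_HALF)
  base <- run_pipeline(sc$seq, rect, lbound = LBOUND)
  scaled <- frame_sequence(lapply(sc$seq$frames, function(f) 0.6 * f + 40),
                           sc$seq$f_fps)
  res2 <- run_pipeline(scaled, rect, lbound = LBOUND)
  expect_equal(res2$profile$mean_rpm, base$profile$mean_rpm,
               tolerance = 0.02)
})

test_that("doubling the frame rate leaves the recovered rpm unchanged", {
  sc15 <- one_cell_scene(60, n_frames = 75, seed = 26)
  r15 <- run_pipeline(sc15$seq, c(60, 60, ROI_HALF, ROI_HALF),
                      lbound = LBOUND)
  sc30 <- render_scene(scene_spec(
    cell_spec(center = c(60, 60), rpm = 60), f_fps = 30,
    n_frames = 150, noise_sd = 3, seed = 26))
  r30 <- run_pipeline(sc30$seq, c(60, 60, ROI_HALF, ROI_HALF), N_bg = 80,
                      lbound = LBOUND)
  # physical intervals double in frames but rpm is unchanged
  expect_equal(mean(r30$profile$intervals), 2 * mean(r15$profile$intervals),
               tolerance = 0.02)
  expect_equal(r30$profile$mean_rpm, 60, tolerance = 0.6)
  expect_equal(r15$profile$mean_rpm, 60, tolerance = 0.6)
})

test_that("sweep_lbound counts peaks monotonically in the threshold", {
  trace <- c(0.1, 0.6, 0.2, 0.9, 0.3, 0.95, 0.1)
  sw <- sweep_lbound(trace, c(0, 0.5, 0.7, 0.92))
  expect_equal(sw$n_peaks, c(3L, 3L, 2L, 1L))
  expect_true(all(diff(sw$n_peaks) <= 0))
})

test_that("pipeline guards its inputs", {
  sc <- one_cell_scene(60, n_frames = 20, seed = 27)
  expect_error(run_pipeline(sc$seq, c(2, 60, 10, 10)), "exceeds")
  expect_error(run_pipeline(sc$seq, c(60, 60, 10, 10), N_bg = 40), "N_bg")
})
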