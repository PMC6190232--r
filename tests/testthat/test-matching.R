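test_that("patch_mean is the arithmetic mean of the rectangle", {
  expect_equal(patch_mean(matrix(9.5, 10, 10), c(5, 5), 2, 2), 9.5)
  f <- matrix(0, 5, 5)
  f[1:3, 1:3] <- matrix(1:9, 3, 3)
  expect_equal(patch_mean(f, c(2, 2), 1, 1), 5)
  set.seed(13)
  g <- matrix(runif(400, 0, 255), 20, 20)
  direct <- 0
  for (m in -3:3) for (n in -2:2) direct <- direct + g[10 + m, 11 + n]
  expect_equal(patch_mean(g, c(10, 11), 2, 3), direct / 35, tolerance = 1e-12)
  expect_error(patch_mean(g, c(1, 10), 3, 3), "exceeds")
})

test_that("ncc is 1 for identical patches and affine-invariant", {
  set.seed(14)
  f <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(ncc(f, c(10, 10), f, c(10, 10), 5, 5), 1, tolerance = 1e-12)
  g <- 3.2 * f + 17         # positive gain
  expect_equal(ncc(f, c(10, 10), g, c(10, 10), 5, 5), 1, tolerance = 1e-12)
  h <- -2 * f + 300         # negative gain flips the sign
  expect_equal(ncc(f, c(10, 10), h, c(10, 10), 5, 5), -1, tolerance = 1e-12)
})

test_that("ncc equals the literal double-summation oracle", {
  set.seed(15)
  for (i in 1:20) {
    fi <- matrix(runif(625, 0, 255), 25, 25)
    fj <- matrix(runif(625, 0, 255), 25, 25)
    ci <- c(sample(6:19, 1), sample(6:19, 1))
    cj <- c(sample(6:19, 1), sample(6:19, 1))
    expect_equal(ncc(fi, ci, fj, cj, 5, 5),
                 ncc_oracle(fi, ci, fj, cj, 5, 5), tolerance = 1e-10)
  }
})

test_that("ncc is symmetric and zero for blank patches", {
  set.seed(16)
  fi <- matrix(runif(400, 0, 255), 20, 20)
  fj <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(ncc(fi, c(10, 10), fj, c(9, 11), 4, 4),
               ncc(fj, c(9, 11), fi, c(10, 10), 4, 4))
  blank <- matrix(128, 20, 20)
  expect_identical(ncc(blank, c(10, 10), fi, c(10, 10), 4, 4), 0)
})

test_that("best_match recovers a pasted template exactly", {
  set.seed(17)
  frame <- matrix(runif(10000, 0, 255), 100, 100)
  tmpl_frame <- matrix(runif(10000, 0, 255), 100, 100)
  patch <- tmpl_frame[43:57, 38:52]        # 15 x 15, centre (50, 45), W=H=7
  frame[63:77, 20:34] <- patch             # pasted at centre (70, 27)
  m <- best_match(frame, c(u_lo = 40, u_hi = 95, v_lo = 10, v_hi = 60),
                  tmpl_frame, c(50, 45), 7, 7)
  expect_equal(c(m$u, m$v), c(70, 27))
  expect_equal(m$C, 1, tolerance = 1e-9)
})

test_that("best_match ties resolve in raster-scan order", {
  frame <- matrix(0, 60, 60)
  patch <- matrix(c(1:24, 255), 5, 5)
  frame[11:15, 11:15] <- patch
  frame[41:45, 41:45] <- patch             # identical second copy
  tmpl <- matrix(0, 20, 20)
  tmpl[8:12, 8:12] <- patch
  m <- best_match(frame, c(u_lo = 5, u_hi = 55, v_lo = 5, v_hi = 55),
                  tmpl, c(10, 10), 2, 2)
  expect_equal(c(m$u, m$v), c(13, 13))     # first maximiser
})

test_that("a constant window scores zero everywhere, first candidate wins", {
  frame <- matrix(50, 40, 40)
  tmpl <- matrix(runif(400, 0, 255), 20, 20)
  m <- best_match(frame, c(u_lo = 10, u_hi = 30, v_lo = 12, v_hi = 30),
                  tmpl, c(10, 10), 4, 4)
  expect_identical(m$C, 0)
  expect_equal(c(m$u, m$v), c(10, 12))
  expect_error(best_match(frame, c(u_lo = 2, u_hi = 3, v_lo = 2, v_hi = 3),
                          tmpl, c(10, 10), 9, 9), "no valid candidate")
})

test_that("matching its own source frame returns the template centre with C=1", {
  sc <- one_cell_scene(60, n_frames = 10, seed = 18)
  f <- sc$seq$frames[[3]]
  m <- best_match(f, c(u_lo = 45, u_hi = 75, v_lo = 45, v_hi = 75),
                  f, c(60, 60), 10, 10)
  expect_equal(c(m$u, m$v), c(60, 60))
  expect_equal(m$C, 1, tolerance = 1e-9)
})

test_that("rank-sum reference rule matches the brute-force oracle", {
  set.seed(19)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    c_adj <- round(runif(n - 1, -1, 1), sample(c(1, 2, 6), 1))  # force ties
    expect_identical(reference_from_correlations(c_adj)$T,
                     reference_oracle(c_adj))
  }
  expect_error(reference_from_correlations(0.5), "at least 3")
})

test_that("identical frames give an all-ties rank sum resolved to frame 2", {
  expect_identical(reference_from_correlations(rep(1, 9))$T, 2L)
})

test_that("one anomalous interior frame is selected as the reference", {
  sc <- one_cell_scene(0, n_frames = 12, noise_sd = 0, seed = 20)
  frames <- sc$seq$frames
  # replace frame 7 with an unrelated texture inside the cell area
  set.seed(21)
  f7 <- frames[[7]]
  f7[43:77, 43:77] <- matrix(runif(35^2, 0, 255), 35, 35)
  frames[[7]] <- f7
  # rotating variant so that segmentation sees a moving region
  sc2 <- one_cell_scene(60, n_frames = 12, noise_sd = 0, seed = 20)
  frames2 <- sc2$seq$frames
  frames2[[7]] <- f7
  s <- frame_sequence(frames2, 15)
  # the pixel-noise frame segments to nothing (opening removes it), so the
  # tracker falls back to the previous centre there — by design
  expect_warning(
    tr <- track(s, region_rect(60, 60, ROI_HALF, ROI_HALF), N_bg = 12),
    "frame 7")
  ref <- select_reference(s, tr, region_rect(60, 60, ROI_HALF, ROI_HALF),
                          N = 12)
  expect_identical(ref$T, 7L)
  expect_true(all(ref$c_adj >= -1 & ref$c_adj <= 1))
})

test_that("reference frame index always has both neighbours", {
  sc <- one_cell_scene(54.76, n_frames = 50, seed = 22)
  tr <- track(sc$seq, region_rect(60, 60, ROI_HALF, ROI_HALF), N_bg = 40)
  ref <- select_reference(sc$seq, tr, region_rect(60, 60, ROI_HALF, ROI_HALF))
  expect_gte(ref$T, 2L)
  expect_lte(ref$T, 39L)
  rs <- ref$rank_sums
  expect_lte(min(rs), rs[as.character(ref$T)])
})
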