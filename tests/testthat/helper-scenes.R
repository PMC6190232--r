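# Shared fixture builders. All scenes are rendered in code at test time;
# the experiment configuration used throughout is a single rotating cell of
# radius 15 px observed at 15 fps, ROI half-extents 17 (covering rectangle),
# additive noise sigma = 3 gray levels, and peak threshold 0.85.

ROI_HALF <- 17L
LBOUND <- 0.85

one_cell_scene <- function(rpm, n_frames = 158, seed = 1, noise_sd = 3,
                           texture_seed = 1, drift = c(0, 0), base = 100,
                           width = 120, height = 120, center = c(60, 60)) {
  render_scene(scene_spec(
    cell_spec(center = center, rpm = rpm, drift = drift,
              texture_seed = texture_seed, base = base),
    width = width, height = height, n_frames = n_frames,
    noise_sd = noise_sd, seed = seed))
}

# independent literal double-sum implementation of the correlation formula
ncc_oracle <- function(fi, ci, fj, cj, W, H) {
  pi_ <- fi[(ci[1] - H):(ci[1] + H), (ci[2] - W):(ci[2] + W)]
  pj_ <- fj[(cj[1] - H):(cj[1] + H), (cj[2] - W):(cj[2] + W)]
  num <- 0; di2 <- 0; dj2 <- 0
  mi <- sum(pi_) / length(pi_); mj <- sum(pj_) / length(pj_)
  for (m in seq_len(nrow(pi_)))
    for (n in seq_len(ncol(pi_))) {
      a <- pj_[m, n] - mj; b <- pi_[m, n] - mi
      num <- num + a * b; di2 <- di2 + b^2; dj2 <- dj2 + a^2
    }
  if (di2 == 0 || dj2 == 0) return(0)
  num / sqrt(di2 * dj2)
}

# exhaustive Otsu oracle: minimise the weighted within-class variance
otsu_oracle <- function(img) {
  vals <- pmin(pmax(floor(as.numeric(img) + 0.5), 0), 255)
  if (min(vals) == max(vals)) return(as.integer(vals[1]))
  best_t <- 0L; best_w <- Inf
  pvar <- function(x) mean((x - mean(x))^2)
  for (t in 0:255) {
    g0 <- vals[vals <= t]; g1 <- vals[vals > t]
    if (length(g0) == 0 || length(g1) == 0) next
    w <- length(g0) * pvar(g0) + length(g1) * pvar(g1)
    if (w < best_w - 1e-9) { best_w <- w; best_t <- t }
  }
  as.integer(best_t)
}

# brute-force reference-frame oracle: explicit ordinal ranks by counting
reference_oracle <- function(c_adj) {
  N <- length(c_adj) + 1L
  fs <- c_adj[1:(N - 2)]
  bs <- c_adj[2:(N - 1)]
  ordinal <- function(x, k)
    sum(x < x[k]) + sum(x[seq_len(k - 1)] == x[k]) + 1L
  best_i <- NA_integer_; best_s <- Inf
  for (i in 2:(N - 1)) {
    s <- ordinal(fs, i - 1L) + ordinal(bs, i - 1L)
    if (s < best_s) { best_s <- s; best_i <- i }
  }
  best_i
}
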