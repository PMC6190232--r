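#' Specify a synthetic cell
#'
#' One textured, roughly circular cell for [scene_spec()]. The texture is an
#' asymmetric intensity pattern (smoothed random blobs plus a bright and a
#' dark marker at different bearings), so the rendered cell looks different
#' at different rotation angles — the property the correlation matching
#' relies on; a rotationally symmetric cell is unmeasurable by design.
#'
#' @param center Initial centre `(u, v)` in pixels (row, col).
#' @param radius Cell radius in pixels (default 15, emulating a ~12 um cell
#'   at typical magnification).
#' @param rpm Rotation speed in rpm; a scalar or a per-frame vector.
#' @param drift Per-frame translation `(du, dv)` in pixels (default none).
#' @param path Optional explicit `n_frames x 2` matrix of centres,
#'   overriding `center`/`drift`.
#' @param texture_seed Seed for this cell's texture pattern.
#' @param base,amp Mean intensity and texture contrast of the cell body.
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(center, radius = 15, rpm = 60, drift = c(0, 0),
                      path = NULL, texture_seed = 1, base = 100, amp = 60) {
  stopifnot(radius >= 3, all(rpm >= 0), base > 0)
  structure(list(center = center, radius = radius, rpm = rpm, drift = drift,
                 path = path, texture_seed = texture_seed,
                 base = base, amp = amp),
            class = "cell_spec")
}

#' Specify a synthetic scene
#'
#' Describes a short microscopy-like video: one or more rotating (optionally
#' translating) textured cells over a static textured background, with
#' additive Gaussian pixel noise, at a known frame rate. Defaults emulate
#' the intended operating conditions: 15 fps, 158 frames, ~30 px cell
#' diameter, a few gray levels of noise.
#'
#' @param cells List of [cell_spec()] objects.
#' @param height,width Frame size in pixels.
#' @param f_fps Frame rate (default 15).
#' @param n_frames Number of frames (default 158).
#' @param bg_level Mean background gray level (default 70).
#' @param bg_amp Background texture contrast (default 5).
#' @param bg_seed Seed for the static background texture.
#' @param noise_sd Additive Gaussian noise sigma in gray levels (default 3).
#' @param seed Global seed for the per-frame noise.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(cells, height = 120, width = 120, f_fps = 15,
                       n_frames = 158, bg_level = 70, bg_amp = 5,
                       bg_seed = 100, noise_sd = 3, seed = 1) {
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  stopifnot(length(cells) >= 1, n_frames >= 2, f_fps > 0, noise_sd >= 0)
  structure(list(cells = cells, height = height, width = width,
                 f_fps = f_fps, n_frames = n_frames, bg_level = bg_level,
                 bg_amp = bg_amp, bg_seed = bg_seed, noise_sd = noise_sd,
                 seed = seed),
            class = "scene_spec")
}

# smoothed random field in [-1, 1]-ish scale, zero mean; the blur kernel is
# capped so it never exceeds the field (small textures, large sigma)
smooth_field <- function(nr, nc, sigma) {
  f <- matrix(rnorm(nr * nc), nr, nc)
  rad <- min(2 * ceiling(3 * sigma) + 1, 2 * (min(nr, nc) %/% 2) - 1)
  f <- EBImage::imageData(EBImage::gblur(f, sigma = sigma, radius = rad))
  f / max(abs(f))
}

# Asymmetric cell texture on a (2*(radius+2)+1)^2 canvas, emulating
# intracellular inhomogeneity. Three soft Gaussian blobs of alternating
# sign sit at unevenly spaced bearings close to the centre: clustered
# central features have a wide angular extent, so the once-per-revolution
# correlation peak is broad (a cell sampled up to ~30 degrees away from the
# reference orientation still correlates strongly), while the uneven
# bearings and signs leave no rotation angle at which the pattern maps onto
# itself. A weak smoothed random field adds fine detail that sharpens the
# peak apex for sub-frame timing.
make_cell_texture <- function(radius, seed, base = 100, amp = 50) {
  s <- 2L * (radius + 2L) + 1L
  ctr <- radius + 3L
  with_seed(seed, {
    d <- seq_len(s) - ctr
    uu <- matrix(d, s, s)
    vv <- t(uu)
    tex <- base + 0.3 * amp * smooth_field(s, s, sigma = max(radius / 3, 1.5))
    off <- radius / 3
    sg <- radius / 2.5
    bearings <- c(0, 100, 200) * pi / 180
    gains <- 0.85 * amp * c(1, -0.95, 0.9)
    for (k in 1:3) {
      g <- exp(-((uu - off * cos(bearings[k]))^2 +
                   (vv - off * sin(bearings[k]))^2) / (2 * sg^2))
      tex <- tex + gains[k] * g
    }
    pmin(pmax(tex, 20), 245)
  })
}

# Bilinear lookup of matrix `m` at real coordinates (u, v), clamped to bounds.
bilinear <- function(m, u, v) {
  nr <- nrow(m); nc <- ncol(m)
  u <- pmin(pmax(u, 1), nr)
  v <- pmin(pmax(v, 1), nc)
  u0 <- pmin(floor(u), nr - 1L); v0 <- pmin(floor(v), nc - 1L)
  du <- u - u0; dv <- v - v0
  m[cbind(u0, v0)] * (1 - du) * (1 - dv) +
    m[cbind(u0 + 1, v0)] * du * (1 - dv) +
    m[cbind(u0, v0 + 1)] * (1 - du) * dv +
    m[cbind(u0 + 1, v0 + 1)] * du * dv
}

cell_path <- function(cell, n_frames) {
  if (!is.null(cell$path)) {
    stopifnot(nrow(cell$path) == n_frames)
    return(cell$path)
  }
  cbind(cell$center[1] + (seq_len(n_frames) - 1) * cell$drift[1],
        cell$center[2] + (seq_len(n_frames) - 1) * cell$drift[2])
}

cell_angles <- function(cell, n_frames, f_fps) {
  inc <- 360 * cell$rpm / (60 * f_fps)     # degrees per frame
  if (length(inc) == 1L) inc <- rep(inc, n_frames - 1L)
  cumsum(c(0, inc[seq_len(n_frames - 1L)]))
}

# paste one cell, rotated by `angle` degrees, onto `img` at real centre (cu, cv)
paste_cell <- function(img, tex, radius, cu, cv, angle) {
  rows <- max(1L, floor(cu - radius)):min(nrow(img), ceiling(cu + radius))
  cols <- max(1L, floor(cv - radius)):min(ncol(img), ceiling(cv + radius))
  uu <- matrix(rows, length(rows), length(cols)) - cu
  vv <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cv
  inside <- uu^2 + vv^2 <= radius^2
  if (!any(inside)) return(img)
  th <- -angle * pi / 180                  # inverse rotation for sampling
  su <- uu[inside] * cos(th) - vv[inside] * sin(th)
  sv <- uu[inside] * sin(th) + vv[inside] * cos(th)
  ctr <- radius + 3
  vals <- bilinear(tex, ctr + su, ctr + sv)
  sub <- img[rows, cols]
  sub[inside] <- vals
  img[rows, cols] <- sub
  img
}

#' Render a synthetic scene
#'
#' Renders every cell as a textured disk rotated by its cumulative angle
#' (increment `360 * rpm / (60 * f_fps)` degrees per frame) with bilinear
#' resampling, composites the cells over the static background, adds
#' Gaussian pixel noise, and quantizes frames to 8-bit levels. The same
#' spec always renders the identical video (all randomness is seeded), and
#' a ground-truth manifest records per-frame centres, angles and the rpm
#' schedule for every cell.
#'
#' @param spec A [scene_spec()].
#' @return A list with `seq` (a [frame_sequence]) and `truth` (a list with
#'   `f_fps`, `n_frames`, and per-cell `centers`, `angles_deg`, `rpm`,
#'   `radius`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$n_frames
  paths <- lapply(spec$cells, cell_path, n_frames = n)
  for (k in seq_along(spec$cells)) {
    r <- spec$cells[[k]]$radius
    p <- paths[[k]]
    if (min(p[, 1]) - r < 1 || max(p[, 1]) + r > spec$height ||
        min(p[, 2]) - r < 1 || max(p[, 2]) + r > spec$width)
      stop("cell ", k, " leaves the frame along its path", call. = FALSE)
  }
  angles <- lapply(spec$cells, cell_angles, n_frames = n, f_fps = spec$f_fps)
  textures <- lapply(spec$cells, function(cl)
    make_cell_texture(cl$radius, cl$texture_seed, cl$base, cl$amp))
  background <- with_seed(spec$bg_seed,
    spec$bg_level + spec$bg_amp * smooth_field(spec$height, spec$width, 3))
  frames <- with_seed(spec$seed, lapply(seq_len(n), function(i) {
    img <- background
    for (k in seq_along(spec$cells))
      img <- paste_cell(img, textures[[k]], spec$cells[[k]]$radius,
                        paths[[k]][i, 1], paths[[k]][i, 2], angles[[k]][i])
    if (spec$noise_sd > 0)
      img <- img + rnorm(length(img), 0, spec$noise_sd)
    ro(pmin(pmax(img, 0), 255))
  }))
  truth <- list(f_fps = spec$f_fps, n_frames = n,
                cells = lapply(seq_along(spec$cells), function(k)
                  list(centers = paths[[k]], angles_deg = angles[[k]],
                       rpm = spec$cells[[k]]$rpm,
                       radius = spec$cells[[k]]$radius)))
  list(seq = frame_sequence(frames, spec$f_fps), truth = truth)
}

#' Write a rendered scene to disk
#'
#' Writes the frames as numbered PNGs plus a JSON ground-truth manifest —
#' the on-disk fixture format that [load_frames()] reads back.
#'
#' @param scene Output of [render_scene()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frames(scene$seq, dir)
  jsonlite::write_json(scene$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
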