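#' Track the cell of interest through the video
#'
#' Runs background subtraction and per-frame segmentation
#' ([segment_moving_regions()]), then associates the cell of interest across
#' frames by nearest centroid: in frame 1 the component whose centroid is
#' closest (Euclidean) to the centre of `init_rect` becomes the moving
#' region of the cell of interest; in frame `i > 1` the component closest to
#' the previous centre `(u[i-1], v[i-1])` is chosen. Equidistant components
#' resolve to the smaller label (labels are assigned in raster-scan order).
#'
#' Each frame's search window is the rectangle centred on the moving region
#' with half-extents `r_i + W` and `r_i + H` (full size
#' `(2r_i + 2W + 1) x (2r_i + 2H + 1)`), where `W`, `H` come from
#' `init_rect` and `r_i` is the moving-region radius. Windows are clipped to
#' the frame bounds when the cell nears an edge.
#'
#' A frame with no segmented components carries the previous centre and
#' radius forward with a warning (one washed-out frame must not abort a
#' multi-cycle measurement); no components in frame 1 is a hard error since
#' tracking cannot start.
#'
#' @param seq A [frame_sequence].
#' @param init_rect A [region_rect] marking the cell of interest in frame 1.
#' @param N_bg Number of frames averaged into the background (default 40).
#' @param R_struct Structuring-element radius for the morphological
#'   clean-up, pixels (default 3).
#' @return An object of class `track_state`: a list with `centers` (an
#'   `n x 3` matrix of columns `u`, `v`, `r`), `windows` (per-frame clipped
#'   search-window bounds, columns `u_lo`, `u_hi`, `v_lo`, `v_hi`),
#'   `regions` (per-frame moving-region bounds, the candidate-centre set
#'   used by the correlation matching), `background`, `levels` (per-frame
#'   Otsu levels), `W`, `H`, `N_bg`, `R_struct`.
#' @export
track <- function(seq, init_rect, N_bg = 40, R_struct = 3) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(init_rect, "region_rect"))
  stopifnot_rect_inside(init_rect, seq$height, seq$width, "init_rect")
  f_B <- compute_background(seq, N_bg)
  n <- length(seq)
  centers <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("u", "v", "r")))
  windows <- matrix(NA_integer_, n, 4,
                    dimnames = list(NULL, c("u_lo", "u_hi", "v_lo", "v_hi")))
  regions <- matrix(NA_integer_, n, 4,
                    dimnames = list(NULL, c("u_lo", "u_hi", "v_lo", "v_hi")))
  levels <- integer(n)
  prev <- c(init_rect$u, init_rect$v)
  prev_r <- NA_real_
  for (i in seq_len(n)) {
    comps <- segment_moving_regions(seq$frames[[i]], f_B, R_struct)
    levels[i] <- attr(comps, "level")
    if (length(comps) == 0L) {
      if (i == 1L)
        stop("no moving regions segmented in frame 1; tracking cannot start",
             call. = FALSE)
      warning("no moving regions in frame ", i,
              "; carrying forward previous centre", call. = FALSE)
      ui <- prev[1]; vi <- prev[2]; ri <- prev_r
    } else {
      d2 <- vapply(comps, function(cc) (cc$u - prev[1])^2 + (cc$v - prev[2])^2,
                   numeric(1))
      best <- which.min(d2)  # ties -> smallest label
      ui <- comps[[best]]$u; vi <- comps[[best]]$v; ri <- comps[[best]]$r
    }
    centers[i, ] <- c(ui, vi, ri)
    windows[i, ] <- c(max(1L, ui - ri - init_rect$H),
                      min(seq$height, ui + ri + init_rect$H),
                      max(1L, vi - ri - init_rect$W),
                      min(seq$width, vi + ri + init_rect$W))
    regions[i, ] <- c(max(1L, ui - ri), min(seq$height, ui + ri),
                      max(1L, vi - ri), min(seq$width, vi + ri))
    prev <- c(ui, vi)
    prev_r <- ri
  }
  structure(list(centers = centers, windows = windows, regions = regions,
                 background = f_B, levels = levels,
                 W = init_rect$W, H = init_rect$H,
                 N_bg = N_bg, R_struct = R_struct),
            class = "track_state")
}

#' @export
print.track_state <- function(x, ...) {
  cat(sprintf("<track_state: %d frames, template %d x %d px, N_bg=%d, R_struct=%d>\n",
              nrow(x$centers), 2 * x$W + 1, 2 * x$H + 1, x$N_bg, x$R_struct))
  invisible(x)
}
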