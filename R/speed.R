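#' Correlation trace against the reference frame
#'
#' For every frame of the video, finds the best match of the reference
#' patch among candidate centres in that frame's tracked moving region,
#' recording the maximum
#' correlation `C_iT` and the matched ROI centre `(u_Ri, v_Ri)`. Because the
#' cell's appearance recurs once per revolution, `C_iT` is a periodic
#' sequence whose peaks mark complete revolutions; the matched centres
#' sample the cell's motion trajectory.
#'
#' @param seq A [frame_sequence].
#' @param track A `track_state` from [track()].
#' @param ref A `ref_selection` from [select_reference()].
#' @return An object of class `correlation_trace`: list with `C` (numeric,
#'   one value per frame), `centers` (matrix of matched `(u, v)`), and the
#'   reference index `T`.
#' @export
correlation_trace <- function(seq, track, ref) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(track, "track_state"),
            inherits(ref, "ref_selection"))
  n <- length(seq)
  C <- numeric(n)
  centers <- matrix(NA_integer_, n, 2, dimnames = list(NULL, c("u", "v")))
  tf <- seq$frames[[ref$T]]
  for (i in seq_len(n)) {
    m <- best_match(seq$frames[[i]], track$regions[i, ], tf, ref$center,
                    ref$W, ref$H)
    C[i] <- m$C
    centers[i, ] <- c(m$u, m$v)
  }
  structure(list(C = C, centers = centers, T = ref$T),
            class = "correlation_trace")
}

#' @export
print.correlation_trace <- function(x, ...) {
  cat(sprintf("<correlation_trace: %d frames, reference %d, C in [%.3f, %.3f]>\n",
              length(x$C), x$T, min(x$C), max(x$C)))
  invisible(x)
}

#' Local maxima of the correlation trace above a threshold
#'
#' Peak points are interior indices that are strict local maxima of the
#' trace and exceed `lbound`. A plateau (a run of equal values higher than
#' both neighbours) collapses to its first frame. Endpoints are never
#' peaks: a peak needs both neighbours for the parabolic fit.
#'
#' @param trace A `correlation_trace`, or a plain numeric vector.
#' @param lbound Threshold in `[0, 1)`; local maxima at or below it are
#'   ignored (guards against spurious within-cycle ripples).
#' @return Integer vector of peak frame indices (possibly empty).
#' @export
find_peaks <- function(trace, lbound = 0.5) {
  C <- if (inherits(trace, "correlation_trace")) trace$C else as.numeric(trace)
  if (lbound < 0 || lbound >= 1)
    stop("`lbound` must be in [0, 1)", call. = FALSE)
  r <- rle(C)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  first_idx <- cumsum(c(1L, r$lengths[-k]))   # first frame of each run
  is_peak <- c(FALSE, r$values[2:(k - 1L)] > r$values[1:(k - 2L)] &
                 r$values[2:(k - 1L)] > r$values[3:k], FALSE)
  is_peak <- is_peak & r$values > lbound
  first_idx[is_peak]
}

#' Sub-frame vertex of a three-point parabola
#'
#' Fits the parabola through `(x_peak - 1, c_prev)`, `(x_peak, c_peak)`,
#' `(x_peak + 1, c_next)` and returns the abscissa of its vertex,
#' `x_peak + (c_prev - c_next) / (2 (c_prev - 2 c_peak + c_next))`. This
#' refines each once-per-revolution peak to sub-frame timing. Collinear
#' points (zero curvature) return `x_peak` unchanged.
#'
#' @param c_prev,c_peak,c_next Trace values at consecutive frames.
#' @param x_peak Frame index of the central (peak) sample.
#' @return The vertex abscissa, a real frame index.
#' @export
parabola_vertex <- function(c_prev, c_peak, c_next, x_peak) {
  den <- c_prev - 2 * c_peak + c_next
  if (den == 0) return(as.numeric(x_peak))
  x_peak + 0.5 * (c_prev - c_next) / den
}

#' Per-cycle rotation speeds from peak timings
#'
#' Each adjacent pair of vertices `(X_{i-1}, X_i)` spans one revolution of
#' `X_i - X_{i-1}` frames, giving the per-cycle speed
#' `n = 60 * f_fps / (X_i - X_{i-1})` rpm. The summary speed is the
#' arithmetic mean of the per-cycle speeds.
#'
#' @param vertices Strictly increasing numeric vector of (sub-frame) peak
#'   positions, in frames.
#' @param f_fps Frame rate, frames per second.
#' @return A list with `intervals` (frames), `speeds_rpm`, and `mean_rpm`
#'   (`NA` with a `complete_cycle = FALSE` flag when fewer than two
#'   vertices exist).
#' @export
cycle_speeds <- function(vertices, f_fps) {
  if (f_fps <= 0) stop("`f_fps` must be positive", call. = FALSE)
  if (is.unsorted(vertices, strictly = TRUE))
    stop("`vertices` must be strictly increasing", call. = FALSE)
  if (length(vertices) < 2L)
    return(list(intervals = numeric(0), speeds_rpm = numeric(0),
                mean_rpm = NA_real_, complete_cycle = FALSE))
  intervals <- diff(vertices)
  speeds <- 60 * f_fps / intervals
  list(intervals = intervals, speeds_rpm = speeds, mean_rpm = mean(speeds),
       complete_cycle = TRUE)
}

#' Motion trajectory at the peak frames
#'
#' The cell's trajectory is sampled at the integer peak frames: once per
#' revolution the cell shows the reference appearance again, and the
#' matched ROI centre at that frame locates it without orientation bias.
#'
#' @param trace A `correlation_trace`.
#' @param peaks Integer peak indices from [find_peaks()].
#' @return A matrix with columns `frame`, `u`, `v` (zero rows if no peaks).
#' @export
trajectory <- function(trace, peaks) {
  stopifnot(inherits(trace, "correlation_trace"))
  cbind(frame = as.integer(peaks),
        u = trace$centers[peaks, 1], v = trace$centers[peaks, 2])
}

#' Speed profile from a correlation trace
#'
#' Convenience wrapper chaining [find_peaks()], [parabola_vertex()] at each
#' peak, [cycle_speeds()] and [trajectory()] into a single `speed_profile`.
#'
#' @param trace A `correlation_trace`.
#' @param f_fps Frame rate, frames per second.
#' @param lbound Peak threshold (default 0.5).
#' @return An object of class `speed_profile`: list with `peaks`,
#'   `vertices`, `intervals`, `speeds_rpm`, `mean_rpm`, `complete_cycle`,
#'   `trajectory`, `lbound`, `f_fps`.
#' @export
speed_profile <- function(trace, f_fps, lbound = 0.5) {
  stopifnot(inherits(trace, "correlation_trace"))
  peaks <- find_peaks(trace, lbound)
  vertices <- vapply(peaks, function(p)
    parabola_vertex(trace$C[p - 1L], trace$C[p], trace$C[p + 1L], p),
    numeric(1))
  sp <- cycle_speeds(vertices, f_fps)
  structure(list(peaks = peaks, vertices = vertices,
                 intervals = sp$intervals, speeds_rpm = sp$speeds_rpm,
                 mean_rpm = sp$mean_rpm, complete_cycle = sp$complete_cycle,
                 trajectory = trajectory(trace, peaks),
                 lbound = lbound, f_fps = f_fps),
            class = "speed_profile")
}

#' @export
print.speed_profile <- function(x, ...) {
  cat(sprintf("<speed_profile: %d peaks, %d cycles, mean %.2f rpm>\n",
              length(x$peaks), length(x$speeds_rpm),
              if (is.na(x$mean_rpm)) NA_real_ else x$mean_rpm))
  invisible(x)
}

#' Peak count as a function of the threshold
#'
#' Tabulates how many peaks [find_peaks()] returns over a grid of `lbound`
#' values — an aid for choosing the threshold by hand on difficult videos:
#' a stable plateau of the count across a wide threshold range marks the
#' once-per-revolution peaks.
#'
#' @param trace A `correlation_trace` or numeric vector.
#' @param lbounds Thresholds to evaluate (default `seq(0, 0.95, 0.05)`).
#' @return A data frame with columns `lbound` and `n_peaks`.
#' @export
sweep_lbound <- function(trace, lbounds = seq(0, 0.95, by = 0.05)) {
  data.frame(lbound = lbounds,
             n_peaks = vapply(lbounds, function(lb)
               length(find_peaks(trace, lb)), integer(1)))
}
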