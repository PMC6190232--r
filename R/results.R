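#' Write pipeline results to disk
#'
#' Writes three files into `out_dir`:
#' * `cycles.csv` — one row per completed cycle: cycle index, interval in
#'   frames (from the sub-frame vertices), speed in rpm;
#' * `trajectory.csv` — one row per trajectory point: peak frame index and
#'   matched centre `(u, v)`;
#' * `summary.json` — mean rpm (null when no complete cycle exists), number
#'   of cycles, reference frame index, and the parameters used.
#'
#' Output is deterministic: identical inputs produce byte-identical files.
#'
#' @param profile A `speed_profile`.
#' @param trace The `correlation_trace` the profile was computed from.
#' @param out_dir Output directory (created if missing).
#' @param params Optional named list of extra parameters echoed into the
#'   JSON summary (e.g. the full pipeline configuration).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(profile, trace, out_dir, params = list()) {
  stopifnot(inherits(profile, "speed_profile"),
            inherits(trace, "correlation_trace"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  n_cyc <- length(profile$speeds_rpm)
  cycles <- data.frame(cycle = seq_len(n_cyc),
                       interval_frames = profile$intervals,
                       rpm = profile$speeds_rpm)
  traj <- data.frame(peak_frame = profile$trajectory[, "frame"],
                     u = profile$trajectory[, "u"],
                     v = profile$trajectory[, "v"])
  paths <- file.path(out_dir, c("cycles.csv", "trajectory.csv",
                                "summary.json"))
  write.csv(cycles, paths[1], row.names = FALSE)
  write.csv(traj, paths[2], row.names = FALSE)
  summary <- c(list(
    mean_rpm = if (is.na(profile$mean_rpm)) NULL else profile$mean_rpm,
    n_cycles = n_cyc,
    n_peaks = length(profile$peaks),
    reference_frame = trace$T,
    lbound = profile$lbound,
    f_fps = profile$f_fps
  ), params)
  jsonlite::write_json(summary, paths[3], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}

#' Read back a cycles table
#'
#' @param path Path to a `cycles.csv` written by [write_results()].
#' @return A data frame with columns `cycle`, `interval_frames`, `rpm`.
#' @export
read_cycles <- function(path) read.csv(path)
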