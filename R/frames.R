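#' Frame sequences
#'
#' A `frame_sequence` is the container the whole pipeline operates on: an
#' ordered list of grayscale frames of identical dimensions plus the video
#' frame rate. Frames are numeric matrices holding 8-bit intensities
#' (0--255); they are kept as doubles so that background averaging and
#' correlation arithmetic run at full precision. Frame indices are 1-based
#' everywhere in the public API.
#'
#' Pixel coordinates follow the matrix convention: `(u, v)` is
#' `(row, column)`, 1-based, origin at the top-left of the image.
#'
#' @param frames List of numeric matrices, all of identical dimensions,
#'   values in `[0, 255]`.
#' @param f_fps Frame rate in frames per second (> 0).
#' @return An object of class `frame_sequence` with elements `frames`,
#'   `height`, `width` and `f_fps`.
#' @export
frame_sequence <- function(frames, f_fps) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("`frames` must be a list of at least 2 matrices", call. = FALSE)
  if (!is.numeric(f_fps) || length(f_fps) != 1L || f_fps <= 0)
    stop("`f_fps` must be a single positive number", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions", call. = FALSE)
  structure(
    list(frames = lapply(frames, function(f) {
      storage.mode(f) <- "double"
      f
    }),
    height = dims[1, 1], width = dims[2, 1], f_fps = as.numeric(f_fps)),
    class = "frame_sequence"
  )
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence: %d frames, %d x %d px, %.3g fps>\n",
              length(x), x$height, x$width, x$f_fps))
  invisible(x)
}

#' Convert an image array to 8-bit grayscale
#'
#' RGB images are converted with the ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114) and rounded half-up; grayscale input passes
#' through unchanged (idempotent). An alpha channel, if present, is ignored.
#'
#' @param img A numeric matrix (grayscale) or a `height x width x channels`
#'   array, values on the 0--255 scale.
#' @return A numeric matrix of intensities in `[0, 255]`.
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    if (nch == 1L) return(img[, , 1])
    if (nch >= 3L)
      return(ro(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]))
    if (nch == 2L) return(img[, , 1])  # gray + alpha
  }
  stop("unsupported image shape: ", paste(dim(img), collapse = "x"),
       call. = FALSE)
}

read_image_8bit <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  # readPNG/readTIFF return intensities on [0, 1] regardless of source bit
  # depth; >8-bit sources are therefore linearly rescaled onto 0--255.
  to_grayscale(img * 255)
}

# numeric-aware sort: frame_2.png before frame_10.png
sort_numeric <- function(files) {
  nums <- suppressWarnings(
    as.numeric(gsub("^.*?(\\d+)\\D*$", "\\1", basename(files)))
  )
  if (anyNA(nums)) files[order(basename(files))] else files[order(nums)]
}

#' Load a video as a frame sequence
#'
#' Reads a directory of numbered PNG/TIFF frames into a [frame_sequence],
#' converting colour frames to grayscale (see [to_grayscale()]). Frames are
#' ordered by the number embedded in their filenames. Container formats
#' (AVI/MP4) are not read directly; decode them to a frame directory first
#' (e.g. `ffmpeg -i video.avi frames/f_%04d.png`).
#'
#' @param source_path Path to a directory of image frames.
#' @param f_fps Frame rate of the source video, frames per second.
#' @return A [frame_sequence].
#' @export
load_frames <- function(source_path, f_fps) {
  if (!file.exists(source_path))
    stop("input not found: ", source_path, call. = FALSE)
  if (!dir.exists(source_path))
    stop("`source_path` must be a directory of PNG/TIFF frames; ",
         "decode video containers to frames first", call. = FALSE)
  files <- list.files(source_path, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) < 2L)
    stop("need at least 2 frames, found ", length(files), call. = FALSE)
  frames <- lapply(sort_numeric(files), read_image_8bit)
  frame_sequence(frames, f_fps)
}

#' Write a frame sequence as numbered PNG files
#'
#' @param seq A [frame_sequence].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_frames <- function(seq, dir) {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("frame_%04d.png", seq_along(seq$frames)))
  for (i in seq_along(seq$frames))
    png::writePNG(pmin(pmax(seq$frames[[i]], 0), 255) / 255, paths[i])
  invisible(paths)
}
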