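#' Background image by temporal averaging
#'
#' The background is the pixel-wise arithmetic mean of the first `N` frames,
#' kept at full real precision. For the subtraction step to suppress the
#' rotating cell, `N` must exceed the number of frames in one rotation
#' cycle, so that every orientation contributes to the average; choosing `N`
#' is the caller's responsibility.
#'
#' @param seq A [frame_sequence].
#' @param N Number of leading frames to average, `2 <= N <= length(seq)`.
#' @return A numeric matrix (same size as the frames).
#' @export
compute_background <- function(seq, N) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (N != floor(N) || N < 2 || N > length(seq))
    stop("`N` must be an integer in [2, ", length(seq), "], got ", N,
         call. = FALSE)
  Reduce(`+`, seq$frames[seq_len(N)]) / N
}

#' Otsu threshold on the 8-bit histogram
#'
#' Returns the smallest integer level in `[0, 255]` maximizing the
#' between-class variance of the 256-bin intensity histogram. Pixels are
#' assigned to bins by rounding (half-up) and clamping to `[0, 255]`. The
#' downstream binarization rule is strictly-greater: foreground is
#' `img > level`, so a constant image (for which every split leaves one
#' class empty) returns that constant value and yields an empty foreground.
#'
#' @param img Numeric matrix of intensities.
#' @return Integer threshold level in `[0, 255]`.
#' @export
otsu_threshold <- function(img) {
  if (length(img) < 1L) stop("image has no pixels", call. = FALSE)
  vals <- pmin(pmax(ro(as.numeric(img)), 0), 255)
  if (min(vals) == max(vals)) return(as.integer(vals[1]))
  h <- tabulate(vals + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  w0 <- cumsum(p)                      # P(class <= t)
  mu_t <- cumsum(p * levels)           # partial mean
  mu <- mu_t[256]
  w1 <- 1 - w0
  # between-class variance; splits with an empty class carry no information
  sb <- (mu * w0 - mu_t)^2 / (w0 * w1)
  sb[w0 == 0 | w1 == 0] <- 0
  as.integer(levels[which.max(sb)])    # which.max -> smallest maximiser
}

#' Disk-shaped structuring element
#'
#' Flat disk of radius `R`: the element contains every pixel whose centre is
#' at distance <= `R` from the origin, as a `(2R+1) x (2R+1)` 0/1 matrix.
#'
#' @param R Radius in pixels, >= 1.
#' @return A binary matrix usable as a morphological kernel.
#' @export
disk_element <- function(R) {
  if (R != floor(R) || R < 1) stop("`R` must be an integer >= 1", call. = FALSE)
  d <- -R:R
  (outer(d^2, d^2, `+`) <= R^2) + 0
}

#' Segment moving regions in one frame
#'
#' Implements the background-subtraction segmentation: the absolute
#' difference image `|frame - background|` is binarized at the Otsu level
#' (strictly-greater rule), cleaned by morphological opening (removes small
#' noise) then closing (reconnects adjacent fragments) with a flat disk of
#' radius `R_struct`, and its 8-connected components are labelled in
#' raster-scan order. Each component is summarised by its pixel count, its
#' centroid rounded half-up, and its rounded maximum distance from the
#' (unrounded) centroid.
#'
#' @param frame,f_B Numeric matrices of identical size: the frame and the
#'   background image.
#' @param R_struct Structuring-element radius in pixels (default 3).
#' @param level Optional fixed binarization level; default is the Otsu level
#'   of the difference image.
#' @return A list of components, each a list with elements `u`, `v`
#'   (rounded centroid), `r` (rounded max radius), `M` (pixel count) and
#'   `pixels` (an `M x 2` matrix of (row, col) coordinates). The list
#'   carries the level used as attribute `"level"`. Zero components is a
#'   valid empty-list result.
#' @export
segment_moving_regions <- function(frame, f_B, R_struct = 3, level = NULL) {
  if (!all(dim(frame) == dim(f_B)))
    stop("frame and background dimensions differ", call. = FALSE)
  delta <- abs(frame - f_B)
  if (is.null(level)) level <- otsu_threshold(delta)
  mask <- delta > level
  if (any(mask)) {
    kern <- disk_element(R_struct)
    m <- EBImage::closing(EBImage::opening(mask + 0, kern), kern)
    mask <- EBImage::imageData(m) > 0
  }
  lab <- .label_components_cpp(mask)
  n <- max(lab)
  comps <- vector("list", n)
  if (n > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    labs <- lab[lab > 0]
    for (q in seq_len(n))
      comps[[q]] <- component_stats(idx[labs == q, , drop = FALSE])
  }
  attr(comps, "level") <- level
  comps
}

# Summary of one labelled component: rounded centroid, rounded maximum
# distance of any pixel from the (unrounded) centroid, pixel count.
component_stats <- function(px) {
  cu <- mean(px[, 1])
  cv <- mean(px[, 2])
  r <- max(sqrt((px[, 1] - cu)^2 + (px[, 2] - cv)^2))
  list(u = ro(cu), v = ro(cv), r = ro(r), M = nrow(px),
       pixels = unname(px))
}
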