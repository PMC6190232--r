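#' Odd-sized rectangular region
#'
#' The template/ROI primitive: a rectangle centred at pixel `(u, v)` with
#' half-extents `W` (columns) and `H` (rows), spanning `2W+1 x 2H+1` pixels,
#' so width and height are odd by construction. This is the shape of the
#' manually selected cell-of-interest rectangle, of the matching template,
#' and of every search window.
#'
#' @param u,v Centre pixel (row, column), 1-based.
#' @param W,H Half-width and half-height in pixels, each >= 1.
#' @return An object of class `region_rect`.
#' @export
region_rect <- function(u, v, W, H) {
  if (any(c(u, v, W, H) != floor(c(u, v, W, H))))
    stop("region_rect fields must be integers", call. = FALSE)
  if (W < 1 || H < 1)
    stop("half-extents W and H must be >= 1", call. = FALSE)
  structure(list(u = as.integer(u), v = as.integer(v),
                 W = as.integer(W), H = as.integer(H)),
            class = "region_rect")
}

#' @export
print.region_rect <- function(x, ...) {
  cat(sprintf("<region_rect: centre (%d, %d), %d x %d px>\n",
              x$u, x$v, 2 * x$W + 1, 2 * x$H + 1))
  invisible(x)
}

# TRUE iff the rectangle lies fully inside an nr x nc frame
rect_inside <- function(rect, nr, nc) {
  rect$u - rect$H >= 1 && rect$u + rect$H <= nr &&
    rect$v - rect$W >= 1 && rect$v + rect$W <= nc
}

stopifnot_rect_inside <- function(rect, nr, nc, what = "rectangle") {
  if (!rect_inside(rect, nr, nc))
    stop(sprintf("%s (centre (%d, %d), half-extents W=%d, H=%d) exceeds the %d x %d frame",
                 what, rect$u, rect$v, rect$W, rect$H, nr, nc), call. = FALSE)
}
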