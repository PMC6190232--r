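#' Mean intensity of a rectangular patch
#'
#' Arithmetic mean over the `(2W+1) x (2H+1)` rectangle centred at
#' `(center[1], center[2])` = (row, col).
#'
#' @param frame Numeric matrix.
#' @param center Length-2 integer vector `(u, v)`.
#' @param W,H Half-extents in pixels.
#' @return The mean intensity.
#' @export
patch_mean <- function(frame, center, W, H) {
  r <- region_rect(center[1], center[2], W, H)
  stopifnot_rect_inside(r, nrow(frame), ncol(frame), "patch")
  .patch_mean_cpp(frame, r$u, r$v, W, H)
}

#' Normalized correlation coefficient between two patches
#'
#' The mean-subtracted, variance-normalized similarity in `[-1, 1]` between
#' the `(2W+1) x (2H+1)` patch of `frame_i` centred at `center_i` and the
#' equally sized patch of `frame_j` centred at `center_j`. Invariant to
#' adding a constant to either patch and to scaling either by a positive
#' gain; a negative gain flips the sign. If either patch has zero variance
#' the coefficient is defined as 0: a blank patch carries no orientation
#' information and must never outrank a textured match.
#'
#' @param frame_i,frame_j Numeric matrices.
#' @param center_i,center_j Length-2 `(u, v)` centres, one per frame.
#' @param W,H Half-extents of the rectangles.
#' @return A correlation value in `[-1, 1]`.
#' @export
ncc <- function(frame_i, center_i, frame_j, center_j, W, H) {
  ri <- region_rect(center_i[1], center_i[2], W, H)
  rj <- region_rect(center_j[1], center_j[2], W, H)
  stopifnot_rect_inside(ri, nrow(frame_i), ncol(frame_i), "patch i")
  stopifnot_rect_inside(rj, nrow(frame_j), ncol(frame_j), "patch j")
  .ncc_cpp(frame_i, ri$u, ri$v, frame_j, rj$u, rj$v, W, H)
}

# Valid candidate-centre bounds inside a clipped window: centres whose
# template rectangle fits in the nr x nc frame.
candidate_bounds <- function(window, W, H, nr, nc) {
  c(u_lo = max(window[["u_lo"]], H + 1L), u_hi = min(window[["u_hi"]], nr - H),
    v_lo = max(window[["v_lo"]], W + 1L), v_hi = min(window[["v_hi"]], nc - W))
}

#' Best template match within a search window
#'
#' Evaluates the normalized correlation coefficient between the template
#' patch (centred at `template_center` in `template_frame`) and the patch of
#' `frame` at every candidate centre inside the search window whose
#' rectangle fits in the frame, returning the maximizing centre and its
#' coefficient. Ties resolve to the first maximiser in raster-scan order.
#'
#' @param frame Numeric matrix searched for the match.
#' @param window Either a named vector `(u_lo, u_hi, v_lo, v_hi)` as stored
#'   in a `track_state`, or a [region_rect] giving the window.
#' @param template_frame Frame providing the template patch.
#' @param template_center Length-2 `(u, v)` centre of the template.
#' @param W,H Template half-extents.
#' @return A list with `u`, `v` (matched centre) and `C` (its coefficient).
#' @export
best_match <- function(frame, window, template_frame, template_center, W, H) {
  if (inherits(window, "region_rect"))
    window <- c(u_lo = window$u - window$H, u_hi = window$u + window$H,
                v_lo = window$v - window$W, v_hi = window$v + window$W)
  tr <- region_rect(template_center[1], template_center[2], W, H)
  stopifnot_rect_inside(tr, nrow(template_frame), ncol(template_frame),
                        "template")
  b <- candidate_bounds(window, W, H, nrow(frame), ncol(frame))
  if (b[["u_lo"]] > b[["u_hi"]] || b[["v_lo"]] > b[["v_hi"]])
    stop("search window contains no valid candidate centres", call. = FALSE)
  res <- .best_match_cpp(frame, template_frame, tr$u, tr$v, W, H,
                         b[["u_lo"]], b[["u_hi"]], b[["v_lo"]], b[["v_hi"]])
  list(u = as.integer(res[1]), v = as.integer(res[2]), C = res[3])
}

#' Reference-frame index from an adjacent-correlation sequence
#'
#' The rank-sum rule on the maximum adjacent-frame correlations
#' `c_adj = [C_21, C_32, ..., C_N,N-1]`: sort `[C_21 .. C_{N-1,N-2}]`
#' ascending into `FS` and `[C_32 .. C_N,N-1]` ascending into `BS` (stable
#' sorts; ties keep original order), and pick the frame `i` in `[2, N-1]`
#' minimizing the ordinal position of `C_{i,i-1}` in `FS` plus that of
#' `C_{i+1,i}` in `BS`. A frame that is unlike both its neighbours has two
#' small correlations, hence two small ranks. Rank-sum ties resolve to the
#' smallest frame index.
#'
#' @param c_adj Numeric vector of length `N - 1` of adjacent correlations,
#'   element `k` being the correlation between frames `k+1` and `k`.
#' @return A list with the selected frame index `T` and `rank_sums`
#'   (named by candidate frame index).
#' @export
reference_from_correlations <- function(c_adj) {
  N <- length(c_adj) + 1L
  if (N < 3L) stop("need at least 3 frames (2 adjacent correlations)",
                   call. = FALSE)
  fs <- c_adj[seq_len(N - 2L)]            # C_21 .. C_{N-1,N-2}
  bs <- c_adj[seq(2L, N - 1L)]            # C_32 .. C_{N,N-1}
  rank_fs <- rank(fs, ties.method = "first")
  rank_bs <- rank(bs, ties.method = "first")
  rs <- rank_fs + rank_bs                 # candidate i = 2 .. N-1
  names(rs) <- as.character(seq(2L, N - 1L))
  list(T = as.integer(which.min(rs)) + 1L, rank_sums = rs)
}

#' Automatic reference-frame selection
#'
#' Chains the region of interest forward through the first `N` frames:
#' the ROI in frame 1 is `init_rect`; the ROI in frame `i` is the best
#' match of frame `i-1`'s ROI patch among candidate centres in frame `i`'s
#' tracked moving region,
#' yielding the maximum adjacent correlations `C_i,i-1` for `i` in
#' `[2, N]`. The reference frame — the frame whose cell appearance is most
#' distinct from both neighbours — is then picked by the rank-sum rule
#' ([reference_from_correlations()]).
#'
#' @param seq A [frame_sequence].
#' @param track A `track_state` from [track()].
#' @param init_rect The [region_rect] selected in frame 1.
#' @param N Number of leading frames to consider (>= 3); conventionally the
#'   same span used for the background.
#' @return An object of class `ref_selection`: list with `T` (reference
#'   frame index, in `[2, N-1]`), `center` (ROI centre `(u, v)` in the
#'   reference frame), `c_adj`, `roi_centers` (an `N x 2` matrix), and
#'   `rank_sums`.
#' @export
select_reference <- function(seq, track, init_rect, N = track$N_bg) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(track, "track_state"))
  if (N < 3L) stop("`N` must be >= 3 to rank both neighbours", call. = FALSE)
  if (N > length(seq)) stop("`N` exceeds the number of frames", call. = FALSE)
  W <- init_rect$W; H <- init_rect$H
  roi <- matrix(NA_integer_, N, 2, dimnames = list(NULL, c("u", "v")))
  roi[1, ] <- c(init_rect$u, init_rect$v)
  c_adj <- numeric(N - 1L)
  for (i in 2:N) {
    m <- best_match(seq$frames[[i]], track$regions[i, ],
                    seq$frames[[i - 1L]], roi[i - 1L, ], W, H)
    roi[i, ] <- c(m$u, m$v)
    c_adj[i - 1L] <- m$C
  }
  sel <- reference_from_correlations(c_adj)
  structure(list(T = sel$T, center = roi[sel$T, ], c_adj = c_adj,
                 roi_centers = roi, rank_sums = sel$rank_sums,
                 W = W, H = H),
            class = "ref_selection")
}

#' @export
print.ref_selection <- function(x, ...) {
  cat(sprintf("<ref_selection: reference frame %d, ROI centre (%d, %d)>\n",
              x$T, x$center[1], x$center[2]))
  invisible(x)
}
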