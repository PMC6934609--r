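#' Local binary pattern code of a single pixel
#'
#' The LBP code is the 8-bit word \eqn{\sum_{n=0}^{7} 2^n s(i_n - i_c)} where
#' \eqn{i_c} is the center intensity, \eqn{i_n} the intensity of the n-th
#' neighbor, and \eqn{s(x) = 1} for \eqn{x \ge 0}, else 0 (ties with the
#' center set the bit). Neighbors are taken clockwise starting from the
#' top-left neighbor, with neighbor n contributing weight \eqn{2^n}. All bits
#' carry the same significance, so any fixed ordering is valid; this one is
#' frozen so codes are reproducible.
#'
#' @param center Intensity of the center pixel.
#' @param neighbors Numeric vector of exactly 8 neighbor intensities, in the
#'   documented order.
#'
#' @return Integer code in `[0, 255]`.
#' @export
#'
#' @examples
#' lbp_code(100, c(120, 90, 100, 50, 200, 100, 99, 101))  # 181
lbp_code <- function(center, neighbors) {
  if (length(neighbors) != 8L) stop("exactly 8 neighbor values are required")
  as.integer(sum(2^(0:7) * (neighbors >= center)))
}

#' LBP code map of a frame
#'
#' Applies [lbp_code()] at every interior pixel. Border pixels have no full
#' 8-neighborhood and are skipped (no padding), so the code map of an
#' `H x W` frame is `(H-2) x (W-2)`. The map is invariant to any strictly
#' increasing (monotonic) remapping of gray levels.
#'
#' @param frame A [cem_frame] or intensity matrix, at least 3 x 3.
#' @return Integer matrix of LBP codes in `[0, 255]`.
#' @export
lbp_map <- function(frame) {
  px <- frame_pixels(frame)
  if (nrow(px) < 3L || ncol(px) < 3L) stop("frame must be at least 3 x 3")
  storage.mode(px) <- "integer"
  lbp_map_cpp(px)
}

#' Concatenated patch-histogram LBP features
#'
#' The frame's LBP code map is tiled into non-overlapping `N x N` patches over
#' the largest fitting grid (`floor(H'/N) x floor(W'/N)` patches; remainder
#' rows/columns are dropped). Each patch contributes a 256-bin histogram of
#' its codes; histograms are concatenated in row-major patch order. With the
#' default `N = 8` -- roughly the diameter of a healthy vesicular crypt -- a
#' nominal 290 x 292 frame yields a 288 x 290 code map, 36 x 36 = 1296
#' patches, and a feature vector of length 331,776. Histograms are raw
#' counts: each interior patch sums to `N^2`, so normalization is a constant
#' rescale absorbed by the downstream linear SVM.
#'
#' @param frame A [cem_frame] or intensity matrix.
#' @param patch_size Patch side `N` in pixels (default 8).
#' @return Numeric feature vector of length `n_patches * 256` with attributes
#'   `patch_grid` (rows, cols of the patch grid) and `patch_size`.
#' @export
extract_features <- function(frame, patch_size = 8L) {
  patch_size <- as.integer(patch_size)
  if (patch_size < 2L) stop("`patch_size` must be at least 2")
  codes <- lbp_map(frame)
  npr <- nrow(codes) %/% patch_size
  npc <- ncol(codes) %/% patch_size
  if (npr < 1L || npc < 1L) stop("code map smaller than one patch")
  v <- as.numeric(lbp_patch_hist_cpp(codes, patch_size))
  attr(v, "patch_grid") <- c(npr, npc)
  attr(v, "patch_size") <- patch_size
  v
}

#' LBP feature matrix for a set of frames
#'
#' Extracts [extract_features()] for each frame and stacks them as rows of a
#' sparse matrix (most of the 256 histogram bins are empty in any patch, so
#' sparse storage is dramatically smaller).
#'
#' @param frames List of [cem_frame] objects or intensity matrices.
#' @param patch_size Patch side in pixels.
#' @return A `dgCMatrix` with one row per frame.
#' @export
featurize_frames <- function(frames, patch_size = 8L) {
  n <- length(frames)
  stopifnot(n >= 1L)
  cap <- 0L; ncolv <- NULL; used <- 0L
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    v <- extract_features(frames[[i]], patch_size)
    if (is.null(ncolv)) {
      ncolv <- length(v)
      cap <- min(n * ncolv, as.integer(1.3 * n * sum(v != 0)) + ncolv)
      ii <- integer(cap); jj <- integer(cap); xx <- numeric(cap)
    } else if (length(v) != ncolv) {
      stop("frames produce feature vectors of different lengths")
    }
    nz <- which(v != 0)
    if (used + length(nz) > cap) {  # grow the triplet buffers
      cap <- max(cap * 2L, used + length(nz))
      length(ii) <- cap; length(jj) <- cap; length(xx) <- cap
    }
    at <- used + seq_along(nz)
    ii[at] <- i; jj[at] <- nz; xx[at] <- v[nz]
    used <- used + length(nz)
  }
  Matrix::sparseMatrix(i = ii[seq_len(used)], j = jj[seq_len(used)],
                       x = xx[seq_len(used)], dims = c(n, ncolv))
}
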