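#' Gray-level histogram skewness of a frame
#'
#' Computes the Fisher-Pearson standardized third moment
#' \eqn{g_1 = m_3 / m_2^{3/2}} of the pixel-intensity distribution, using
#' population (uncorrected) moments. Computing over raw pixel values is
#' mathematically identical to computing over the count-weighted gray-level
#' histogram and avoids any binning choice. Saturated frames pile mass at the
#' top of the intensity range and have strongly negative skewness;
#' underexposed frames have strongly positive skewness.
#'
#' @param frame A [cem_frame] or an intensity matrix with at least 2 pixels.
#'
#' @return The skewness as a numeric scalar, or `NA_real_` when the frame has
#'   zero variance (the statistic is undefined for a constant frame).
#' @seealso [filter_frames()] for the informative-frame filter built on it.
#' @export
#'
#' @examples
#' px <- matrix(c(rep(50L, 50), rep(150L, 50)), 10, 10)
#' histogram_skewness(px)  # symmetric: 0
histogram_skewness <- function(frame) {
  x <- as.numeric(frame_pixels(frame))
  if (length(x) < 2L) stop("frame must contain at least 2 pixels")
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 == 0) return(NA_real_)
  mean(d^3) / m2^1.5
}

#' Informative-frame filtering by histogram skewness
#'
#' Frames whose gray-level histogram skewness is higher than `threshold`
#' (default -5) are kept as informative; the rest -- in practice frames with a
#' saturated sensor, which concentrate intensity mass at the top of the range
#' -- are discarded. Zero-variance (constant) frames carry no diagnostic
#' texture and are discarded with reason `"zero_variance"`.
#'
#' Note that underexposed frames have strongly *positive* skewness and
#' therefore pass this filter: the rule is a one-sided threshold on skewness,
#' applied literally, and catches saturation-type artifacts only.
#'
#' @param frames A list of [cem_frame] objects (or intensity matrices).
#' @param threshold Keep a frame iff its skewness is strictly greater than
#'   this value. Default -5.
#'
#' @return A list with elements `kept` and `discarded` (sublists of `frames`,
#'   input order preserved) and `results`, a data frame with one row per input
#'   frame: `skewness`, `keep`, `reason` (`"kept"`, `"low_skewness"` or
#'   `"zero_variance"`).
#' @export
filter_frames <- function(frames, threshold = -5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  if (inherits(frames, "cem_frame") || is.matrix(frames)) frames <- list(frames)
  skew <- vapply(frames, histogram_skewness, numeric(1))
  keep <- !is.na(skew) & skew > threshold
  reason <- ifelse(keep, "kept", ifelse(is.na(skew), "zero_variance", "low_skewness"))
  list(kept = frames[keep],
       discarded = frames[!keep],
       results = data.frame(skewness = skew, keep = keep, reason = reason,
                            stringsAsFactors = FALSE))
}

#' Apply the skewness filter to a dataset manifest
#'
#' Reads each frame listed in the manifest, computes its histogram skewness
#' and appends `skewness`, `keep` and `reason` columns.
#'
#' @param manifest Data frame with at least a `path` column of PNG file paths.
#' @param threshold Passed to [filter_frames()].
#' @return The manifest with QC columns appended.
#' @export
qc_manifest <- function(manifest, threshold = -5) {
  stopifnot(is.data.frame(manifest), "path" %in% names(manifest))
  frames <- lapply(manifest$path, read_frame_png)
  res <- filter_frames(frames, threshold = threshold)$results
  cbind(manifest, res)
}
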