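#' @useDynLib cemclass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans predict rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

# Canonical class order used for confusion matrices and severity tie-breaks:
# most to least severe.
CEM_CLASS_ORDER <- c("cancer", "inflammation", "healthy")

#' Tissue class labels
#'
#' The three colonic tissue states the pipeline classifies, ordered from most
#' to least clinically severe. This order fixes both the layout of confusion
#' matrices (rows = predicted, columns = true) and the tie-break used by
#' [subject_majority_label()].
#'
#' @return Character vector `c("cancer", "inflammation", "healthy")`.
#' @export
cem_classes <- function() CEM_CLASS_ORDER

#' Construct a CEM frame
#'
#' A frame is one 8-bit grayscale endomicroscopy image plus its metadata:
#' the subject (mouse) it was acquired from, its tissue class, its ordinal
#' position in the acquisition sequence, and whether it is an artifact
#' (saturated/underexposed) frame.
#'
#' @param pixels Integer matrix of intensities in `[0, 255]`; rows are image
#'   rows (height), columns are image columns (width).
#' @param subject_id Character scalar identifying the subject.
#' @param class_label One of `"healthy"`, `"inflammation"`, `"cancer"`.
#' @param frame_index Integer ordinal of the frame within the subject's
#'   acquisition sequence.
#' @param is_artifact Logical; `TRUE` for non-informative artifact frames.
#'
#' @return An object of class `cem_frame`.
#' @export
cem_frame <- function(pixels, subject_id = "s1", class_label = "healthy",
                      frame_index = 1L, is_artifact = FALSE) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("pixel intensities must lie in [0, 255]")
  if (!class_label %in% CEM_CLASS_ORDER)
    stop("`class_label` must be one of: ", paste(CEM_CLASS_ORDER, collapse = ", "))
  structure(
    list(pixels = pixels,
         subject_id = as.character(subject_id),
         class_label = class_label,
         frame_index = as.integer(frame_index),
         is_artifact = isTRUE(is_artifact)),
    class = "cem_frame")
}

#' @export
print.cem_frame <- function(x, ...) {
  cat(sprintf("<cem_frame> %dx%d  subject=%s  class=%s  index=%d%s\n",
              nrow(x$pixels), ncol(x$pixels), x$subject_id, x$class_label,
              x$frame_index, if (x$is_artifact) "  [artifact]" else ""))
  invisible(x)
}

# Accept either a cem_frame or a bare matrix of intensities.
frame_pixels <- function(frame) {
  if (inherits(frame, "cem_frame")) return(frame$pixels)
  if (is.matrix(frame)) return(frame)
  stop("expected a `cem_frame` or an intensity matrix")
}

#' Read and write 8-bit grayscale frames as PNG
#'
#' Thin wrappers around the png package that preserve 8-bit intensities
#' exactly.
#'
#' @param path File path of the PNG image.
#' @return `read_frame_png()` returns an integer matrix in `[0, 255]`.
#' @export
read_frame_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]  # tolerate gray-encoded-as-RGB
  m <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  m
}

#' @rdname read_frame_png
#' @param pixels Integer matrix in `[0, 255]`.
#' @export
write_frame_png <- function(pixels, path) {
  storage.mode(pixels) <- "integer"
  png::writePNG(pixels / 255, path)
  invisible(path)
}
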