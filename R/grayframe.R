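#' Grayscale frame objects
#'
#' A `gray_frame` is the unit of analysis: a numeric matrix of luminance
#' values (nominal range 0--255) with 0-based pixel coordinates, origin at
#' the top-left, `x` indexing columns and `y` indexing rows.
#'
#' @param pixels numeric matrix, rows = image rows (top first), columns =
#'   image columns (left first). Values must be finite.
#' @return A `gray_frame` object (a classed numeric matrix).
#' @examples
#' f <- gray_frame(matrix(128, 40, 60))
#' dim(f)
#' @export
gray_frame <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("pixel values must be numeric")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("frame must be at least 1x1")
  }
  if (!all(is.finite(pixels))) stop("all luminance values must be finite")
  structure(pixels, class = c("gray_frame", "matrix"))
}

#' @export
print.gray_frame <- function(x, ...) {
  cat(sprintf("<gray_frame %d x %d px, mean luminance %.2f, range [%.1f, %.1f]>\n",
              ncol(x), nrow(x), mean(x), min(x), max(x)))
  invisible(x)
}

frame_width <- function(frame) ncol(frame)
frame_height <- function(frame) nrow(frame)

#' Convert a color raster to a grayscale frame
#'
#' Applies the ITU-R BT.601 luma weights (0.299 R + 0.587 G + 0.114 B).
#' Single-channel input passes through unchanged. The original acquisition
#' in this line of work used a monochrome camera, so any fixed convention
#' is acceptable; BT.601 is the conventional one for 8-bit video.
#'
#' @param x either a `gray_frame` / 2-D numeric matrix (returned as a
#'   `gray_frame` unchanged) or a 3-D array `height x width x 3` with
#'   channel values in \[0, 255\].
#' @return A [gray_frame].
#' @examples
#' arr <- array(0, c(2, 2, 3))
#' arr[, , 1] <- 100; arr[, , 2] <- 200; arr[, , 3] <- 50
#' to_grayscale(arr)[1, 1]  # 153.0
#' @export
to_grayscale <- function(x) {
  if (is.matrix(x)) return(gray_frame(x))
  if (is.array(x) && length(dim(x)) == 3L) {
    nc <- dim(x)[3L]
    if (nc == 1L) return(gray_frame(x[, , 1L]))
    if (nc != 3L) {
      stop(sprintf("expected 1 or 3 channels, got %d", nc))
    }
    if (min(x) < 0 || max(x) > 255) {
      stop("channel values must lie in [0, 255]")
    }
    return(gray_frame(0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]))
  }
  stop("input must be a 2-D matrix or a 3-D height x width x channels array")
}

#' Invert a frame photometrically
#'
#' Returns `255 - frame`. Under the center-surround analysis this swaps the
#' roles of ON and OFF exactly (the filter is antisymmetric in contrast
#' polarity).
#'
#' @param frame a [gray_frame].
#' @return The inverted [gray_frame].
#' @export
invert_frame <- function(frame) {
  gray_frame(255 - unclass(frame))
}
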