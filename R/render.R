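#' Render a segment as an RGB raster image
#'
#' Draws the waveform as a connected 1-px (by default) black polyline on a
#' white background with no axes, ticks or margins. The sample index maps
#' linearly to x in \[0, width - 1\]; the segment's own \[min, max\] maps linearly
#' to y in \[height - 1 - pad, pad\] with pad = 2 px (y inverted so larger
#' values sit higher). Rendering is deterministic and amplitude
#' scale-invariant (per-segment min-max y mapping). A constant segment is
#' drawn on the middle row.
#'
#' @param segment an `ecg_segment` (or any list with `samples`, `label`,
#'   `parent_id`, `segment_index`).
#' @param width,height raster dimensions in pixels (>= 16).
#' @param line_width stroke thickness in pixels.
#' @return A `signal_image`: list with `pixels` (height x width x 3 integer
#'   array, 0-255), `label`, `parent_id`, `segment_index`.
#' @export
render_segment <- function(segment, width = 200L, height = 200L, line_width = 1L) {
  s <- segment$samples
  if (length(s) == 0) stop("empty segment")
  if (width < 16 || height < 16) stop("width and height must be >= 16")
  pad <- 2L
  xs <- as.integer(round(seq(0, width - 1, length.out = length(s))))
  lo <- min(s); hi <- max(s)
  ys <- if (hi == lo) rep((height - 1L) %/% 2L, length(s))
        else as.integer(round((height - 1 - pad) - (s - lo) / (hi - lo) * (height - 1 - 2 * pad)))
  mask <- .draw_polyline_cpp(height, width, xs, ys, as.integer(line_width))
  px <- array(255L, dim = c(height, width, 3L))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[mask] <- 0L
    px[, , ch] <- plane
  }
  structure(list(pixels = px, label = segment$label,
                 parent_id = segment$parent_id,
                 segment_index = segment$segment_index),
            class = "signal_image")
}

#' @export
print.signal_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<signal_image %s_s%d> %dx%dx%d, label=%s\n",
              x$parent_id, x$segment_index, d[1], d[2], d[3], x$label))
  invisible(x)
}

#' Write / read a signal image as 8-bit RGB PNG
#'
#' @param image a `signal_image`.
#' @param path PNG file path; the conventional name is
#'   `{parent_id}_s{segment_index}.png`.
#' @return `write_signal_image()` returns `path` invisibly;
#'   `read_signal_image()` returns the height x width x 3 integer pixel array.
#' @export
write_signal_image <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' @rdname write_signal_image
#' @export
read_signal_image <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  array(as.integer(round(arr[, , 1:3] * 255)), dim = c(dim(arr)[1], dim(arr)[2], 3L))
}

#' Convert an RGB pixel array to grayscale luma in \[0, 1\]
#'
#' Fixed weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param pixels height x width x 3 array (0-255 integers or \[0,1\] reals).
#' @return height x width numeric matrix in \[0, 1\].
#' @export
rgb_to_gray <- function(pixels) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] >= 3)
  scale <- if (max(pixels) > 1) 255 else 1
  (0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]) / scale
}
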