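#' Moving-average denoising
#'
#' Centered moving average of odd window length with reflected boundary
#' padding, so the output has the same length as the input and a constant
#' signal passes through unchanged.
#'
#' @param samples numeric signal.
#' @param window odd positive window length, at most `length(samples)`.
#' @return Smoothed numeric vector of the same length.
#' @export
denoise <- function(samples, window = 5L) {
  n <- length(samples)
  if (window <= 0 || window %% 2 == 0) stop("window must be odd and positive")
  if (window > n) stop("window larger than signal")
  if (window == 1L) return(samples)
  r <- (window - 1L) %/% 2L
  # symmetric reflection: (x_r, ..., x_1), x, (x_n, ..., x_{n-r+1})
  padded <- c(samples[r:1], samples, samples[n:(n - r + 1L)])
  cs <- cumsum(c(0, padded))
  (cs[(window + 1L):(n + window)] - cs[1:n]) / window
}

#' Min-max normalization to \[0, 1\]
#'
#' Degenerate (constant) inputs map to 0.5 everywhere.
#'
#' @param samples non-empty numeric vector of finite values.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize <- function(samples) {
  if (length(samples) == 0) stop("empty input")
  if (any(!is.finite(samples))) stop("non-finite values in input")
  lo <- min(samples); hi <- max(samples)
  if (hi == lo) return(rep(0.5, length(samples)))
  (samples - lo) / (hi - lo)
}

#' Split a record into equal-length contiguous segments
#'
#' Produces `n_segments` non-overlapping segments of length
#' `floor(length / n_segments)` taken from the start of the record; trailing
#' remainder samples are discarded. A 65,535-sample record split six ways
#' yields six segments of 10,922 samples (3 samples dropped).
#'
#' @param record an `ecg_record` (or any list with `record_id`, `label`,
#'   `samples`).
#' @param n_segments number of segments (>= 1).
#' @return List of `ecg_segment`s: `parent_id`, `label`, `segment_index`
#'   (0-based), `samples`.
#' @export
segment_record <- function(record, n_segments = 6L) {
  L <- length(record$samples)
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (n_segments > L) stop("n_segments exceeds record length")
  seg_len <- L %/% n_segments
  lapply(seq_len(n_segments) - 1L, function(i) {
    structure(list(parent_id = record$record_id, label = record$label,
                   segment_index = i,
                   samples = record$samples[(i * seg_len + 1L):((i + 1L) * seg_len)]),
              class = "ecg_segment")
  })
}

#' Denoise, normalize and segment a set of records
#'
#' Applies the fixed pipeline order denoise -> normalize -> segment. The
#' record is normalized as a whole before segmentation, preserving relative
#' amplitude differences between its segments.
#'
#' @param records list of `ecg_record`s.
#' @param window denoising window (odd).
#' @param n_segments segments per record.
#' @return Flat list of `ecg_segment`s (length `n_segments * length(records)`).
#' @export
preprocess_records <- function(records, window = 5L, n_segments = 6L) {
  out <- lapply(records, function(r) {
    r$samples <- normalize(denoise(r$samples, window))
    segment_record(r, n_segments)
  })
  unlist(out, recursive = FALSE)
}
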