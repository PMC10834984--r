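# Shared fixtures: all generated in code, deterministically.

# Brute-force 26-neighbor extrema oracle over a H x W x L array.
extrema_oracle <- function(arr) {
  d <- dim(arr)
  out <- NULL
  for (l in 2:(d[3] - 1)) for (j in 2:(d[2] - 1)) for (i in 2:(d[1] - 1)) {
    nb <- arr[(i - 1):(i + 1), (j - 1):(j + 1), (l - 1):(l + 1)]
    v <- arr[i, j, l]
    others <- nb[-14] # center is element 14 in column-major 3x3x3
    if (all(v > others) || all(v < others))
      out <- rbind(out, c(row = i, col = j, level = l))
  }
  if (is.null(out)) out <- matrix(integer(), 0, 3,
                                  dimnames = list(NULL, c("row", "col", "level")))
  out
}

# Three-class separable blob images for classifier tests: class = location of
# a bright square on a noisy background.
blob_image <- function(cls, seed, size = 32L) {
  stopifnot(cls %in% 1:3)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  img <- array(runif(size * size * 3, 0, 0.2), dim = c(size, size, 3))
  pos <- list(c(6, 6), c(6, size - 10), c(size - 10, size %/% 2 - 3))[[cls]]
  sel_i <- pos[1]:(pos[1] + 6)
  sel_j <- pos[2]:(pos[2] + 6)
  img[sel_i, sel_j, ] <- img[sel_i, sel_j, ] + 0.8
  pmin(img, 1)
}

blob_dataset <- function(n_per_class = 20L, size = 32L) {
  x <- array(0, dim = c(size, size, 3L, 3L * n_per_class))
  y <- character(3 * n_per_class)
  i <- 0L
  for (cls in 1:3) for (r in seq_len(n_per_class)) {
    i <- i + 1L
    x[, , , i] <- blob_image(cls, 1000L * cls + r, size)
    y[i] <- c("A", "B", "C")[cls]
  }
  list(x = x, y = y)
}

# A small rendered ECG image fixture (deterministic).
render_fixture <- function(label = "ARR", seed = 3, width = 64L, height = 64L) {
  r <- generate_record(label, seed = seed, n_samples = 4096L, sampling_rate = 128)
  r$samples <- normalize(denoise(r$samples, 5L))
  seg <- segment_record(r, 6L)[[1]]
  render_segment(seg, width, height, 1L)
}

# Rotate an RGB pixel array 90 degrees counter-clockwise.
rot90_rgb <- function(px) {
  d <- dim(px)
  out <- array(0L, dim = c(d[2], d[1], d[3]))
  for (ch in seq_len(d[3]))
    out[, , ch] <- t(px[, , ch])[d[2]:1, ]
  out
}
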