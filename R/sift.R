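#' Two-dimensional Gaussian kernel function
#'
#' G(a, b, sigma) = exp(-(a^2 + b^2) / (2 sigma^2)) / (2 pi sigma^2), the
#' continuous kernel whose discrete, truncated, renormalized form blurs each
#' scale-space level.
#'
#' @param a,b spatial offsets.
#' @param sigma Gaussian scale (> 0).
#' @return Kernel value(s).
#' @export
gaussian_2d <- function(a, b, sigma) {
  exp(-(a^2 + b^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
}

#' Build a Gaussian scale-space pyramid
#'
#' Each octave holds `n_intervals + 3` progressively blurred versions of the
#' image; the blur of level i is `base_sigma * k^i` (in that octave's pixel
#' units) with `k = 2^(1/n_intervals)`. The next octave starts from the level
#' whose blur is `2 * base_sigma`, downsampled by taking every second pixel
#' (floor division). Kernels are truncated at a 3-sigma radius, renormalized
#' to sum 1, and applied with reflected borders, so a constant image is a
#' fixed point of every level.
#'
#' @param image grayscale matrix (values in \[0, 1\]), at least 16 x 16.
#' @param n_octaves number of octaves (>= 1).
#' @param n_intervals scales per octave (>= 1).
#' @param base_sigma blur of the first level (default 1.6).
#' @return A `scale_space`: list with `octaves` (list of lists of matrices),
#'   `sigmas_rel` (per-level blur in octave pixels), `sigmas_abs`
#'   (octave x level matrix of absolute scales), `k`, `n_intervals`,
#'   `base_sigma`.
#' @export
build_scale_space <- function(image, n_octaves = 4L, n_intervals = 3L,
                              base_sigma = 1.6) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 16 || ncol(image) < 16) stop("image must be at least 16x16")
  if (n_octaves < 1 || n_intervals < 1) stop("n_octaves and n_intervals must be >= 1")
  if (min(dim(image)) %/% 2^(n_octaves - 1) < 8)
    stop("image too small for ", n_octaves, " octaves")
  n_levels <- n_intervals + 3L
  k <- 2^(1 / n_intervals)
  sigmas_rel <- base_sigma * k^(seq_len(n_levels) - 1)
  # incremental blurs: level i from level i-1
  sig_inc <- c(base_sigma, sqrt(sigmas_rel[-1]^2 - sigmas_rel[-n_levels]^2))

  octaves <- vector("list", n_octaves)
  base <- image
  for (o in seq_len(n_octaves)) {
    levels <- vector("list", n_levels)
    levels[[1]] <- .blur_gaussian_cpp(base, sig_inc[1], as.integer(ceiling(3 * sig_inc[1])))
    for (i in 2:n_levels)
      levels[[i]] <- .blur_gaussian_cpp(levels[[i - 1]], sig_inc[i],
                                        as.integer(ceiling(3 * sig_inc[i])))
    octaves[[o]] <- levels
    if (o < n_octaves) {
      src <- levels[[n_intervals + 1L]] # blur 2*base_sigma in octave units
      base <- src[seq(1, nrow(src), by = 2), seq(1, ncol(src), by = 2), drop = FALSE]
    }
  }
  sigmas_abs <- outer(2^(seq_len(n_octaves) - 1), sigmas_rel)
  structure(list(octaves = octaves, sigmas_rel = sigmas_rel,
                 sigmas_abs = sigmas_abs, k = k, n_intervals = n_intervals,
                 base_sigma = base_sigma),
            class = "scale_space")
}

#' Difference-of-Gaussians stack
#'
#' Subtracts each Gaussian level from the next within every octave
#' (D_i = L_{i+1} - L_i), yielding `n_levels - 1` difference images per
#' octave — the band-pass stack whose scale-space extrema are keypoint
#' candidates.
#'
#' @param space a [build_scale_space()] result.
#' @return A `dog_stack`: list with `octaves` (list of H x W x (levels - 1)
#'   arrays) plus the scale bookkeeping of the input.
#' @export
compute_dog <- function(space) {
  octs <- lapply(space$octaves, function(levels) {
    if (length(levels) < 2) stop("octave has a single level")
    d <- dim(levels[[1]])
    arr <- array(0, dim = c(d[1], d[2], length(levels) - 1L))
    for (i in seq_len(length(levels) - 1L))
      arr[, , i] <- levels[[i + 1L]] - levels[[i]]
    arr
  })
  structure(list(octaves = octs, sigmas_rel = space$sigmas_rel,
                 k = space$k, n_intervals = space$n_intervals,
                 base_sigma = space$base_sigma),
            class = "dog_stack")
}

#' Detect scale-space extrema candidates
#'
#' A voxel is a candidate iff it is strictly greater than, or strictly smaller
#' than, all 26 neighbors in its 3 x 3 x 3 scale-space neighborhood. Border
#' voxels (spatial and scale) are excluded.
#'
#' @param dog a [compute_dog()] result.
#' @return data.frame with 1-based columns `octave`, `row`, `col`, `level`
#'   (level indexes the DoG stack).
#' @export
detect_extrema <- function(dog) {
  out <- lapply(seq_along(dog$octaves), function(o) {
    arr <- dog$octaves[[o]]
    if (dim(arr)[3] < 3) stop("need at least 3 DoG levels per octave")
    m <- .detect_extrema_cpp(arr)
    if (nrow(m) == 0) return(NULL)
    data.frame(octave = o, row = m[, 1] + 1L, col = m[, 2] + 1L,
               level = m[, 3] + 1L)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(octave = integer(), row = integer(), col = integer(),
                      level = integer())
  out
}

# Gradient and Hessian of the DoG stack at an interior voxel, by central
# finite differences over (row, col, level).
.dog_derivatives <- function(arr, i, j, l) {
  g <- c(
    (arr[i + 1, j, l] - arr[i - 1, j, l]) / 2,
    (arr[i, j + 1, l] - arr[i, j - 1, l]) / 2,
    (arr[i, j, l + 1] - arr[i, j, l - 1]) / 2)
  v <- arr[i, j, l]
  dii <- arr[i + 1, j, l] - 2 * v + arr[i - 1, j, l]
  djj <- arr[i, j + 1, l] - 2 * v + arr[i, j - 1, l]
  dll <- arr[i, j, l + 1] - 2 * v + arr[i, j, l - 1]
  dij <- (arr[i + 1, j + 1, l] - arr[i + 1, j - 1, l] -
          arr[i - 1, j + 1, l] + arr[i - 1, j - 1, l]) / 4
  dil <- (arr[i + 1, j, l + 1] - arr[i + 1, j, l - 1] -
          arr[i - 1, j, l + 1] + arr[i - 1, j, l - 1]) / 4
  djl <- (arr[i, j + 1, l + 1] - arr[i, j + 1, l - 1] -
          arr[i, j - 1, l + 1] + arr[i, j - 1, l - 1]) / 4
  list(g = g, H = matrix(c(dii, dij, dil, dij, djj, djl, dil, djl, dll), 3, 3),
       value = v)
}

#' Subpixel keypoint localization with contrast and edge rejection
#'
#' Fits the second-order Taylor expansion of the DoG stack around the
#' candidate voxel and solves for the offset of the true extremum. If any
#' offset component reaches 0.5 the candidate is re-centered on the
#' corresponding neighbor and the fit is repeated (at most `max_iter` times).
#' Accepted keypoints must have interpolated |D| at least
#' `contrast_threshold` and a spatial Hessian with
#' tr(H)^2 / det(H) < (r + 1)^2 / r (edge rejection).
#'
#' @param dog a [compute_dog()] result.
#' @param candidate one row of [detect_extrema()] output (list or 1-row
#'   data.frame with `octave`, `row`, `col`, `level`).
#' @param contrast_threshold minimum interpolated |D| (default 0.03 on
#'   \[0, 1\]-scaled images).
#' @param edge_r principal-curvature ratio bound r (default 10).
#' @param max_iter re-centering iteration limit.
#' @return A `sift_keypoint` (list with subpixel `x`, `y` at full image
#'   resolution, 0-based; `octave`, `interval`, `sigma`, `response`,
#'   `row`, `col` in octave coordinates) or `NULL` with attribute lost when
#'   rejected.
#' @export
localize_keypoint <- function(dog, candidate, contrast_threshold = 0.03,
                              edge_r = 10, max_iter = 5L) {
  arr <- dog$octaves[[candidate$octave]]
  d <- dim(arr)
  i <- candidate$row; j <- candidate$col; l <- candidate$level
  offset <- NULL
  for (iter in seq_len(max_iter)) {
    if (i < 2 || i > d[1] - 1 || j < 2 || j > d[2] - 1 || l < 2 || l > d[3] - 1)
      return(NULL) # drifted to the border
    der <- .dog_derivatives(arr, i, j, l)
    offset <- tryCatch(-solve(der$H, der$g), error = function(e) NULL)
    if (is.null(offset)) return(NULL) # singular Hessian
    if (all(abs(offset) < 0.5)) break
    i <- i + sign(offset[1]) * (abs(offset[1]) >= 0.5)
    j <- j + sign(offset[2]) * (abs(offset[2]) >= 0.5)
    l <- l + sign(offset[3]) * (abs(offset[3]) >= 0.5)
    if (iter == max_iter) return(NULL) # did not converge
  }
  value <- der$value + 0.5 * sum(der$g * offset)
  if (abs(value) < contrast_threshold) return(NULL)
  # edge rejection on the 2x2 spatial Hessian
  tr <- der$H[1, 1] + der$H[2, 2]
  det2 <- der$H[1, 1] * der$H[2, 2] - der$H[1, 2]^2
  if (det2 <= 0 || tr^2 / det2 >= (edge_r + 1)^2 / edge_r) return(NULL)

  o <- candidate$octave
  scale_fac <- 2^(o - 1)
  sigma <- dog$base_sigma * scale_fac * dog$k^((l - 1) + offset[3])
  structure(list(
    x = (j - 1 + offset[2]) * scale_fac,
    y = (i - 1 + offset[1]) * scale_fac,
    octave = o, interval = l,
    row = i - 1 + offset[1], col = j - 1 + offset[2],
    sigma = sigma, response = abs(value), orientation = NA_real_),
    class = "sift_keypoint")
}

# Gradient magnitude and (y-up) orientation of a Gaussian level at integer
# pixel positions rows/cols (1-based, interior).
.level_gradients <- function(L, rows, cols) {
  n <- nrow(L)
  idx <- cbind(rows, cols)
  dx <- L[cbind(rows, cols + 1L)] - L[cbind(rows, cols - 1L)]
  dy <- L[cbind(rows - 1L, cols)] - L[cbind(rows + 1L, cols)]
  list(mag = sqrt(dx^2 + dy^2), theta = atan2(dy, dx) %% (2 * pi))
}

#' Assign dominant gradient orientations to a keypoint
#'
#' Builds a 36-bin gradient-orientation histogram around the keypoint,
#' Gaussian-weighted with scale 1.5 x the keypoint's octave-relative sigma,
#' and emits one oriented keypoint per histogram peak reaching 80% of the
#' maximum, with parabolic peak interpolation.
#'
#' @param space the [build_scale_space()] pyramid.
#' @param kp a [localize_keypoint()] result.
#' @param n_bins histogram resolution (default 36).
#' @param peak_ratio secondary-peak acceptance ratio (default 0.8).
#' @return List of `sift_keypoint`s with `orientation` set (radians in
#'   \[0, 2 pi)); empty list if the keypoint's support falls outside the image.
#' @export
assign_orientations <- function(space, kp, n_bins = 36L, peak_ratio = 0.8) {
  L <- space$octaves[[kp$octave]][[min(kp$interval + 1L, length(space$sigmas_rel))]]
  sig_rel <- space$base_sigma * space$k^(kp$interval - 1)
  sig_w <- 1.5 * sig_rel
  r <- max(1L, as.integer(round(3 * sig_w)))
  ci <- round(kp$row) + 1L; cj <- round(kp$col) + 1L # 1-based center
  rows <- (ci - r):(ci + r); cols <- (cj - r):(cj + r)
  rows <- rows[rows >= 2 & rows <= nrow(L) - 1]
  cols <- cols[cols >= 2 & cols <= ncol(L) - 1]
  if (length(rows) == 0 || length(cols) == 0) return(list())
  grid <- expand.grid(row = rows, col = cols)
  gr <- .level_gradients(L, grid$row, grid$col)
  w <- gr$mag * exp(-((grid$row - ci)^2 + (grid$col - cj)^2) / (2 * sig_w^2))
  bin <- floor(gr$theta / (2 * pi) * n_bins) %% n_bins + 1L
  hist <- numeric(n_bins)
  agg <- rowsum(w, bin)
  hist[as.integer(rownames(agg))] <- agg
  if (all(hist == 0)) return(list())

  hmax <- max(hist)
  out <- list()
  for (b in seq_len(n_bins)) {
    lb <- if (b == 1) n_bins else b - 1L
    rb <- if (b == n_bins) 1L else b + 1L
    if (hist[b] >= peak_ratio * hmax && hist[b] > hist[lb] && hist[b] > hist[rb]) {
      denom <- hist[lb] - 2 * hist[b] + hist[rb]
      off <- if (denom == 0) 0 else 0.5 * (hist[lb] - hist[rb]) / denom
      theta <- ((b - 1 + 0.5 + off) * 2 * pi / n_bins) %% (2 * pi)
      k2 <- kp; k2$orientation <- theta
      out[[length(out) + 1L]] <- k2
    }
  }
  out
}

#' Compute the 128-dimensional keypoint descriptor
#'
#' Gradients in a window around the keypoint are rotated into the keypoint's
#' orientation frame and accumulated with trilinear interpolation into a
#' 4 x 4 spatial grid of 8-bin orientation histograms, Gaussian-weighted over
#' the window. The 128-vector is L2-normalized, clamped at 0.2 and
#' renormalized, giving illumination robustness.
#'
#' @param space the [build_scale_space()] pyramid.
#' @param kp an oriented `sift_keypoint`.
#' @param d spatial grid size (default 4).
#' @param n_ori orientation bins per cell (default 8).
#' @return Numeric vector of length `d^2 * n_ori` (128 by default) with unit
#'   L2 norm.
#' @export
compute_descriptor <- function(space, kp, d = 4L, n_ori = 8L) {
  if (is.na(kp$orientation)) stop("keypoint has no orientation; run assign_orientations()")
  L <- space$octaves[[kp$octave]][[min(kp$interval + 1L, length(space$sigmas_rel))]]
  sig_rel <- space$base_sigma * space$k^(kp$interval - 1)
  hist_width <- 3 * sig_rel
  radius <- as.integer(round(hist_width * sqrt(2) * (d + 1) / 2))
  ci <- round(kp$row) + 1L; cj <- round(kp$col) + 1L
  rows <- (ci - radius):(ci + radius); cols <- (cj - radius):(cj + radius)
  rows <- rows[rows >= 2 & rows <= nrow(L) - 1]
  cols <- cols[cols >= 2 & cols <= ncol(L) - 1]
  desc <- numeric(d * d * n_ori)
  if (length(rows) == 0 || length(cols) == 0)
    return(desc)
  grid <- expand.grid(row = rows, col = cols)
  gr <- .level_gradients(L, grid$row, grid$col)
  # offsets in octave pixels from the (subpixel) keypoint center;
  # u is the x offset (columns), v the y-up offset (rows inverted)
  u <- grid$col - 1 - kp$col
  v <- -(grid$row - 1 - kp$row)
  ct <- cos(kp$orientation); st <- sin(kp$orientation)
  u_rot <- (ct * u + st * v) / hist_width
  v_rot <- (-st * u + ct * v) / hist_width
  rbin <- v_rot + d / 2 - 0.5
  cbin <- u_rot + d / 2 - 0.5
  obin <- ((gr$theta - kp$orientation) %% (2 * pi)) / (2 * pi) * n_ori
  wgt <- gr$mag * exp(-(u_rot^2 + v_rot^2) / (2 * (0.5 * d)^2))
  keep <- rbin > -1 & rbin < d & cbin > -1 & cbin < d
  rbin <- rbin[keep]; cbin <- cbin[keep]; obin <- obin[keep]; wgt <- wgt[keep]
  if (length(wgt) == 0) return(desc)

  r0 <- floor(rbin); c0 <- floor(cbin); o0 <- floor(obin)
  fr <- rbin - r0; fc <- cbin - c0; fo <- obin - o0
  for (dr in 0:1) for (dc in 0:1) for (do in 0:1) {
    rr <- r0 + dr; cc <- c0 + dc; oo <- (o0 + do) %% n_ori
    wr <- if (dr == 0) 1 - fr else fr
    wc <- if (dc == 0) 1 - fc else fc
    wo <- if (do == 0) 1 - fo else fo
    ok <- rr >= 0 & rr < d & cc >= 0 & cc < d
    if (!any(ok)) next
    idx <- (rr[ok] * d + cc[ok]) * n_ori + oo[ok] + 1L
    contrib <- (wgt * wr * wc * wo)[ok]
    agg <- rowsum(contrib, idx)
    ai <- as.integer(rownames(agg))
    desc[ai] <- desc[ai] + agg
  }
  nrm <- sqrt(sum(desc^2))
  if (nrm > 0) desc <- desc / nrm
  desc <- pmin(desc, 0.2)
  nrm <- sqrt(sum(desc^2)) # norm of the clamped vector, exposed for checking
  if (nrm > 0) desc <- desc / nrm
  attr(desc, "clamp_norm") <- nrm
  desc
}

#' Detect keypoints and compute descriptors for a rendered image
#'
#' End-to-end composition: grayscale conversion (luma weights 0.299, 0.587,
#' 0.114), Gaussian pyramid, DoG, 26-neighbor extrema, subpixel localization
#' with contrast/edge rejection, orientation assignment, and descriptor
#' computation. Fully deterministic.
#'
#' @param image a `signal_image` or a height x width x 3 pixel array.
#' @param n_octaves,n_intervals,base_sigma pyramid parameters.
#' @param contrast_threshold,edge_r rejection thresholds.
#' @param descriptors if `FALSE`, skip descriptor computation (keypoints only).
#' @return List with `keypoints` (data.frame: `x`, `y`, `sigma`,
#'   `orientation`, `response`, `octave`, `interval`) and `descriptors`
#'   (n x 128 matrix, `NULL` when `descriptors = FALSE`).
#' @export
detect_and_describe <- function(image, n_octaves = 4L, n_intervals = 3L,
                                base_sigma = 1.6, contrast_threshold = 0.03,
                                edge_r = 10, descriptors = TRUE) {
  px <- if (inherits(image, "signal_image")) image$pixels else image
  gray <- rgb_to_gray(px)
  n_octaves <- min(n_octaves, max(1L, floor(log2(min(dim(gray)) / 8)) + 1L))
  space <- build_scale_space(gray, n_octaves, n_intervals, base_sigma)
  dog <- compute_dog(space)
  cand <- detect_extrema(dog)
  kps <- list()
  descs <- list()
  for (r in seq_len(nrow(cand))) {
    kp <- localize_keypoint(dog, cand[r, ], contrast_threshold, edge_r)
    if (is.null(kp)) next
    for (okp in assign_orientations(space, kp)) {
      kps[[length(kps) + 1L]] <- okp
      if (descriptors)
        descs[[length(descs) + 1L]] <- compute_descriptor(space, okp)
    }
  }
  if (length(kps) == 0) {
    return(list(keypoints = data.frame(x = numeric(), y = numeric(),
                                       sigma = numeric(), orientation = numeric(),
                                       response = numeric(), octave = integer(),
                                       interval = integer()),
                descriptors = if (descriptors) matrix(0, 0, 128) else NULL))
  }
  keypoints <- do.call(rbind, lapply(kps, function(k)
    data.frame(x = k$x, y = k$y, sigma = k$sigma, orientation = k$orientation,
               response = k$response, octave = k$octave, interval = k$interval)))
  list(keypoints = keypoints,
       descriptors = if (descriptors) do.call(rbind, descs) else NULL)
}

# Integer circle outline (midpoint algorithm) around 0-based center, returns
# cbind(row, col) 0-based offsets applied to the center.
.circle_points <- function(cx, cy, radius) {
  if (radius <= 0) return(cbind(row = cy, col = cx))
  x <- radius; y <- 0; err <- 1 - radius
  pts <- list()
  while (x >= y) {
    pts[[length(pts) + 1L]] <- rbind(
      c(cy + y, cx + x), c(cy + x, cx + y), c(cy + x, cx - y), c(cy + y, cx - x),
      c(cy - y, cx - x), c(cy - x, cx - y), c(cy - x, cx + y), c(cy - y, cx + x))
    y <- y + 1
    if (err < 0) err <- err + 2 * y + 1 else { x <- x - 1; err <- err + 2 * (y - x) + 1 }
  }
  m <- unique(do.call(rbind, pts))
  colnames(m) <- c("row", "col")
  m
}

#' Overlay detected keypoints on an image
#'
#' Draws each keypoint as a red circle of radius `round(sigma)` with a 1-px
#' stroke. The input is not modified; dimensions are preserved. This overlaid
#' raster is the fused feature+image input given to the CNN.
#'
#' @param image a `signal_image`.
#' @param keypoints data.frame with `x`, `y`, `sigma` (as produced by
#'   [detect_and_describe()]).
#' @return A new `signal_image` with the circles drawn.
#' @export
overlay_keypoints <- function(image, keypoints) {
  px <- image$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  for (r in seq_len(nrow(keypoints))) {
    pts <- .circle_points(round(keypoints$x[r]), round(keypoints$y[r]),
                          round(keypoints$sigma[r]))
    ok <- pts[, "row"] >= 0 & pts[, "row"] < H & pts[, "col"] >= 0 & pts[, "col"] < W
    pts <- pts[ok, , drop = FALSE]
    if (nrow(pts) == 0) next
    px[cbind(pts[, "row"] + 1L, pts[, "col"] + 1L, 1L)] <- 255L
    px[cbind(pts[, "row"] + 1L, pts[, "col"] + 1L, 2L)] <- 0L
    px[cbind(pts[, "row"] + 1L, pts[, "col"] + 1L, 3L)] <- 0L
  }
  out <- image
  out$pixels <- px
  out
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Unsigned gradients (0-180 degrees) are accumulated into per-cell
#' histograms with linear interpolation between adjacent orientation bins;
#' overlapping blocks of cells are L2-normalized (with an epsilon guard) and
#' concatenated.
#'
#' @param image a `signal_image` or height x width x 3 array; dimensions must
#'   be divisible by `cell_px`.
#' @param cell_px cell side in pixels.
#' @param block_cells block side in cells.
#' @param stride_cells block stride in cells.
#' @param n_bins orientation bins over \[0, 180).
#' @param eps normalization guard.
#' @return A `hog_descriptor`: list with `values` (numeric vector) and
#'   `geometry`.
#' @export
compute_hog <- function(image, cell_px = 8L, block_cells = 2L,
                        stride_cells = 1L, n_bins = 9L, eps = 1e-6) {
  px <- if (inherits(image, "signal_image")) image$pixels else image
  gray <- rgb_to_gray(px)
  H <- nrow(gray); W <- ncol(gray)
  if (H %% cell_px != 0 || W %% cell_px != 0)
    stop("image dimensions must be divisible by cell_px")
  # central differences, zero at borders
  dx <- matrix(0, H, W); dy <- matrix(0, H, W)
  dx[, 2:(W - 1)] <- (gray[, 3:W] - gray[, 1:(W - 2)]) / 2
  dy[2:(H - 1), ] <- (gray[3:H, ] - gray[1:(H - 2), ]) / 2
  mag <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 180

  nci <- H %/% cell_px; ncj <- W %/% cell_px
  bin_w <- 180 / n_bins
  b <- theta / bin_w - 0.5
  b0 <- floor(b)
  f <- b - b0
  cell_i <- (row(gray) - 1L) %/% cell_px
  cell_j <- (col(gray) - 1L) %/% cell_px
  hist <- array(0, dim = c(nci, ncj, n_bins))
  acc <- function(bins, w) {
    bins <- bins %% n_bins
    idx <- cell_i + cell_j * nci + bins * nci * ncj + 1
    agg <- rowsum(as.vector(w), as.vector(idx))
    hist[as.integer(rownames(agg))] <<- hist[as.integer(rownames(agg))] + agg
  }
  acc(b0, mag * (1 - f))
  acc(b0 + 1, mag * f)

  nbi <- (nci - block_cells) %/% stride_cells + 1L
  nbj <- (ncj - block_cells) %/% stride_cells + 1L
  values <- numeric(nbi * nbj * block_cells^2 * n_bins)
  pos <- 0L
  blk_len <- block_cells^2 * n_bins
  for (bj in seq_len(nbj)) for (bi in seq_len(nbi)) {
    ri <- (bi - 1L) * stride_cells + seq_len(block_cells)
    rj <- (bj - 1L) * stride_cells + seq_len(block_cells)
    v <- as.vector(hist[ri, rj, ])
    values[pos + seq_len(blk_len)] <- v / sqrt(sum(v^2) + eps^2)
    pos <- pos + blk_len
  }
  structure(list(values = values,
                 geometry = list(cell_px = cell_px, block_cells = block_cells,
                                 stride_cells = stride_cells, n_bins = n_bins,
                                 n_blocks = c(nbi, nbj))),
            class = "hog_descriptor")
}
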