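test_that("the Gaussian kernel function matches its closed form", {
  expect_equal(gaussian_2d(0, 0, 1), 1 / (2 * pi), tolerance = 1e-12)
  expect_equal(gaussian_2d(1, 2, 2), exp(-5 / 8) / (8 * pi), tolerance = 1e-12)
})

test_that("scale-space construction follows the level/sigma conventions", {
  ss <- build_scale_space(matrix(runif(32 * 32), 32), n_octaves = 2L,
                          n_intervals = 3L, base_sigma = 1.6)
  expect_equal(ss$k, 2^(1 / 3), tolerance = 1e-12)
  expect_length(ss$octaves[[1]], 6L) # n_intervals + 3
  expect_equal(ss$sigmas_rel, 1.6 * 2^((0:5) / 3), tolerance = 1e-12)
  expect_true(all(diff(ss$sigmas_rel) > 0))
  # spatial halving between octaves
  expect_equal(dim(ss$octaves[[2]][[1]]), c(16L, 16L))
  expect_error(build_scale_space(matrix(0.5, 10, 10)), "16x16")
  expect_error(build_scale_space(matrix(0.5, 20, 20), n_octaves = 4L), "octaves")
})

test_that("a constant image is a fixed point of every scale-space level", {
  ss <- build_scale_space(matrix(0.37, 24, 24), n_octaves = 2L, n_intervals = 3L)
  for (o in 1:2) for (lev in ss$octaves[[o]])
    expect_equal(max(abs(lev - 0.37)), 0, tolerance = 1e-12)
})

test_that("DoG equals elementwise subtraction of adjacent levels", {
  set.seed(8)
  ss <- build_scale_space(matrix(runif(24 * 24), 24), n_octaves = 2L,
                          n_intervals = 2L)
  dog <- compute_dog(ss)
  expect_equal(dim(dog$octaves[[1]])[3], length(ss$octaves[[1]]) - 1L)
  for (o in 1:2) for (i in seq_len(dim(dog$octaves[[o]])[3]))
    expect_equal(dog$octaves[[o]][, , i],
                 ss$octaves[[o]][[i + 1]] - ss$octaves[[o]][[i]],
                 tolerance = 1e-14)
  # constant image: all differences vanish
  dc <- compute_dog(build_scale_space(matrix(1, 16, 16), 1L, 3L))
  expect_equal(max(abs(dc$octaves[[1]])), 0, tolerance = 1e-14)
})

test_that("extrema detection matches the exhaustive 26-neighbor oracle", {
  set.seed(31)
  shapes <- list(c(20, 20, 3), c(12, 16, 4), c(32, 32, 5))
  for (sh in shapes) {
    arr <- array(rnorm(prod(sh)), dim = sh)
    dog <- structure(list(octaves = list(arr), sigmas_rel = 1:5, k = 2^(1 / 3),
                          n_intervals = 3L, base_sigma = 1.6),
                     class = "dog_stack")
    got <- detect_extrema(dog)
    want <- extrema_oracle(arr)
    expect_equal(nrow(got), nrow(want))
    expect_equal(as.matrix(got[, c("row", "col", "level")]), want,
                 ignore_attr = TRUE)
  }
  # degenerate cases
  flat <- structure(list(octaves = list(array(1, c(8, 8, 3)))), class = "dog_stack")
  expect_equal(nrow(detect_extrema(flat)), 0L)
  spike <- array(0, c(8, 8, 3)); spike[4, 5, 2] <- 1
  one <- detect_extrema(structure(list(octaves = list(spike)), class = "dog_stack"))
  expect_equal(nrow(one), 1L)
  expect_equal(unlist(one[1, c("row", "col", "level")]), c(4, 5, 2),
               ignore_attr = TRUE)
})

# Quadratic DoG stack with analytic optimum at integer voxel + offset.
quadratic_stack <- function(center, offset, curv = c(0.5, 0.4, 0.3),
                            peak = 0.2, dims = c(11, 11, 5)) {
  arr <- array(0, dim = dims)
  for (l in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    u <- c(i, j, l) - center - offset
    arr[i, j, l] <- peak - sum(curv * u^2)
  }
  arr
}

test_that("Taylor localization recovers an analytic optimum to 1e-6", {
  off <- c(0.3, -0.2, 0.1)
  arr <- quadratic_stack(center = c(6, 6, 3), offset = off)
  dog <- structure(list(octaves = list(arr), base_sigma = 1.6, k = 2^(1 / 3)),
                   class = "dog_stack")
  kp <- localize_keypoint(dog, list(octave = 1L, row = 6L, col = 6L, level = 3L))
  expect_false(is.null(kp))
  expect_equal(kp$row, 5 + off[1], tolerance = 1e-6)   # 0-based
  expect_equal(kp$col, 5 + off[2], tolerance = 1e-6)
  expect_equal(kp$x, 5 + off[2], tolerance = 1e-6)     # octave 1: full resolution
  expect_equal(kp$y, 5 + off[1], tolerance = 1e-6)
  expect_equal(kp$response, 0.2, tolerance = 1e-6)
  expect_equal(kp$sigma, 1.6 * (2^(1 / 3))^(2 + off[3]), tolerance = 1e-5)
})

test_that("localization re-centers when the offset exceeds half a voxel", {
  off <- c(0.3, -0.2, 0.1)
  arr <- quadratic_stack(center = c(7, 6, 3), offset = off) # optimum 1 row away
  dog <- structure(list(octaves = list(arr), base_sigma = 1.6, k = 2^(1 / 3)),
                   class = "dog_stack")
  kp <- localize_keypoint(dog, list(octave = 1L, row = 6L, col = 6L, level = 3L))
  expect_false(is.null(kp))
  expect_equal(kp$row, 6 + off[1], tolerance = 1e-6)
})

test_that("poor-contrast and edge-like candidates are rejected", {
  # same quadratic but with |D| at the optimum below the 0.03 threshold
  weak <- quadratic_stack(center = c(6, 6, 3), offset = c(0, 0, 0), peak = 0.02)
  dog_w <- structure(list(octaves = list(weak), base_sigma = 1.6, k = 2^(1 / 3)),
                     class = "dog_stack")
  expect_null(localize_keypoint(dog_w, list(octave = 1L, row = 6L, col = 6L,
                                            level = 3L)))
  # ridge: one strong and one tiny spatial curvature
  ridge <- quadratic_stack(center = c(6, 6, 3), offset = c(0, 0, 0),
                           curv = c(0.5, 0.001, 0.3))
  dog_r <- structure(list(octaves = list(ridge), base_sigma = 1.6, k = 2^(1 / 3)),
                     class = "dog_stack")
  expect_null(localize_keypoint(dog_r, list(octave = 1L, row = 6L, col = 6L,
                                            level = 3L)))
})

fake_kp <- function(row, col, octave = 1L, interval = 2L, space = NULL) {
  sigma <- 1.6 * (2^(1 / 3))^(interval - 1)
  structure(list(x = col, y = row, octave = octave, interval = interval,
                 row = row, col = col, sigma = sigma, response = 1,
                 orientation = NA_real_), class = "sift_keypoint")
}

test_that("a uniform gradient yields a single orientation at its angle", {
  # ramp increasing along +x: gradient angle 0
  img <- matrix(rep(seq(0, 1, length.out = 48), each = 48), 48, byrow = FALSE)
  img <- t(img) * 0 + matrix(seq(0, 1, length.out = 48), 48, 48, byrow = TRUE)
  ss <- build_scale_space(img, 1L, 3L)
  oriented <- assign_orientations(ss, fake_kp(24, 24))
  expect_length(oriented, 1L)
  th <- oriented[[1]]$orientation
  bin_w <- 2 * pi / 36
  expect_lt(min(abs(th), abs(th - 2 * pi)), bin_w)

  # ramp increasing down the rows: y-up gradient angle 3*pi/2
  img2 <- matrix(seq(0, 1, length.out = 48), 48, 48, byrow = FALSE)
  ss2 <- build_scale_space(img2, 1L, 3L)
  oriented2 <- assign_orientations(ss2, fake_kp(24, 24))
  expect_length(oriented2, 1L)
  expect_lt(abs(oriented2[[1]]$orientation - 3 * pi / 2), bin_w)
})

test_that("two equal orthogonal gradient populations emit two keypoints", {
  # f = max(col, row)/n: gradient +x where col > row, +row (y-down) where
  # row > col — equal slopes, orthogonal directions, continuous at the seam
  n <- 48
  img <- outer(seq_len(n), seq_len(n), function(i, j) pmax(i, j)) / n
  ss <- build_scale_space(img, 1L, 3L)
  oriented <- assign_orientations(ss, fake_kp(24, 24))
  expect_equal(length(oriented), 2L)
  ths <- vapply(oriented, `[[`, 0, "orientation")
  bin_w <- 2 * pi / 36
  circ_d <- function(a, b) pmin(abs(a - b), 2 * pi - abs(a - b))
  # one orientation near 0 (gradient +x), the other near 270 deg (y-down)
  expect_lt(min(circ_d(ths, 0)), bin_w)
  expect_lt(min(circ_d(ths, 3 * pi / 2)), bin_w)
})

test_that("descriptors satisfy the 128-d normalization and clamp contract", {
  img <- render_fixture("ARR", seed = 3)
  ft <- detect_and_describe(img)
  expect_gte(nrow(ft$keypoints), 1L)
  expect_equal(ncol(ft$descriptors), 128L)
  nrms <- sqrt(rowSums(ft$descriptors^2))
  expect_true(all(abs(nrms - 1) < 1e-9))
  expect_true(all(ft$descriptors >= 0))
  # clamp: before the final renormalization no element exceeded 0.2
  gray <- rgb_to_gray(img$pixels)
  ss <- build_scale_space(gray, 3L, 3L)
  kp <- fake_kp(round(ft$keypoints$y[1]), round(ft$keypoints$x[1]),
                octave = ft$keypoints$octave[1],
                interval = ft$keypoints$interval[1])
  kp$orientation <- ft$keypoints$orientation[1]
  d <- compute_descriptor(ss, kp)
  pre <- as.numeric(d) * attr(d, "clamp_norm")
  expect_true(all(pre <= 0.2 + 1e-9))
})

test_that("descriptors are invariant to global intensity scaling", {
  img <- render_fixture("NSR", seed = 5)
  gray <- rgb_to_gray(img$pixels)
  ss1 <- build_scale_space(gray, 2L, 3L)
  ss2 <- build_scale_space(0.5 * gray, 2L, 3L)
  kp <- fake_kp(30, 30)
  o1 <- assign_orientations(ss1, kp)
  o2 <- assign_orientations(ss2, kp)
  expect_equal(length(o1), length(o2))
  if (length(o1) > 0) {
    d1 <- compute_descriptor(ss1, o1[[1]])
    d2 <- compute_descriptor(ss2, o2[[1]])
    expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-6)
  }
})

test_that("keypoints and descriptors track a 90-degree rotation", {
  img <- render_fixture("ARR", seed = 9, width = 64L, height = 64L)
  ft1 <- detect_and_describe(img)
  rot <- img
  rot$pixels <- rot90_rgb(img$pixels)
  ft2 <- detect_and_describe(rot)
  expect_gte(nrow(ft1$keypoints), 1L)
  # counter-clockwise rotation maps (x, y) -> (y, W - 1 - x)
  W <- dim(img$pixels)[2]
  n_match <- 0L; sims <- c(); dtheta <- c()
  for (i in seq_len(nrow(ft1$keypoints))) {
    ex <- ft1$keypoints$y[i]
    ey <- W - 1 - ft1$keypoints$x[i]
    dd <- sqrt((ft2$keypoints$x - ex)^2 + (ft2$keypoints$y - ey)^2)
    j <- which.min(dd)
    if (length(j) == 1 && dd[j] < 2) {
      n_match <- n_match + 1L
      sims <- c(sims, sum(ft1$descriptors[i, ] * ft2$descriptors[j, ]))
      dtheta <- c(dtheta, (ft2$keypoints$orientation[j] -
                             ft1$keypoints$orientation[i]) %% (2 * pi))
    }
  }
  expect_gte(n_match, 1L)
  expect_gt(median(sims), 0.9)
  # orientations rotate by +pi/2 (mod 2pi) within a bin width or so
  err <- pmin(abs(dtheta - pi / 2), abs(dtheta - pi / 2 - 2 * pi),
              abs(dtheta - pi / 2 + 2 * pi))
  expect_lt(median(err), 2 * pi / 18)
})

test_that("detection is deterministic and empty on blank images", {
  blank <- structure(list(pixels = array(255L, c(48, 48, 3)), label = "NSR",
                          parent_id = "b", segment_index = 0L),
                     class = "signal_image")
  expect_equal(nrow(detect_and_describe(blank)$keypoints), 0L)
  img <- render_fixture("CHF", seed = 2)
  a <- detect_and_describe(img)
  b <- detect_and_describe(img)
  expect_identical(a$keypoints, b$keypoints)
  expect_identical(a$descriptors, b$descriptors)
})

test_that("2x upsampling shifts keypoints by about one octave", {
  img <- render_fixture("ARR", seed = 12, width = 64L, height = 64L)
  big <- img
  idx <- rep(1:64, each = 2)
  big$pixels <- img$pixels[idx, idx, , drop = FALSE]
  ft1 <- detect_and_describe(img, descriptors = FALSE)
  ft2 <- detect_and_describe(big, descriptors = FALSE)
  n_match <- 0L; ratios <- c()
  for (i in seq_len(nrow(ft1$keypoints))) {
    dd <- sqrt((ft2$keypoints$x - 2 * ft1$keypoints$x[i])^2 +
               (ft2$keypoints$y - 2 * ft1$keypoints$y[i])^2)
    j <- which.min(dd)
    if (length(j) == 1 && dd[j] < 4) {
      n_match <- n_match + 1L
      ratios <- c(ratios, ft2$keypoints$sigma[j] / ft1$keypoints$sigma[i])
    }
  }
  expect_gte(n_match, ceiling(nrow(ft1$keypoints) / 2))
  expect_lt(abs(median(ratios) - 2), 0.4) # sigma ratio ~2 within 20%
})

test_that("keypoint overlay draws only the circle pixels", {
  img <- render_fixture("NSR", seed = 1, width = 200L, height = 200L)
  same <- overlay_keypoints(img, data.frame(x = numeric(), y = numeric(),
                                            sigma = numeric()))
  expect_identical(same$pixels, img$pixels)
  one <- overlay_keypoints(img, data.frame(x = 100, y = 100, sigma = 3))
  expect_equal(dim(one$pixels), c(200L, 200L, 3L))
  diff_mask <- apply(one$pixels != img$pixels, c(1, 2), any)
  pts <- which(diff_mask, arr.ind = TRUE)
  expect_gt(nrow(pts), 0)
  radii <- sqrt((pts[, 1] - 101)^2 + (pts[, 2] - 101)^2)
  expect_true(all(abs(radii - 3) < 1.2)) # 1-px stroke on the radius-3 circle
  # the input image is unmodified
  expect_true(all(img$pixels[cbind(pts[, 1], pts[, 2], 1)] %in% c(0L, 255L)))
})

test_that("HOG geometry, degenerate input and edge response are correct", {
  img <- structure(list(pixels = array(255L, c(200, 200, 3))), class = "signal_image")
  h <- compute_hog(img, cell_px = 8L, block_cells = 2L, stride_cells = 1L,
                   n_bins = 9L)
  expect_length(h$values, (25 - 1)^2 * 4 * 9) # 20,736
  expect_true(all(h$values == 0)) # constant image, epsilon guard
  # block norms bounded
  img2 <- render_fixture("ARR", seed = 4, width = 64L, height = 64L)
  h2 <- compute_hog(img2, cell_px = 8L)
  blk <- matrix(h2$values, nrow = 4 * 9)
  expect_true(all(colSums(blk^2) <= 1 + 1e-6))
  # vertical step edge -> horizontal gradient -> mass at the 0-degree wrap bins
  # (block vectors are laid out cell-major within each orientation bin)
  px <- array(0L, c(32, 32, 3)); px[, 17:32, ] <- 255L
  h3 <- compute_hog(structure(list(pixels = px), class = "signal_image"),
                    cell_px = 8L, n_bins = 9L)
  cellsums <- colSums(matrix(h3$values, nrow = 4))
  mass <- tapply(cellsums, rep(1:9, length.out = length(cellsums)), sum)
  expect_gt((mass[1] + mass[9]) / sum(mass), 0.9)
  expect_error(compute_hog(img2, cell_px = 7L), "divisible")
})
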