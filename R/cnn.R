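#' Specification of the compact convolutional classifier
#'
#' Three blocks of (3 x 3 valid convolution with 32 filters + ReLU, 2 x 2
#' stride-2 max pooling), then flatten, dropout 0.5, a 64-unit ReLU dense
#' layer and a softmax output over the classes — trained with Adam on
#' categorical cross-entropy, batch size 16, 30 epochs by default. With
#' 200 x 200 x 3 inputs the spatial trace is
#' 200 -> 198 -> 99 -> 97 -> 48 -> 46 -> 23, so the flattened width is
#' 23 * 23 * 32 = 16,928.
#'
#' @param input_shape c(height, width, channels).
#' @param n_classes output classes.
#' @param n_filters filters per conv layer.
#' @param kernel conv kernel side.
#' @param n_blocks conv/pool blocks.
#' @param hidden width of the dense ReLU layer.
#' @param dropout dropout rate in [0, 1).
#' @param epochs,batch_size,lr,beta1,beta2,epsilon training hyperparameters
#'   (Adam defaults lr 0.001, beta1 0.9, beta2 0.999).
#' @return A `cnn_spec`.
#' @export
cnn_spec <- function(input_shape = c(200L, 200L, 3L), n_classes = 3L,
                     n_filters = 32L, kernel = 3L, n_blocks = 3L,
                     hidden = 64L, dropout = 0.5, epochs = 30L,
                     batch_size = 16L, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, epsilon = 1e-8) {
  stopifnot(length(input_shape) == 3, dropout >= 0, dropout < 1,
            n_blocks >= 1, n_classes >= 2)
  trace <- spatial_trace(input_shape[1:2], kernel, n_blocks)
  if (any(trace$dims <= 0)) stop("input smaller than the receptive chain allows")
  structure(list(input_shape = as.integer(input_shape), n_classes = as.integer(n_classes),
                 n_filters = as.integer(n_filters), kernel = as.integer(kernel),
                 n_blocks = as.integer(n_blocks), hidden = as.integer(hidden),
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon),
            class = "cnn_spec")
}

#' Spatial dimension trace through the conv/pool chain
#'
#' @param hw c(height, width) of the input.
#' @param kernel conv kernel side (valid padding).
#' @param n_blocks number of conv+pool blocks.
#' @return List with `dims` (matrix of dimensions after each layer) and
#'   `flatten` width given `n_filters` = attribute use via [flatten_width()].
#' @export
spatial_trace <- function(hw, kernel = 3L, n_blocks = 3L) {
  dims <- matrix(hw, nrow = 1)
  cur <- hw
  for (b in seq_len(n_blocks)) {
    cur <- cur - (kernel - 1L)      # valid convolution
    dims <- rbind(dims, cur)
    cur <- cur %/% 2L               # floor 2x2/2 pooling
    dims <- rbind(dims, cur)
  }
  rownames(dims) <- NULL
  list(dims = dims, final = cur)
}

#' Flattened width before the dense layers
#'
#' @param spec a [cnn_spec()].
#' @return Integer: final height x width x n_filters.
#' @export
flatten_width <- function(spec) {
  fin <- spatial_trace(spec$input_shape[1:2], spec$kernel, spec$n_blocks)$final
  as.integer(fin[1] * fin[2] * spec$n_filters)
}

#' Build (initialize) an untrained CNN
#'
#' Glorot-uniform weight initialization driven by `seed`.
#'
#' @param spec a [cnn_spec()].
#' @param seed integer seed for the initialization.
#' @return A `cnn_model`: list with `spec`, `weights`, `adam` (empty), `t`,
#'   `history`, `seed`.
#' @export
build_cnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(seed, {
    Wc <- list(); bc <- list()
    c_in <- spec$input_shape[3]
    for (b in seq_len(spec$n_blocks)) {
      K <- spec$kernel^2 * c_in
      Wc[[b]] <- glorot(spec$n_filters, K, K, spec$n_filters)
      bc[[b]] <- numeric(spec$n_filters)
      c_in <- spec$n_filters
    }
    fw <- flatten_width(spec)
    weights <- list(
      Wc = Wc, bc = bc,
      Wd = glorot(spec$hidden, fw, fw, spec$hidden),
      bd = numeric(spec$hidden),
      Wo = glorot(spec$n_classes, spec$hidden, spec$hidden, spec$n_classes),
      bo = numeric(spec$n_classes),
      kernel = spec$kernel)
    structure(list(spec = spec, weights = weights, adam = list(), t = 0L,
                   history = data.frame(epoch = integer(), loss = numeric(),
                                        accuracy = numeric()),
                   seed = seed, classes = NULL),
              class = "cnn_model")
  })
}

#' Layer-by-layer architecture summary
#'
#' @param model a `cnn_model` (or a `cnn_spec`).
#' @return Character vector, one line per layer.
#' @export
cnn_layer_summary <- function(model) {
  spec <- if (inherits(model, "cnn_model")) model$spec else model
  tr <- spatial_trace(spec$input_shape[1:2], spec$kernel, spec$n_blocks)$dims
  lines <- sprintf("input %dx%dx%d", spec$input_shape[1], spec$input_shape[2],
                   spec$input_shape[3])
  row <- 1L
  for (b in seq_len(spec$n_blocks)) {
    row <- row + 1L
    lines <- c(lines, sprintf("conv2d %d filters %dx%d valid relu -> %dx%dx%d",
                              spec$n_filters, spec$kernel, spec$kernel,
                              tr[row, 1], tr[row, 2], spec$n_filters))
    row <- row + 1L
    lines <- c(lines, sprintf("maxpool 2x2 stride 2 -> %dx%dx%d",
                              tr[row, 1], tr[row, 2], spec$n_filters))
  }
  c(lines,
    sprintf("flatten -> %d", flatten_width(spec)),
    sprintf("dropout rate %.2f", spec$dropout),
    sprintf("dense %d relu", spec$hidden),
    sprintf("dense %d softmax", spec$n_classes))
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model>\n")
  cat(paste0("  ", cnn_layer_summary(x), collapse = "\n"), "\n")
  cat(sprintf("  trained epochs: %d\n", nrow(x$history)))
  invisible(x)
}

#' Train the CNN with minibatch Adam
#'
#' Runs `spec$epochs` passes with per-epoch shuffling and dropout both driven
#' by `seed`, so results are reproducible bit-for-bit. Aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param model a [build_cnn()] result.
#' @param x numeric array (height, width, channels, n) of inputs in \[0, 1\].
#' @param y class labels: factor/character, or an n x K one-hot matrix.
#' @param seed integer seed for shuffling/dropout.
#' @param epochs optional override of `spec$epochs`.
#' @param verbose print per-epoch loss/accuracy.
#' @return The trained `cnn_model` with `history` filled (one row per epoch).
#' @export
train_cnn <- function(model, x, y, seed = 1L, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  spec <- model$spec
  dims <- dim(x)
  if (length(dims) != 4 || !all(dims[1:3] == spec$input_shape))
    stop("input array must be (", paste(spec$input_shape, collapse = ", "), ", n)")
  n <- dims[4]
  if (n == 0) stop("empty training data")
  if (is.matrix(y)) {
    classes <- colnames(y)
    if (is.null(classes)) classes <- as.character(seq_len(ncol(y)))
    yi <- max.col(y, ties.method = "first") - 1L
  } else {
    yf <- factor(y)
    classes <- levels(yf)
    yi <- as.integer(yf) - 1L
  }
  if (length(yi) != n) stop("labels do not match the number of images")
  if (length(classes) > spec$n_classes) stop("more classes than output units")
  model$classes <- classes
  n_epochs <- if (is.null(epochs)) spec$epochs else as.integer(epochs)
  if (n_epochs == 0) return(model)

  with_seed(seed, {
    for (e in seq_len(n_epochs)) {
      ord <- sample.int(n) - 1L
      dropout_seed <- sample.int(.Machine$integer.max - 1L, 1)
      res <- .cnn_epoch_cpp(x, yi, model$weights, model$adam,
                            spec$lr, spec$beta1, spec$beta2, spec$epsilon,
                            spec$batch_size, ord, spec$dropout,
                            dropout_seed, model$t)
      if (!is.finite(res$loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d", e))
      model$weights <- res$weights
      model$adam <- res$adam
      model$t <- res$t
      model$history <- rbind(model$history,
                             data.frame(epoch = nrow(model$history) + 1L,
                                        loss = res$loss, accuracy = res$acc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.4f", e, res$loss, res$acc))
    }
  })
  model
}

#' Predict class probabilities and labels
#'
#' @param model a trained `cnn_model`.
#' @param x numeric array (height, width, channels, n).
#' @return List with `probabilities` (n x K matrix, rows summing to 1) and
#'   `labels` (argmax with lowest-index tie-break).
#' @export
predict_cnn <- function(model, x) {
  dims <- dim(x)
  if (length(dims) == 3) { dim(x) <- c(dims, 1L); dims <- dim(x) }
  if (length(dims) != 4 || !all(dims[1:3] == model$spec$input_shape))
    stop("input array must be (", paste(model$spec$input_shape, collapse = ", "), ", n)")
  p <- .cnn_predict_cpp(x, model$weights)
  classes <- model$classes
  if (is.null(classes)) classes <- as.character(seq_len(ncol(p)))
  colnames(p) <- c(classes, rep(NA, ncol(p) - length(classes)))[seq_len(ncol(p))]
  idx <- apply(p, 1, which.max)
  list(probabilities = p, labels = classes[pmin(idx, length(classes))])
}

#' Stack signal images into a training array
#'
#' @param images list of `signal_image`s (all the same size).
#' @param scale divide pixel values by 255 into \[0, 1\] (default TRUE).
#' @return Numeric array (height, width, 3, n).
#' @export
stack_images <- function(images, scale = TRUE) {
  d <- dim(images[[1]]$pixels)
  out <- array(0, dim = c(d, length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]$pixels
  if (scale) out <- out / 255
  out
}
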