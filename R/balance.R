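#' Feature dataset container
#'
#' A plain n x d feature matrix with class labels and per-row provenance
#' (original vs SMOTE-synthesized).
#'
#' @param features numeric matrix, one row per instance.
#' @param labels character/factor vector of length `nrow(features)`.
#' @param provenance per-row `"original"` / `"synthetic"` flags.
#' @return A `feature_dataset`.
#' @export
feature_dataset <- function(features, labels,
                            provenance = rep("original", nrow(features))) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            length(provenance) == nrow(features))
  structure(list(features = features, labels = as.character(labels),
                 provenance = provenance),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d x %d; classes: %s\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' SMOTE minority-class oversampling
#'
#' Brings every class count up to the majority count by interpolating
#' synthetic rows: each new row is `x + u * (x_nn - x)` with `u ~ U(0, 1)`,
#' `x` a minority-class row (cycled in order) and `x_nn` one of its k nearest
#' same-class neighbors by Euclidean distance (effective
#' k = min(k_neighbors, class size - 1); neighbor ties broken by row index).
#' Original rows are preserved verbatim and synthetic rows flagged.
#'
#' @param data a [feature_dataset()].
#' @param k_neighbors neighborhood size (default 5).
#' @param seed integer seed; the result is a pure function of (data, k, seed).
#' @return A `feature_dataset` with equal class counts; synthetic rows carry
#'   attributes `parent` and `neighbor` (row indices into the input) in the
#'   `parents` element.
#' @export
smote <- function(data, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(data, "feature_dataset"))
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  x <- data$features
  labels <- data$labels
  counts <- table(labels)
  n_target <- max(counts)
  minority <- names(counts)[counts < n_target]
  if (any(counts[minority] < 2)) stop("a minority class has fewer than 2 members")
  if (length(minority) == 0) return(data)

  new_rows <- list(); new_labels <- character(0); parents <- list()
  with_seed(seed, {
    for (cls in minority) {
      idx <- which(labels == cls)
      n_new <- n_target - length(idx)
      xc <- x[idx, , drop = FALSE]
      # pairwise Euclidean distances via the Gram matrix
      sq <- rowSums(xc^2)
      d2 <- outer(sq, sq, "+") - 2 * tcrossprod(xc)
      diag(d2) <- Inf
      k_eff <- min(k_neighbors, length(idx) - 1L)
      # k nearest neighbors per row, ties broken by row index
      nn <- apply(d2, 1, function(dr) order(dr)[seq_len(k_eff)])
      nn <- if (k_eff == 1) matrix(nn, ncol = 1) else t(nn)

      base <- rep(seq_along(idx), length.out = n_new)
      pick <- if (k_eff == 1) rep(1L, n_new) else sample.int(k_eff, n_new, replace = TRUE)
      u <- runif(n_new)
      for (s in seq_len(n_new)) {
        b <- base[s]
        nb <- nn[b, pick[s]]
        new_rows[[length(new_rows) + 1L]] <- xc[b, ] + u[s] * (xc[nb, ] - xc[b, ])
        parents[[length(parents) + 1L]] <- c(parent = idx[b], neighbor = idx[nb])
      }
      new_labels <- c(new_labels, rep(cls, n_new))
    }
  })
  if (length(new_rows) == 0) return(data)
  synth <- do.call(rbind, new_rows)
  out <- feature_dataset(
    rbind(x, synth),
    c(labels, new_labels),
    c(data$provenance, rep("synthetic", nrow(synth))))
  out$parents <- do.call(rbind, parents)
  out
}
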