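#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that per-class fold sizes differ
#' by at most one; classes' remainder samples go to the currently
#' least-loaded folds, keeping total fold sizes balanced (972 samples split
#' 5 ways with the 576/180/216 class structure gives fold sizes 195, 195,
#' 194, 194, 194).
#'
#' @param labels class label vector.
#' @param k number of folds (>= 2); every class must have >= k members.
#' @param seed integer seed for the within-class shuffles.
#' @return Integer vector of fold ids (1..k) per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  if (k < 2) stop("k must be >= 2")
  counts <- table(labels)
  if (any(counts < k)) stop("class '", names(counts)[which.min(counts)],
                            "' has fewer than k members")
  fold <- integer(length(labels))
  load <- integer(k)
  with_seed(seed, {
    for (cls in names(counts)) {
      idx <- sample(which(labels == cls))
      n <- length(idx)
      base <- n %/% k
      rem <- n - base * k
      sizes <- rep(base, k)
      if (rem > 0) {
        extra <- order(load, seq_len(k))[seq_len(rem)]
        sizes[extra] <- sizes[extra] + 1L
      }
      pos <- 1L
      for (f in seq_len(k)) {
        if (sizes[f] == 0) next
        fold[idx[pos:(pos + sizes[f] - 1L)]] <- f
        pos <- pos + sizes[f]
      }
      load <- load + sizes
    }
  })
  fold
}

#' Stratified k-fold cross-validation harness
#'
#' Each sample is tested exactly once. All fitting — including SMOTE or any
#' other resampling — must happen inside `train_fn`, which only ever sees
#' training indices, so no information leaks from test folds.
#'
#' @param labels class labels (defines stratification and n).
#' @param k number of folds.
#' @param seed integer seed (fold assignment and per-fold training seeds).
#' @param train_fn function(train_idx, seed) returning a fitted object.
#' @param eval_fn function(fit, test_idx) returning a `metric_report` (e.g.
#'   from [evaluate_predictions()]).
#' @return A `cv_result`: list with `fold_reports`, `folds`, and `summary`
#'   (mean and SD of the macro metrics and overall accuracy across folds).
#' @export
kfold_cv <- function(labels, k, seed, train_fn, eval_fn) {
  folds <- stratified_folds(labels, k, seed)
  fold_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    fit <- train_fn(train_idx, fold_seeds[f])
    reports[[f]] <- eval_fn(fit, test_idx)
  }
  acc <- vapply(reports, function(r) r$overall_accuracy, numeric(1))
  macro <- t(vapply(reports, function(r) r$macro, numeric(5)))
  structure(list(
    fold_reports = reports, folds = folds,
    summary = list(
      accuracy_mean = mean(acc), accuracy_sd = sd(acc),
      macro_mean = colMeans(macro),
      macro_sd = apply(macro, 2, sd))),
    class = "cv_result")
}

#' Stratified hold-out split and evaluation
#'
#' @param labels class labels.
#' @param test_fraction fraction of each class held out (0 < f < 1); per-class
#'   test counts are `round(f * n_class)`, kept within 1..(n_class - 1).
#' @param seed integer seed.
#' @param train_fn,eval_fn as in [kfold_cv()]; if omitted, only the split is
#'   returned.
#' @return If `train_fn` is `NULL`, a list with `train_idx`, `test_idx`.
#'   Otherwise the `eval_fn` report, with the split attached as attributes.
#' @export
holdout_cv <- function(labels, test_fraction = 0.2, seed = 1L,
                       train_fn = NULL, eval_fn = NULL) {
  labels <- as.character(labels)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  test_idx <- integer(0)
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      n_test <- round(test_fraction * length(idx))
      n_test <- min(max(n_test, 1L), length(idx) - 1L)
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(labels), test_idx)
  if (is.null(train_fn)) return(list(train_idx = train_idx, test_idx = test_idx))
  fit_seed <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 1))
  fit <- train_fn(train_idx, fit_seed)
  report <- eval_fn(fit, test_idx)
  attr(report, "train_idx") <- train_idx
  attr(report, "test_idx") <- test_idx
  report
}
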