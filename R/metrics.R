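#' Confusion matrix
#'
#' K x K count matrix with rows = true class, columns = predicted class.
#'
#' @param y_true,y_pred equal-length label vectors with values in `classes`.
#' @param classes class names; defaults to the sorted union of observed labels.
#' @return A `confusion_matrix` (integer matrix with class names, plus the
#'   derived totals as attributes).
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (!all(y_true %in% classes)) stop("unknown label in y_true")
  if (!all(y_pred %in% classes)) stop("unknown label in y_pred")
  K <- length(classes)
  cm <- matrix(0L, K, K, dimnames = list(true = classes, predicted = classes))
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

# Per-class one-vs-rest counts: TP = C_kk, FP = colsum - TP, FN = rowsum - TP,
# TN = s - TP - FP - FN.
.ovr_counts <- function(cm) {
  s <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- s - tp - fp - fn
  data.frame(class = rownames(cm), tp = tp, fp = fp, fn = fn, tn = tn,
             row.names = NULL)
}

.safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Confusion-matrix performance metrics
#'
#' Per-class one-vs-rest accuracy, precision, recall, F1 and specificity,
#' with macro averages across classes. Divisions by zero yield 0 and set the
#' `degenerate` flag.
#'
#' @param cm a [confusion_matrix()].
#' @return A `metric_report`: list with `per_class` (data.frame), `macro`
#'   (named numeric), `overall_accuracy` (trace / total) and `degenerate`.
#' @export
basic_metrics <- function(cm) {
  if (sum(cm) < 1) stop("empty confusion matrix")
  d <- .ovr_counts(cm)
  per <- data.frame(
    class = d$class,
    accuracy = .safe_div(d$tp + d$tn, d$tp + d$tn + d$fn + d$fp),
    precision = .safe_div(d$tp, d$tp + d$fp),
    recall = .safe_div(d$tp, d$tp + d$fn),
    specificity = .safe_div(d$tn, d$tn + d$fp))
  per$f1 <- .safe_div(2 * per$precision * per$recall, per$precision + per$recall)
  degenerate <- any((d$tp + d$fp) == 0) || any((d$tp + d$fn) == 0)
  macro <- c(accuracy = mean(per$accuracy), precision = mean(per$precision),
             recall = mean(per$recall), f1 = mean(per$f1),
             specificity = mean(per$specificity))
  structure(list(per_class = per, macro = macro,
                 overall_accuracy = sum(diag(cm)) / sum(cm),
                 degenerate = degenerate),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n  overall accuracy:", sprintf("%.4f", x$overall_accuracy), "\n")
  cat(sprintf("  macro: acc %.4f  pre %.4f  rec %.4f  f1 %.4f  spe %.4f\n",
              x$macro["accuracy"], x$macro["precision"], x$macro["recall"],
              x$macro["f1"], x$macro["specificity"]))
  invisible(x)
}

#' Multiclass Matthews correlation coefficient
#'
#' MCC = (c s - sum_k p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2)),
#' where c is the number of correct predictions, s the total count, p_k the
#' number of times class k was predicted (column totals) and t_k the number of
#' times it truly occurred (row totals). A zero denominator (e.g. all
#' predictions in one class) yields 0 with the `degenerate` attribute set.
#'
#' @param cm a [confusion_matrix()].
#' @return Numeric in \[-1, 1\].
#' @export
mcc <- function(cm) {
  if (sum(cm) < 1) stop("empty confusion matrix")
  c_ <- sum(diag(cm))
  s <- sum(cm)
  p <- colSums(cm)
  t_ <- rowSums(cm)
  den2 <- (s^2 - sum(p^2)) * (s^2 - sum(t_^2))
  if (den2 <= 0) return(structure(0, degenerate = TRUE))
  (c_ * s - sum(p * t_)) / sqrt(den2)
}

#' Cohen's kappa
#'
#' K = (P_o - P_e) / (1 - P_e) with observed agreement P_o = c / s and chance
#' agreement P_e = sum_k (t_k / s)(p_k / s). When P_e = 1 the statistic is 1
#' if P_o = 1 and flagged 0 otherwise.
#'
#' @param cm a [confusion_matrix()].
#' @return Numeric kappa with attributes `P_o` and `P_e`.
#' @export
cohen_kappa <- function(cm) {
  if (sum(cm) < 1) stop("empty confusion matrix")
  s <- sum(cm)
  p_o <- sum(diag(cm)) / s
  p_e <- sum((rowSums(cm) / s) * (colSums(cm) / s))
  k <- if (p_e == 1) {
    if (p_o == 1) 1 else structure(0, degenerate = TRUE)
  } else (p_o - p_e) / (1 - p_e)
  attr(k, "P_o") <- p_o
  attr(k, "P_e") <- p_e
  k
}

#' Root-mean-square error between one-hot truth and predicted probabilities
#'
#' sqrt of the mean squared difference over all n x K entries.
#'
#' @param truth n x K one-hot matrix.
#' @param probs n x K probability matrix of the same shape.
#' @return Non-negative numeric.
#' @export
rmse <- function(truth, probs) {
  if (!all(dim(truth) == dim(probs))) stop("shape mismatch")
  sqrt(mean((truth - probs)^2))
}

#' One-hot encode labels
#'
#' @param labels factor/character vector.
#' @param classes class order (default sorted unique labels).
#' @return n x K 0/1 matrix with `classes` as column names.
#' @export
one_hot <- function(labels, classes = sort(unique(as.character(labels)))) {
  labels <- as.character(labels)
  if (!all(labels %in% classes)) stop("unknown label")
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(labels), match(labels, classes))] <- 1
  m
}

#' Full metric report for a set of predictions
#'
#' Convenience wrapper combining [basic_metrics()], [mcc()], [cohen_kappa()]
#' and (when probabilities are supplied) [rmse()].
#'
#' @param y_true,y_pred label vectors.
#' @param probs optional n x K probability matrix with class column names.
#' @param classes class set.
#' @return A `metric_report` with `mcc`, `kappa` and `rmse` elements added.
#' @export
evaluate_predictions <- function(y_true, y_pred, probs = NULL, classes = NULL) {
  cm <- confusion_matrix(y_true, y_pred, classes)
  rep <- basic_metrics(cm)
  rep$confusion <- cm
  rep$mcc <- as.numeric(mcc(cm))
  rep$kappa <- as.numeric(cohen_kappa(cm))
  if (!is.null(probs)) {
    cls <- colnames(probs)
    rep$rmse <- rmse(one_hot(y_true, cls), probs)
  }
  rep
}
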