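test_that("confusion matrices count pairs exactly", {
  y <- rep(c("ARR", "CHF", "NSR"), each = 10)
  cm <- confusion_matrix(y, y)
  expect_equal(diag(cm), c(ARR = 10L, CHF = 10L, NSR = 10L))
  expect_equal(sum(cm), 30L)
  # brute-force pairwise oracle on random labels
  set.seed(77)
  classes <- c("a", "b", "c")
  yt <- sample(classes, 200, replace = TRUE)
  yp <- sample(classes, 200, replace = TRUE)
  cm2 <- confusion_matrix(yt, yp, classes)
  for (i in classes) for (j in classes)
    expect_equal(cm2[i, j], sum(yt == i & yp == j))
  expect_error(confusion_matrix(c("a"), c("a", "b")), "length")
  expect_error(confusion_matrix("z", "a", classes = c("a", "b")), "unknown")
})

test_that("per-class metrics match the binary closed forms", {
  # TP=50 TN=40 FP=5 FN=5 for the first class of a 2x2 matrix
  cm <- structure(matrix(c(50L, 5L, 5L, 40L), 2, byrow = TRUE,
                         dimnames = list(true = c("pos", "neg"),
                                         predicted = c("pos", "neg"))),
                  class = c("confusion_matrix", "matrix"))
  r <- basic_metrics(cm)
  pos <- r$per_class[r$per_class$class == "pos", ]
  expect_equal(pos$accuracy, 0.9)
  expect_equal(pos$precision, 50 / 55)
  expect_equal(pos$recall, 50 / 55)
  expect_equal(pos$f1, 50 / 55)
  expect_equal(pos$specificity, 40 / 45)
  # perfect diagonal: everything 1
  pd <- confusion_matrix(rep(c("a", "b", "c"), 5), rep(c("a", "b", "c"), 5))
  rp <- basic_metrics(pd)
  expect_true(all(abs(rp$macro - 1) < 1e-12))
  expect_equal(rp$overall_accuracy, 1)
})

test_that("metrics agree with an independent per-formula oracle", {
  set.seed(13)
  for (trial in 1:5) {
    cm <- confusion_matrix(sample(c("x", "y", "z"), 120, TRUE),
                           sample(c("x", "y", "z"), 120, TRUE))
    r <- basic_metrics(cm)
    s <- sum(cm)
    for (k in 1:3) {
      tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
      tn <- s - tp - fp - fn
      expect_equal(r$per_class$accuracy[k], (tp + tn) / s, tolerance = 1e-12)
      expect_equal(r$per_class$precision[k], tp / (tp + fp), tolerance = 1e-12)
      expect_equal(r$per_class$recall[k], tp / (tp + fn), tolerance = 1e-12)
      expect_equal(r$per_class$specificity[k], tn / (tn + fp), tolerance = 1e-12)
      pr <- tp / (tp + fp); rc <- tp / (tp + fn)
      expect_equal(r$per_class$f1[k], 2 * pr * rc / (pr + rc), tolerance = 1e-12)
    }
  }
})

test_that("multiclass MCC matches hand values and degenerates safely", {
  pd <- confusion_matrix(rep(c("a", "b", "c"), 10), rep(c("a", "b", "c"), 10))
  expect_equal(as.numeric(mcc(pd)), 1)
  cm <- confusion_matrix(rep(c("x", "y"), c(3, 3)),
                         c("x", "x", "y", "y", "y", "x"))
  expect_equal(as.numeric(mcc(cm)), 1 / 3, tolerance = 1e-12)
  # all predictions in one class: zero denominator
  onecol <- confusion_matrix(c("a", "a", "b", "b"), rep("a", 4))
  expect_equal(as.numeric(mcc(onecol)), 0)
  expect_true(attr(mcc(onecol), "degenerate"))
})

test_that("binary multiclass MCC equals the classical formula on 1000 matrices", {
  set.seed(99)
  for (i in 1:1000) {
    m <- matrix(rpois(4, 8), 2, dimnames = list(true = c("n", "p"),
                                                predicted = c("n", "p")))
    class(m) <- c("confusion_matrix", "matrix")
    tn <- m[1, 1]; fp <- m[1, 2]; fn <- m[2, 1]; tp <- m[2, 2]
    den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
      sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
    classical <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(as.numeric(mcc(m)), classical, tolerance = 1e-12)
  }
})

test_that("Cohen's kappa matches its definition and chance behavior", {
  pd <- confusion_matrix(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  expect_equal(as.numeric(cohen_kappa(pd)), 1)
  # P_o 0.9, P_e 0.5 -> kappa 0.8 (balanced 2-class matrix, 45/5 per row)
  cm <- structure(matrix(c(45L, 5L, 5L, 45L), 2, byrow = TRUE,
                         dimnames = list(c("a", "b"), c("a", "b"))),
                  class = c("confusion_matrix", "matrix"))
  k <- cohen_kappa(cm)
  expect_equal(attr(k, "P_o"), 0.9)
  expect_equal(attr(k, "P_e"), 0.5)
  expect_equal(as.numeric(k), 0.8)
  # uniformly random labels: agreement is chance-level
  set.seed(123)
  yt <- sample(c("a", "b", "c"), 10000, TRUE)
  yp <- sample(c("a", "b", "c"), 10000, TRUE)
  expect_lt(abs(as.numeric(cohen_kappa(confusion_matrix(yt, yp)))), 0.05)
})

test_that("probability RMSE matches closed forms and is monotone", {
  truth <- one_hot(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(rmse(truth, truth), 0)
  unif <- matrix(1 / 3, 3, 3)
  expect_equal(rmse(truth, unif), sqrt(2 / 9), tolerance = 1e-12)
  worse <- truth
  worse[1, ] <- c(0.5, 0.5, 0)
  expect_gt(rmse(truth, worse), 0)
  expect_error(rmse(truth, matrix(0, 2, 3)), "shape")
})

test_that("stratified folds are balanced, disjoint and complete", {
  labs <- rep(c("ARR", "CHF", "NSR"), c(576L, 180L, 216L))
  f <- stratified_folds(labs, 5L, seed = 1)
  expect_equal(sort(as.vector(table(f)), decreasing = TRUE),
               c(195L, 195L, 194L, 194L, 194L))
  # per-class fold sizes differ by at most one
  for (cls in unique(labs)) {
    t <- table(f[labs == cls])
    expect_lte(max(t) - min(t), 1L)
  }
  # leave-one-out at k == n
  labs2 <- rep(c("a", "b"), each = 4)
  f2 <- stratified_folds(labs2, 4L, seed = 2)
  expect_equal(as.vector(table(f2)), rep(2L, 4))
  f3 <- stratified_folds(rep("a", 6), 6L, seed = 2)
  expect_equal(as.vector(table(f3)), rep(1L, 6))
  expect_error(stratified_folds(c("a", "a", "b"), 3L, seed = 1), "fewer than k")
})

test_that("k-fold tests every sample exactly once", {
  labs <- rep(c("a", "b", "c"), c(30, 21, 15))
  seen <- integer(0)
  res <- kfold_cv(labs, 3L, seed = 5,
                  train_fn = function(idx, seed) idx,
                  eval_fn = function(fit, test_idx) {
                    expect_length(intersect(fit, test_idx), 0L)
                    seen <<- c(seen, test_idx)
                    basic_metrics(confusion_matrix(labs[test_idx], labs[test_idx]))
                  })
  expect_equal(sort(seen), seq_along(labs))
  expect_equal(res$summary$accuracy_mean, 1)
})

test_that("hold-out splits are stratified, seeded and disjoint", {
  labs <- rep(c("ARR", "CHF", "NSR"), c(576L, 180L, 216L))
  sp <- holdout_cv(labs, 0.2, seed = 3)
  expect_true(length(sp$test_idx) %in% c(194L, 195L))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), seq_along(labs))
  for (cls in unique(labs)) {
    n_te <- sum(labs[sp$test_idx] == cls)
    expect_equal(n_te, round(0.2 * sum(labs == cls)))
  }
  sp2 <- holdout_cv(labs, 0.2, seed = 3)
  expect_identical(sp, sp2)
  expect_error(holdout_cv(labs, 1.2, seed = 1), "test_fraction")
})

test_that("a memorizing pipeline scores at chance on label-shuffled folds", {
  set.seed(21)
  labs <- sample(rep(c("a", "b", "c"), each = 30)) # shuffled labels
  res <- kfold_cv(labs, 5L, seed = 8,
                  train_fn = function(idx, seed) {
                    # memorize training rows; majority vote for unseen rows
                    maj <- names(which.max(table(labs[idx])))
                    list(seen = idx, lab = labs, maj = maj)
                  },
                  eval_fn = function(fit, test_idx) {
                    pred <- rep(fit$maj, length(test_idx))
                    basic_metrics(confusion_matrix(labs[test_idx], pred,
                                                   classes = c("a", "b", "c")))
                  })
  # chance is 1/3; binomial SD over ~18-sample folds is ~0.11
  expect_lt(abs(res$summary$accuracy_mean - 1 / 3), 3 * 0.11)
})

test_that("one-way ANOVA matches stats::aov to high precision", {
  g <- list(c(12.1, 14.2, 13.3, 12.8, 15.0),
            c(11.0, 12.5, 11.8, 12.2, 11.4),
            c(16.2, 15.8, 17.1, 16.6, 15.9),
            c(12.9, 13.4, 14.1, 13.7, 12.6))
  an <- one_way_anova(g)
  expect_equal(an$table$DF[1:3], c(3L, 16L, 19L))
  expect_equal(an$table$SS[3], an$table$SS[1] + an$table$SS[2], tolerance = 1e-9)
  df <- data.frame(y = unlist(g), grp = factor(rep(1:4, each = 5)))
  ref <- summary(stats::aov(y ~ grp, df))[[1]]
  expect_equal(an$table$F[1], ref[1, "F value"], tolerance = 1e-9)
  expect_equal(an$table$p[1], ref[1, "Pr(>F)"], tolerance = 1e-9)
  expect_equal(an$table$SS[1], ref[1, "Sum Sq"], tolerance = 1e-9)
  # identical groups: F = 0
  an0 <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(an0$table$F[1], 0)
  expect_error(one_way_anova(list(1:3)), "2 groups")
  expect_error(one_way_anova(list(1:3, 5)), "at least 2 values")
})

test_that("Tukey HSD agrees with stats::TukeyHSD", {
  set.seed(6)
  g <- list(a = rnorm(6, 10), b = rnorm(7, 10.5), c = rnorm(5, 13))
  tk <- tukey_hsd(g, alpha = 0.05)
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(names(g), lengths(g)), levels = names(g)))
  ref <- stats::TukeyHSD(stats::aov(y ~ grp, df))$grp
  key <- paste(tk$group_j, tk$group_i, sep = "-")
  expect_equal(tk$diff, unname(ref[key, "diff"]), tolerance = 1e-9)
  expect_equal(tk$p, unname(ref[key, "p adj"]), tolerance = 1e-6)
  # all-identical groups: nothing significant
  same <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_false(any(same$significant))
  # one group shifted far away: significant against all others
  far <- tukey_hsd(list(a = rnorm(5), b = rnorm(5), c = rnorm(5) + 100))
  cf <- far$group_i == "c" | far$group_j == "c"
  expect_true(all(far$significant[cf]))
  expect_true(all(tk$q[tk$significant] > attr(tk, "q_crit")))
})
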