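#' One-way analysis of variance
#'
#' Computed directly from sums of squares: SS_between over group means,
#' SS_within over residuals, MS = SS/DF, F = MS_between / MS_within, p from
#' the upper tail of the F distribution.
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2 values).
#' @return An `anova_result`: list with `table` (data.frame: source, SS, DF,
#'   MS, F, p), `group_means`, `ms_within`, `df_within`, `n` and a
#'   `degenerate` flag set when both between- and within-group variance are 0.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs at least 2 values")
  g <- length(groups)
  n_i <- lengths(groups)
  N <- sum(n_i)
  all_x <- unlist(groups)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(g), function(i)
    sum((groups[[i]] - means[i])^2), numeric(1)))
  df_b <- g - 1L
  df_w <- N - g
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  degenerate <- ss_within == 0 && ss_between == 0
  f_stat <- if (ms_w == 0) ifelse(ss_between == 0, 0, Inf) else ms_b / ms_w
  p <- if (is.infinite(f_stat)) 0 else pf(f_stat, df_b, df_w, lower.tail = FALSE)
  tab <- data.frame(
    source = c("between", "within", "total"),
    SS = c(ss_between, ss_within, ss_between + ss_within),
    DF = c(df_b, df_w, N - 1L),
    MS = c(ms_b, ms_w, NA),
    F = c(f_stat, NA, NA),
    p = c(p, NA, NA))
  structure(list(table = tab, group_means = means, ms_within = ms_w,
                 df_within = df_w, n = n_i, degenerate = degenerate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  print(x$table, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' For each pair of groups the q statistic is |mean_i - mean_j| / SE with
#' SE = sqrt(MS_within / 2 * (1/n_i + 1/n_j)) (the Tukey-Kramer convention,
#' which reduces to sqrt(MS_within / n) for balanced groups). p-values and
#' the critical value come from the exact studentized-range distribution at
#' (g, DF_within).
#'
#' @param groups list of numeric vectors (named, optionally).
#' @param alpha significance level (default 0.05).
#' @return A `tukey_result`: data.frame with one row per pair (`group_i`,
#'   `group_j`, `diff`, `se`, `q`, `p`, `significant`) plus the critical q as
#'   attribute `q_crit`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  g <- length(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_len(g))
  means <- an$group_means
  n_i <- an$n
  pairs <- utils::combn(g, 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- means[j] - means[i]
    se <- sqrt(an$ms_within / 2 * (1 / n_i[i] + 1 / n_i[j]))
    q <- if (se == 0) ifelse(diff == 0, 0, Inf) else abs(diff) / se
    p <- if (is.infinite(q)) 0 else ptukey(q, g, an$df_within, lower.tail = FALSE)
    data.frame(group_i = nms[i], group_j = nms[j], diff = diff, se = se,
               q = q, p = p, significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "q_crit") <- qtukey(1 - alpha, g, an$df_within)
  attr(out, "alpha") <- alpha
  class(out) <- c("tukey_result", "data.frame")
  out
}
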