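#' Unpaired two-group comparison with a normality gate
#'
#' Each sample is screened with Shapiro-Wilk at `alpha`; if both pass, an
#' unpaired pooled-variance t-test is used (`df = n_a + n_b - 2`),
#' otherwise the Mann-Whitney U test. The chosen test is recorded. Tests
#' are two-sided.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param alpha level of the Shapiro-Wilk gate (default 0.05).
#' @return an object of class `group_comparison`: `test`, `statistic`,
#'   `df` (`NA` for the nonparametric path), `p_value`, `normality_p`,
#'   `summaries` (mean, sd, n per group), `degenerate` flag.
#' @export
compare_unpaired <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_invalid("invalid-argument: each sample needs n >= 2")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(new_group_comparison("unpaired t (degenerate)",
                                statistic = if (same) 0 else NA_real_,
                                df = length(a) + length(b) - 2,
                                p = if (same) 1 else NA_real_,
                                norm_p = c(NA_real_, NA_real_),
                                a = a, b = b, degenerate = TRUE))
  }
  norm_p <- c(shapiro_gate(a), shapiro_gate(b))
  if (all(norm_p >= alpha, na.rm = TRUE)) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    new_group_comparison("unpaired t", unname(tt$statistic),
                         unname(tt$parameter), tt$p.value, norm_p, a, b)
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    new_group_comparison("mann-whitney", unname(wt$statistic), NA_real_,
                         wt$p.value, norm_p, a, b)
  }
}

# Shapiro-Wilk p, or NA when the test is inapplicable (tiny n, zero
# variance, n > 5000); NA counts as "passes the gate" so the parametric
# path stays the default for degenerate screens.
shapiro_gate <- function(x) {
  if (length(x) < 3 || length(x) > 5000 || stats::var(x) == 0) return(NA_real_)
  stats::shapiro.test(x)$p.value
}

new_group_comparison <- function(test, statistic, df, p, norm_p, a, b,
                                 degenerate = FALSE) {
  structure(list(test = test, statistic = statistic, df = df, p_value = p,
                 normality_p = norm_p,
                 summaries = data.frame(
                   group = c("a", "b"),
                   mean = c(mean(a), mean(b)),
                   sd = c(stats::sd(a), stats::sd(b)),
                   n = c(length(a), length(b))),
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  df_txt <- if (is.finite(x$df %||% NA)) sprintf("(%g)", x$df) else ""
  cat(sprintf("%s%s = %.4g, p = %.4g\n", x$test, df_txt, x$statistic,
              x$p_value))
  invisible(x)
}

#' Paired comparison (dependent-samples t-test)
#'
#' Paired t on the differences, `df = n - 1`. All-zero differences give
#' `t = 0, p = 1`; constant nonzero differences are a zero-variance
#' degenerate case reported with a flag instead of an infinite statistic.
#'
#' @param before,after equal-length numeric samples (n >= 2).
#' @return a `group_comparison` (test `"paired t"`).
#' @export
compare_paired <- function(before, after) {
  if (length(before) != length(after)) {
    stop_invalid("invalid-argument: paired samples must have equal length")
  }
  keep <- is.finite(before) & is.finite(after)
  before <- before[keep]; after <- after[keep]
  n <- length(before)
  if (n < 2) stop_invalid("invalid-argument: need n >= 2 pairs")
  d <- after - before
  if (stats::var(d) == 0) {
    return(new_group_comparison("paired t (zero-variance-difference)",
                                statistic = if (all(d == 0)) 0 else NA_real_,
                                df = n - 1,
                                p = if (all(d == 0)) 1 else NA_real_,
                                norm_p = NA_real_, a = before, b = after,
                                degenerate = TRUE))
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  new_group_comparison("paired t", unname(tt$statistic),
                       unname(tt$parameter), tt$p.value,
                       shapiro_gate(d), before, after)
}

#' Pearson correlation with df = n - 2
#'
#' @param x,y equal-length numeric samples (n >= 3).
#' @return list of class `correlation_result`: `r`, `df`, `p_value`,
#'   `defined` (FALSE with zero variance in either variable).
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("invalid-argument: unequal lengths")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_invalid("invalid-argument: need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(list(r = NA_real_, df = n - 2, p_value = NA_real_,
                          defined = FALSE), class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), df = unname(ct$parameter),
                 p_value = ct$p.value, defined = TRUE),
            class = "correlation_result")
}

#' Exclude non-avoiding fish from IAT records
#'
#' Fish that failed to enter the deep zone within `cutoff` seconds during
#' the chosen phase are removed and counted.
#'
#' @param records an `iat_records` data frame.
#' @param cutoff latency cutoff, s, > 0 (default 180).
#' @param phase which latency defines a non-avoider: `"train"` (default),
#'   `"test"` or `"either"`.
#' @return the filtered records; attribute `n_excluded` holds the count.
#' @export
filter_nonavoiders <- function(records, cutoff = 180, phase = c("train", "test", "either")) {
  if (cutoff <= 0) stop_invalid("invalid-argument: cutoff must be > 0")
  phase <- match.arg(phase)
  bad <- switch(phase,
    train = records$train_latency_s > cutoff,
    test = records$test_latency_s > cutoff,
    either = records$train_latency_s > cutoff | records$test_latency_s > cutoff)
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' One-way ANOVA with Fisher's LSD post-hoc
#'
#' Provided for >2-group comparisons; the shipped pipeline's group
#' contrasts are pairwise, so this is an auxiliary entry point.
#'
#' @param values numeric endpoint vector.
#' @param groups group factor (same length).
#' @return list: `anova` (`F`, `df`, `p_value`) and `lsd` (pairwise t
#'   using the pooled ANOVA MSE, unadjusted p, per Fisher's LSD).
#' @export
anova_lsd <- function(values, groups) {
  groups <- factor(groups)
  keep <- is.finite(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  df_e <- an["Residuals", "Df"]
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  lsd <- do.call(rbind, lapply(pairs, function(pr) {
    xa <- values[groups == pr[1]]; xb <- values[groups == pr[2]]
    se <- sqrt(mse * (1 / length(xa) + 1 / length(xb)))
    tval <- (mean(xa) - mean(xb)) / se
    data.frame(group_a = pr[1], group_b = pr[2], t = tval, df = df_e,
               p_value = 2 * stats::pt(-abs(tval), df_e))
  }))
  list(anova = list(F = an["groups", "F value"],
                    df = c(an["groups", "Df"], df_e),
                    p_value = an["groups", "Pr(>F)"]),
       lsd = lsd)
}
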