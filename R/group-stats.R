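#' Cohen's d from group summary statistics
#'
#' Standardised mean difference `(mean1 - mean2) / s_pooled` with the
#' pooled SD using `(n - 1)` weights.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return Cohen's d (numeric scalar).
#' @examples
#' cohens_d_pooled(3.527, 1.128, 48, 2.882, 1.619, 43) # ~0.47
#' @export
cohens_d_pooled <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2 || sd1 <= 0 || sd2 <= 0) {
    abort("need n >= 2 and sd > 0 in both groups.",
          class = "rrst_argument_error")
  }
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / sp
}

#' Cohen's d from raw samples
#'
#' @param x,y Numeric samples for the two groups.
#' @return Cohen's d.
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  cohens_d_pooled(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' Cross-product ratio `(a d) / (b c)` with a log-scale Wald interval. A
#' zero cell triggers the Haldane-Anscombe correction (0.5 added to every
#' cell), flagged in the result.
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out as rows =
#'   exposure, columns = group: `a`/`b` exposed, `c`/`d` unexposed.
#' @param conf_level Confidence level, default 0.95.
#' @return A one-row tibble: `estimate`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' odds_ratio(19, 24, 2, 44) # ~17.42
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers.",
          class = "rrst_argument_error")
  }
  corrected <- any(counts == 0)
  if (corrected) {
    warn("zero cell: applying Haldane-Anscombe 0.5 correction.")
    counts <- counts + 0.5
  }
  or <- (counts[1] * counts[4]) / (counts[2] * counts[3])
  se <- sqrt(sum(1 / counts))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    estimate = or,
    ci_low = exp(log(or) - zq * se),
    ci_high = exp(log(or) + zq * se),
    corrected = corrected
  )
}

.welch_core <- function(m1, s1, n1, m2, s2, n2, conf_level = 0.95) {
  n1 <- as.numeric(n1)
  n2 <- as.numeric(n2)
  se2 <- s1^2 / n1 + s2^2 / n2
  if (se2 == 0) {
    # zero variance in both groups: identical means give p = 1 by convention
    return(tibble(
      test = "welch_t", estimate = m1 - m2, statistic = 0, df = n1 + n2 - 2,
      p_value = if (m1 == m2) 1 else 0,
      ci_low = m1 - m2, ci_high = m1 - m2,
      effect_size = NA_real_, n1 = n1, n2 = n2
    ))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  d <- if (s1 > 0 && s2 > 0) cohens_d_pooled(m1, s1, n1, m2, s2, n2) else NA_real_
  tibble(
    test = "welch_t", estimate = m1 - m2, statistic = tstat, df = df,
    p_value = p,
    ci_low = m1 - m2 - tq * sqrt(se2), ci_high = m1 - m2 + tq * sqrt(se2),
    effect_size = d, n1 = n1, n2 = n2
  )
}

#' Welch two-sample t-test
#'
#' Welch's unequal-variances t statistic with Satterthwaite degrees of
#' freedom and a two-sided p value, accepting either raw samples or group
#' summary statistics. Both interfaces route through the same summary-based
#' core, so the raw-sample and summary results agree exactly.
#'
#' @param x,y Raw samples (ignored when summaries are supplied).
#' @param mean1,sd1,n1,mean2,sd2,n2 Optional summary statistics.
#' @param conf_level Confidence level for the mean-difference interval.
#' @return A one-row tibble with the statistic, df, p value, CI, and
#'   Cohen's d as the effect size.
#' @examples
#' welch_t(mean1 = 2.882, sd1 = 1.619, n1 = 43,
#'         mean2 = 3.527, sd2 = 1.128, n2 = 48) # p ~ 0.032
#' @export
welch_t <- function(x = NULL, y = NULL, mean1 = NULL, sd1 = NULL, n1 = NULL,
                    mean2 = NULL, sd2 = NULL, n2 = NULL, conf_level = 0.95) {
  if (!is.null(x) && !is.null(y)) {
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      abort("need at least 2 observations per group.",
            class = "rrst_argument_error")
    }
    return(.welch_core(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                       conf_level))
  }
  if (any(vapply(list(mean1, sd1, n1, mean2, sd2, n2), is.null, logical(1)))) {
    abort("supply either raw samples or complete summary statistics.",
          class = "rrst_argument_error")
  }
  if (n1 < 2 || n2 < 2) {
    abort("need n >= 2 per group.", class = "rrst_argument_error")
  }
  .welch_core(mean1, sd1, n1, mean2, sd2, n2, conf_level)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples: exact enumeration when the combined
#' sample is small (`n1 + n2 <= 12`, no ties), tie-corrected normal
#' approximation otherwise (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples.
#' @return One-row tibble with the U statistic (number of `(x, y)` pairs
#'   with `x > y`, ties counting one half), p value, and group sizes.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 1 || length(y) < 1) {
    abort("both samples must be non-empty.", class = "rrst_argument_error")
  }
  exact <- (length(x) + length(y)) <= 12 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)
  )
  p <- wt$p.value
  # fully tied data: zero-variance normal approximation, no evidence either way
  if (is.nan(p)) p <- 1
  tibble(
    test = "mann_whitney",
    statistic = unname(wt$statistic),
    p_value = p,
    exact = exact,
    n1 = length(x), n2 = length(y)
  )
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Pearson's chi-squared statistic without continuity correction, df = 1.
#'
#' @param table A 2x2 matrix of non-negative counts, or the four counts
#'   `a, b, c, d` (row-wise).
#' @param ... Passed counts when `table` is a scalar.
#' @return One-row tibble: statistic, df, p value.
#' @export
chi2_test <- function(table, ...) {
  if (!is.matrix(table)) {
    counts <- c(table, ...)
    if (length(counts) != 4) {
      abort("supply a 2x2 matrix or four counts.",
            class = "rrst_argument_error")
    }
    table <- matrix(counts, nrow = 2, byrow = TRUE)
  }
  if (any(table < 0)) {
    abort("counts must be non-negative.", class = "rrst_argument_error")
  }
  if (sum(table) == 0) {
    abort("all-zero table.", class = "rrst_argument_error")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble(
    test = "chi2",
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value
  )
}

#' Pearson correlation with t-based p value
#'
#' @param x,y Numeric vectors (pairwise complete, `n >= 3`).
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return One-row tibble: `estimate` (r), statistic, df, p value, CI, n.
#' @export
pearson_r <- function(x, y, conf_level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    abort("need at least 3 complete pairs.", class = "rrst_argument_error")
  }
  ct <- stats::cor.test(x, y, conf.level = conf_level)
  tibble(
    test = "pearson_r",
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
    n = length(x)
  )
}

#' Multiplicity adjustment of p values
#'
#' Bonferroni (`min(1, m p)`, with an explicit family size `m` that may
#' exceed the number of p values supplied) or Benjamini-Hochberg FDR
#' step-up.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @param m Family size; defaults to `length(p)`. Must be at least
#'   `length(p)`.
#' @return Adjusted p values.
#' @examples
#' adjust_pvalues(0.01125, method = "bonferroni", m = 4) # 0.045
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh_fdr"),
                           m = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1].", class = "rrst_argument_error")
  }
  if (m < length(p)) {
    abort("family size `m` cannot be smaller than the number of p values.",
          class = "rrst_argument_error")
  }
  switch(method,
    bonferroni = pmin(1, m * p),
    bh_fdr = p.adjust(p, method = "BH", n = m)
  )
}

#' Linear model with group interaction and covariates
#'
#' Ordinary least-squares fit for the regression layer of the analysis
#' (e.g. somatoform-dissociation score on respiratory sensitivity in
#' interaction with group, medication as a covariate). The `group` factor
#' is releveled so the reference is `ref_group` (default `"HC"`), making
#' the main predictor effect the slope in the reference group.
#'
#' @param data Data frame containing the model variables.
#' @param formula Model formula, e.g. `sdq20 ~ sensitivity * group +
#'   medication`.
#' @param ref_group Reference level of the `group` factor.
#' @param conf_level Confidence level for coefficient intervals.
#' @return An object of class `rrst_lm` wrapping the `lm` fit; see
#'   [tidy.rrst_lm()] and [glance.rrst_lm()].
#' @export
fit_linear_model <- function(data, formula, ref_group = "HC",
                             conf_level = 0.95) {
  if ("group" %in% names(data)) {
    data$group <- stats::relevel(factor(data$group), ref = ref_group)
  }
  fit <- lm(formula, data = data)
  if (any(is.na(coef(fit)))) {
    abort(paste0("rank-deficient design; collinear term(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "rrst_argument_error")
  }
  structure(list(fit = fit, conf_level = conf_level, ref_group = ref_group),
            class = "rrst_lm")
}

#' @rdname fit_linear_model
#' @param x An `rrst_lm` object.
#' @param ... Unused.
#' @export
tidy.rrst_lm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = x$conf_level)
  tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p_value = unname(s[, "Pr(>|t|)"]),
    ci_low = unname(ci[, 1]),
    ci_high = unname(ci[, 2])
  )
}

#' @rdname fit_linear_model
#' @export
glance.rrst_lm <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble(
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    f_statistic = unname(f[1]),
    df1 = unname(f[2]),
    df2 = unname(f[3]),
    p_value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    n = length(s$residuals)
  )
}

#' @export
print.rrst_lm <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("linear model: F(%d, %d) = %.2f, p = %.3g, R^2 = %.3f\n",
              g$df1, g$df2, g$f_statistic, g$p_value, g$r_squared))
  print(tidy(x))
  invisible(x)
}
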