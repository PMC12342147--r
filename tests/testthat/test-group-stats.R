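test_that("Cohen's d from summaries: published value, zero and antisymmetry", {
  expect_equal(round(cohens_d_pooled(3.527, 1.128, 48, 2.882, 1.619, 43), 2),
               0.47)
  expect_equal(cohens_d_pooled(5, 1, 10, 5, 2, 12), 0)
  expect_equal(cohens_d_pooled(3, 1, 10, 5, 2, 12),
               -cohens_d_pooled(5, 2, 12, 3, 1, 10))
  expect_error(cohens_d_pooled(1, 0, 10, 2, 1, 10),
               class = "rrst_argument_error")
})

test_that("odds ratio: published value, null table, reciprocity, zero cells", {
  expect_equal(round(odds_ratio(19, 24, 2, 44)$estimate, 2), 17.42)
  or_null <- odds_ratio(10, 10, 10, 10)
  expect_equal(or_null$estimate, 1)
  expect_lt(or_null$ci_low, 1)
  expect_gt(or_null$ci_high, 1)
  # transposing the table inverts the OR
  expect_equal(odds_ratio(19, 2, 24, 44)$estimate,
               1 / odds_ratio(2, 19, 44, 24)$estimate, tolerance = 1e-12)
  expect_warning(orz <- odds_ratio(5, 0, 3, 7), "Haldane")
  expect_true(orz$corrected)
  expect_error(odds_ratio(1.5, 2, 3, 4), class = "rrst_argument_error")
})

test_that("Welch t: published p value, identity, and raw==summary exactly", {
  w <- welch_t(mean1 = 2.882, sd1 = 1.619, n1 = 43,
               mean2 = 3.527, sd2 = 1.128, n2 = 48)
  expect_equal(w$p_value, 0.032, tolerance = 0.02)
  expect_lt(w$statistic, 0)
  set.seed(14)
  x <- rnorm(20, 1); y <- rnorm(25, 1.4)
  wr <- welch_t(x, y)
  ws <- welch_t(mean1 = mean(x), sd1 = sd(x), n1 = 20,
                mean2 = mean(y), sd2 = sd(y), n2 = 25)
  expect_identical(wr, ws)
  # agrees with stats::t.test
  tt <- t.test(x, y)
  expect_equal(wr$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(wr$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(welch_t(x, x)$statistic, 0)
})

test_that("Welch p approximates an exhaustive permutation oracle at small n", {
  set.seed(15)
  x <- rnorm(6, 0); y <- rnorm(6, 1.2)
  w <- welch_t(x, y)
  pooled <- c(x, y)
  combs <- utils::combn(12, 6)
  tstats <- apply(combs, 2, function(idx)
    abs(welch_t(pooled[idx], pooled[-idx])$statistic))
  p_perm <- mean(tstats >= abs(w$statistic) - 1e-12)
  expect_lt(abs(w$p_value - p_perm), 0.06)
})

test_that("Mann-Whitney: exact enumeration, complementarity, tie handling", {
  mw <- mann_whitney(1:3, 4:6)
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)
  expect_true(mw$exact)
  # full-enumeration oracle agrees on a random no-tie set
  set.seed(16)
  x <- rnorm(5); y <- rnorm(6, 0.8)
  expect_equal(mann_whitney(x, y)$p_value, mann_whitney_enumeration_p(x, y),
               tolerance = 1e-12)
  # U(x, y) + U(y, x) = n1 * n2
  expect_equal(mann_whitney(x, y)$statistic + mann_whitney(y, x)$statistic,
               30)
  expect_equal(mann_whitney(5, 5)$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), class = "rrst_argument_error")
})

test_that("chi-squared: proportional, concentrated and symmetric tables", {
  prop <- chi2_test(matrix(c(10, 20, 30, 60), 2))
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  expect_equal(prop$p_value, 1, tolerance = 1e-12)
  # hand computation of the Pearson statistic for (10,0,0,10)
  expect_equal(chi2_test(10, 0, 0, 10)$statistic, 20)
  expect_equal(chi2_test(3, 8, 12, 5)$statistic,
               chi2_test(12, 5, 3, 8)$statistic)
  expect_error(chi2_test(0, 0, 0, 0), class = "rrst_argument_error")
})

test_that("Pearson correlation: exact, null and hand-checked cases", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x + 1)$estimate, 1, tolerance = 1e-12)
  set.seed(17)
  nullr <- pearson_r(rnorm(5000), rnorm(5000))
  expect_lt(abs(nullr$estimate), 0.05)
  # brute-force covariance formula on a hand dataset
  hx <- c(1, 2, 3, 4); hy <- c(2, 1, 4, 3)
  r_hand <- sum((hx - mean(hx)) * (hy - mean(hy))) /
    sqrt(sum((hx - mean(hx))^2) * sum((hy - mean(hy))^2))
  expect_equal(pearson_r(hx, hy)$estimate, r_hand, tolerance = 1e-12)
  expect_error(pearson_r(1:2, 1:2), class = "rrst_argument_error")
})

test_that("multiplicity adjustment: Bonferroni family size and BH step-up", {
  expect_equal(adjust_pvalues(0.01125, method = "bonferroni", m = 4), 0.045)
  expect_equal(adjust_pvalues(0.2, method = "bonferroni", m = 1), 0.2)
  p <- c(0.01, 0.02, 0.03, 0.04)
  # hand step-up: p_(i) * m / i, cumulative minimum from the largest
  hand <- rev(cummin(rev(p * 4 / seq_along(p))))
  expect_equal(adjust_pvalues(p, method = "bh_fdr"), hand)
  expect_error(adjust_pvalues(c(0.1, 0.2), method = "bonferroni", m = 1),
               class = "rrst_argument_error")
  expect_error(adjust_pvalues(1.2), class = "rrst_argument_error")
})

test_that("linear model: exact fit, normal-equations oracle, collinearity", {
  set.seed(18)
  df <- tibble::tibble(x = rnorm(30), z = rnorm(30))
  df$y <- 2 + 3 * df$x - 1.5 * df$z
  fit <- fit_linear_model(df, y ~ x + z)
  expect_equal(glance(fit)$r_squared, 1, tolerance = 1e-12)
  expect_equal(tidy(fit)$estimate, c(2, 3, -1.5), tolerance = 1e-10)

  # 10-row dataset against the direct normal-equations solve
  df2 <- tibble::tibble(x1 = rnorm(10), x2 = rnorm(10),
                        y = rnorm(10, 1))
  fit2 <- fit_linear_model(df2, y ~ x1 + x2)
  X <- cbind(1, df2$x1, df2$x2)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% df2$y)
  expect_equal(tidy(fit2)$estimate, as.numeric(beta_oracle),
               tolerance = 1e-10)

  # collinear design is refused with the term named
  df3 <- df2; df3$x3 <- df3$x1 * 2
  expect_error(fit_linear_model(df3, y ~ x1 + x2 + x3),
               class = "rrst_argument_error")
})

test_that("HC is the reference level so the interaction is the FND slope gap", {
  set.seed(19)
  co <- generate_cohort(seed = 19)
  fit <- fit_linear_model(co, sdq20 ~ sensitivity_true * group + medication)
  td <- tidy(fit)
  expect_true("sensitivity_true:groupFND" %in% td$term)
  # with FND-only negative coupling, the interaction coefficient is negative
  signs <- vapply(1:40, function(s) {
    co <- generate_cohort(seed = s + 100)
    f <- fit_linear_model(co, sdq20 ~ sensitivity_true * group)
    tidy(f)$estimate[tidy(f)$term == "sensitivity_true:groupFND"]
  }, numeric(1))
  expect_gte(mean(signs < 0), 0.9)
})

test_that("tests are invariant to observation order", {
  set.seed(20)
  x <- rnorm(15); y <- rnorm(18, 0.5)
  ix <- sample(15); iy <- sample(18)
  expect_equal(welch_t(x, y), welch_t(x[ix], y[iy]))
  expect_equal(mann_whitney(x, y)$p_value, mann_whitney(x[ix], y[iy])$p_value)
  xy <- cbind(rnorm(12), rnorm(12))
  io <- sample(12)
  expect_equal(pearson_r(xy[, 1], xy[, 2])$estimate,
               pearson_r(xy[io, 1], xy[io, 2])$estimate)
})
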