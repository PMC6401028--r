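test_that("two-sample test routes through the Shapiro-Wilk gate", {
  set.seed(101)
  x <- rnorm(15); y <- rnorm(15)
  r <- two_sample_test(x, y)
  expect_equal(r$method, "welch_t")
  expect_true(all(r$shapiro_p >= 0.05))

  # heavily skewed data fails the gate and takes the permutation path
  xs <- c(0.01, 0.02, 0.02, 0.03, 0.05, 12, 15)
  r2 <- two_sample_test(xs, rnorm(10))
  expect_equal(r2$method, "permutation")
  expect_true(any(r2$shapiro_p < 0.05))
})

test_that("identical and degenerate samples give p = 1", {
  x <- c(1, 2, 3, 4, 5)
  r <- two_sample_test(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # zero variance in both samples with equal means (permutation path)
  r2 <- two_sample_test(rep(2, 4), rep(2, 4), method = "permutation")
  expect_equal(r2$p_value, 1)
  expect_error(two_sample_test(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("exhaustive permutation matches the enumeration value", {
  r <- two_sample_test(c(1, 2, 3), c(4, 5, 6), method = "permutation")
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / 20)
  expect_equal(r$statistic, -3)
})

test_that("Monte Carlo permutation converges to the exhaustive p", {
  x <- c(0.3, 1.1, 2.2, 2.9); y <- c(1.8, 3.4, 4.1, 5.0)
  exact <- two_sample_test(x, y, method = "permutation")$p_value
  mc <- two_sample_test(x, y, method = "permutation", max_exact = 1,
                        B = 1e5, seed = 9)$p_value
  expect_lt(abs(mc - exact), 0.005)
})

test_that("univariate screen reports signed R, RMSE and Bonferroni flags", {
  set.seed(33)
  x <- rnorm(20)
  screen <- suppressWarnings(  # exact fit: lm warns about perfect R^2
    univariate_screen(3 - 2 * x, data.frame(x = x)))
  expect_equal(screen$R, -1, tolerance = 1e-9)
  expect_equal(screen$RMSE, 0, tolerance = 1e-9)

  preds <- data.frame(a = x, b = rnorm(20), const = rep(1, 20))
  sc <- univariate_screen(3 - 2 * x + rnorm(20, sd = 0.3), preds)
  expect_true(sc$degenerate[sc$predictor == "const"])
  expect_equal(sc$R[sc$predictor == "const"], 0)
  expect_equal(attr(sc, "family_size"), 3L)
  # Bonferroni monotonicity: corrected significance implies raw
  expect_true(all(!sc$sig_bonf_05 | sc$p_raw < 0.05))
})

test_that("screen false-positive rate matches Bonferroni control", {
  set.seed(44)
  m <- 23L
  flags_raw <- flags_bonf <- 0L
  reps <- 150L
  for (i in seq_len(reps)) {
    y <- rnorm(20)
    preds <- as.data.frame(matrix(rnorm(20 * m), 20))
    sc <- univariate_screen(y, preds)
    flags_raw <- flags_raw + sum(sc$p_raw < 0.05)
    flags_bonf <- flags_bonf + sum(sc$sig_bonf_05)
  }
  # raw: ~ alpha * m per family; corrected: ~ alpha per family
  expect_lt(abs(flags_raw / reps - 0.05 * m), 0.4)
  expect_lt(flags_bonf / reps, 0.15)
})

test_that("AICc matches its closed form", {
  set.seed(55)
  df <- data.frame(x = rnorm(25))
  df$y <- 1 + 2 * df$x + rnorm(25, sd = 0.4)
  fit <- lm(y ~ x, data = df)
  ll <- logLik(fit)
  k <- attr(ll, "df"); n <- nobs(fit)
  expect_equal(aicc(fit),
               -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  expect_equal(aicc(loglik = -10, k = 3, n = 20),
               20 + 6 + 2 * 3 * 4 / 16)
  expect_equal(aicc(loglik = -10, k = 10, n = 11), Inf)
})

test_that("response model recovers a linear signal and matches the screen", {
  set.seed(66)
  df <- data.frame(x = runif(40, -2, 2))
  df$y <- 2 * df$x + rnorm(40, sd = 0.01)
  fit <- fit_response_model(df, "y", linear = "x")
  expect_lt(abs(coef(fit$fit)["x"] - 2) / 2, 0.01)
  expect_gt(fit$deviance_explained, 0.99)
  expect_gt(fit$effect_direction["x"], 0)

  # simple-regression R^2 equals one-term linear deviance explained
  df2 <- data.frame(x = rnorm(30))
  df2$y <- 0.8 * df2$x + rnorm(30, sd = 0.7)
  sc <- univariate_screen(df2$y, df2["x"])
  f2 <- fit_response_model(df2, "y", linear = "x")
  expect_equal(sc$R^2, f2$deviance_explained, tolerance = 1e-9)
})

test_that("shrinkage smooths collapse on pure-noise responses", {
  set.seed(77)
  dv <- replicate(100, {
    df <- data.frame(y = rnorm(50), x = rnorm(50))
    f <- fit_response_model(df, "y", smooth = "x")
    c(f$deviance_explained, sum(f$edf))
  })
  expect_lt(mean(dv[1, ]), 0.15)
  expect_lt(mean(dv[2, ]), 1)
})

test_that("model comparison ranks by AICc and F-tests nested deviance", {
  set.seed(88)
  df <- data.frame(x = rnorm(30), z = rnorm(30))
  df$y <- 1.5 * df$x + rnorm(30, sd = 0.5)
  f_x <- fit_response_model(df, "y", linear = "x")
  f_xz <- fit_response_model(df, "y", linear = c("x", "z"))
  cmp <- compare_models(list(a = f_x, b = f_x, full = f_xz),
                        nested_pairs = list(c("a", "full")))
  expect_equal(cmp$ranking$delta_AICc[cmp$ranking$model == "b"],
               cmp$ranking$delta_AICc[cmp$ranking$model == "a"])

  # hand oracle from residual sums of squares
  rss1 <- sum(resid(lm(y ~ x, df))^2)
  rss2 <- sum(resid(lm(y ~ x + z, df))^2)
  f_oracle <- ((rss1 - rss2) / 1) / (rss2 / 27)
  expect_equal(cmp$anova$F, f_oracle, tolerance = 1e-8)
  expect_equal(cmp$anova$p_value,
               pf(f_oracle, 1, 27, lower.tail = FALSE), tolerance = 1e-8)

  # adding a useless term never reports a negative F
  f_z <- fit_response_model(df, "y", linear = "z")
  cmp2 <- compare_models(list(z = f_z, x = f_x),
                         nested_pairs = list(c("x", "x")))
  expect_equal(cmp2$anova$F, 0)
})

test_that("interaction models include the product term", {
  set.seed(99)
  df <- data.frame(a = rnorm(30), b = rnorm(30))
  df$y <- df$a + df$b + 2 * df$a * df$b + rnorm(30, sd = 0.1)
  f <- fit_response_model(df, "y", linear = c("a", "b"),
                          interaction = c("a", "b"))
  expect_true("a:b" %in% names(coef(f$fit)))
  expect_lt(abs(coef(f$fit)["a:b"] - 2), 0.1)
})
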