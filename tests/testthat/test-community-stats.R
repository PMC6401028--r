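test_that("Bray-Curtis matches hand-computed values and bounds", {
  m <- rbind(a = c(1, 0, 3), b = c(0, 2, 1), c = c(1, 0, 3))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 5 / 7)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))

  disjoint <- rbind(x = c(1, 1, 0, 0), y = c(0, 0, 2, 3))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)

  expect_error(bray_curtis(rbind(c(1, 2), c(0, 0))), "all-zero")
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "non-negative")
})

test_that("NMDS recovers realizable configurations with ~zero stress", {
  # three mutually equidistant sites embed exactly in the plane
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  o3 <- nmds(d3, k = 2, seed = 1)
  expect_lte(o3$stress, 1e-6)

  # distances from a planted 2-D configuration are fully recoverable
  set.seed(12)
  X <- matrix(runif(24), 12, 2)
  d <- as.matrix(dist(X))
  o <- nmds(d, k = 2, seed = 2)
  expect_lte(o$stress, 0.01)
  # recovered distances correlate with the planted ones
  expect_gt(cor(lower_d(as.matrix(dist(o$points))), lower_d(d)), 0.99)
})

test_that("NMDS stress is non-increasing in k and rank-invariant", {
  set.seed(13)
  m <- matrix(abs(rnorm(48)), 8, 6)
  d <- bray_curtis(m)
  s2 <- nmds(d, k = 2, seed = 3)$stress
  s3 <- nmds(d, k = 3, seed = 3)$stress
  expect_lte(s3, s2 + 1e-9)

  # any strictly monotone transform of the dissimilarities leaves the
  # rank-based stress unchanged
  s2_sq <- nmds(d^2, k = 2, seed = 3)$stress
  expect_equal(s2_sq, s2, tolerance = 1e-6)
})

test_that("NMDS output orientation is canonical and seeded runs repeat", {
  set.seed(14)
  d <- bray_curtis(matrix(abs(rnorm(40)), 8, 5))
  o1 <- nmds(d, seed = 7)
  o2 <- nmds(d, seed = 7)
  expect_identical(o1$points, o2$points)
  expect_true(all(colSums(o1$points) >= -1e-9))
  expect_equal(colMeans(o1$points), c(0, 0), tolerance = 1e-9)
})

test_that("PERMANOVA partitions the total sum of squares exactly", {
  set.seed(15)
  for (i in 1:10) {
    n <- sample(8:14, 1)
    m <- matrix(abs(rnorm(n * 5)), n, 5)
    d <- bray_curtis(m)
    df <- data.frame(x = rnorm(n), g = sample(c("u", "v"), n, TRUE),
                     z = runif(n))
    pt <- permanova(d, df, c("x", "g", "z"), n_perm = 99, seed = i)
    ss <- pt$SumsOfSqs
    expect_equal(sum(ss[1:4]), ss[5], tolerance = 1e-9)
    expect_equal(sum(pt$R2[1:4]), 1, tolerance = 1e-9)
  }
})

test_that("PERMANOVA on Euclidean distances reproduces classical ANOVA", {
  set.seed(16)
  y <- rnorm(12)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- as.matrix(dist(y))
  pt <- permanova(d, data.frame(g = g), "g", n_perm = 99, seed = 1)
  f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(pt$F.model[1], f_aov, tolerance = 1e-9)
  expect_equal(pt$Df[1], 2L)
})

test_that("exhaustive PERMANOVA p equals an independent enumeration oracle", {
  set.seed(17)
  m <- matrix(abs(rnorm(30)), 6, 5)
  d <- bray_curtis(m)
  g <- rep(c("A", "B"), each = 3)

  # oracle: classical distance-based F over all label assignments
  f_stat <- function(d, g) {
    n <- length(g)
    ss_tot <- sum(d[lower.tri(d)]^2) / n
    ss_w <- 0
    for (lv in unique(g)) {
      idx <- which(g == lv)
      dd <- d[idx, idx]
      ss_w <- ss_w + sum(dd[lower.tri(dd)]^2) / length(idx)
    }
    ((ss_tot - ss_w) / 1) / (ss_w / (n - 2))
  }
  f_obs <- f_stat(d, g)
  assigns <- combn(6, 3)
  f_all <- apply(assigns, 2, function(idx) {
    gg <- rep("B", 6); gg[idx] <- "A"
    f_stat(d, gg)
  })
  p_oracle <- mean(f_all >= f_obs - 1e-12)

  pt <- permanova(d, data.frame(g = g), "g", n_perm = 720, seed = 1)
  expect_true(attr(pt, "exhaustive"))
  expect_equal(pt$F.model[1], f_obs, tolerance = 1e-9)
  expect_equal(pt$p[1], p_oracle, tolerance = 1e-12)
})

test_that("PERMANOVA agrees with vegan's sequential adonis on SS and F", {
  skip_if_not_installed("vegan")
  set.seed(18)
  m <- matrix(abs(rnorm(60)), 10, 6)
  d <- bray_curtis(m)
  df <- data.frame(x = rnorm(10), g = rep(c("a", "b"), 5))
  pt <- permanova(d, df, c("x", "g"), n_perm = 199, seed = 1)
  va <- vegan::adonis2(as.dist(d) ~ x + g, data = df, by = "terms",
                       permutations = 199)
  expect_equal(pt$SumsOfSqs[1:3], va$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(pt$F.model[1:2], va$F[1:2], tolerance = 1e-9)
  expect_equal(pt$R2[1:2], va$R2[1:2], tolerance = 1e-9)
})

test_that("PERMANOVA rejects degenerate terms and missing values", {
  d <- bray_curtis(matrix(abs(rnorm(25)), 5, 5))
  df <- data.frame(c1 = rep(1, 5), x = c(1, 2, NA, 4, 5))
  expect_error(permanova(d, df, "c1", n_perm = 99), "degrees of freedom")
  expect_error(permanova(d, df, "x", n_perm = 99), "missing values")
  expect_error(permanova(d, df["x"], "x", n_perm = 50), "n_perm")
})
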