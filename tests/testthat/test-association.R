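test_that("Spearman statistic matches the d-squared closed form and limits", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  r <- spearman_test(x, y)
  expect_equal(r$rs, oracle_spearman_d2(x, y))  # 0.8 for this arrangement
  expect_equal(r$n, 5)

  expect_equal(spearman_test(1:8, exp(1:8))$rs, 1)
  expect_equal(spearman_test(1:8, rev(1:8))$rs, -1)
  expect_equal(spearman_test(1:8, exp(1:8))$p, 0)  # limiting value at |rs| = 1
})

test_that("Spearman p follows the t transform with n - 2 degrees of freedom", {
  set.seed(20)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  r <- spearman_test(x, y)
  t_stat <- r$rs * sqrt((r$n - 2) / (1 - r$rs^2))
  expect_equal(r$p, 2 * pt(-abs(t_stat), r$n - 2))
  expect_gte(r$p, 0); expect_lte(r$p, 1)
  # tie-free large-ish n: agrees with the stats:: AS89 path to rounding
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(r$rs, unname(ct$estimate))
})

test_that("rank correlation is invariant under monotone maps and antisymmetric", {
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(15); y <- rnorm(15)
    base <- spearman_test(x, y)$rs
    expect_equal(spearman_test(exp(x), y)$rs, base, tolerance = 1e-12)
    expect_equal(spearman_test(x, y^3 + 5 * y)$rs, base, tolerance = 1e-12)
    expect_equal(spearman_test(-x, y)$rs, -base, tolerance = 1e-12)
  }
})

test_that("constant inputs raise an undefined-correlation error", {
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r2(1:5, rep(2, 5)), "constant")
  expect_error(spearman_test(1:2, 1:2), "at least 3")
})

test_that("Pearson r-squared matches the covariance formula and its limits", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.3, 2.8)
  y <- c(2.0, 6.1, 5.0, 9.9, 9.1, 1.2, 6.3)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r2(x, y), (num / den)^2, tolerance = 1e-12)

  expect_equal(pearson_r2(x, 2 * x + 1), 1)

  set.seed(22)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(pearson_r2(a, b), 0.01)  # independent noise at large n
})

test_that("assoc bundles rs, p and r2 consistently", {
  set.seed(23)
  x <- rnorm(40); y <- x + rnorm(40)
  a <- assoc(x, y)
  expect_equal(a$rs, spearman_test(x, y)$rs)
  expect_equal(a$r2, pearson_r2(x, y))
})

test_that("bootstrap of a contrast against itself is degenerate at zero", {
  set.seed(24)
  age <- rnorm(30, 40, 10)
  v <- -2 * age + rnorm(30, 0, 5)
  b <- bootstrap_corr_difference(age, list(a = v, b = v), "rs",
                                 n_boot = 200, seed = 1)
  expect_equal(b$pairs$lower, 0)
  expect_equal(b$pairs$upper, 0)
  expect_equal(b$pairs$median, 0)
  expect_true(b$pairs$ci_includes_zero)
})

test_that("bootstrap intervals are reproducible from the seed and well ordered", {
  set.seed(25)
  age <- rnorm(40, 40, 10)
  contrasts <- list(one = -age + rnorm(40, 0, 8),
                    two = -0.5 * age + rnorm(40, 0, 8),
                    three = rnorm(40))
  b1 <- bootstrap_corr_difference(age, contrasts, "rs", n_boot = 500, seed = 9)
  b2 <- bootstrap_corr_difference(age, contrasts, "rs", n_boot = 500, seed = 9)
  expect_identical(b1$pairs, b2$pairs)
  expect_equal(nrow(b1$pairs), 3)  # all unordered pairs of 3 contrasts
  expect_true(all(b1$pairs$lower <= b1$pairs$median))
  expect_true(all(b1$pairs$median <= b1$pairs$upper))

  br2 <- bootstrap_corr_difference(age, contrasts, "r2", n_boot = 200, seed = 9)
  expect_true(all(br2$pairs$lower >= -1 & br2$pairs$upper <= 1))

  expect_error(bootstrap_corr_difference(age, contrasts, "rs", n_boot = 0),
               "n_boot")
  expect_error(bootstrap_corr_difference(age, list(a = age), "rs"), "at least 2")
})

test_that("degenerate bootstrap resamples are redrawn, keeping n_boot replicates", {
  # a contrast with a single outlying value often resamples to a constant
  age <- c(rep(1, 9), 2)
  v <- c(rep(0, 9), 1)
  b <- bootstrap_corr_difference(age + seq(0.001, 0.01, length.out = 10),
                                 list(a = v, b = rev(v)), "rs",
                                 n_boot = 100, seed = 3)
  expect_gt(b$n_redrawn, 0)
  expect_false(any(is.na(b$pairs$median)))
})
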