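test_that("consistency ICC equals the loop-based ANOVA oracle on random tables", {
  set.seed(30)
  for (rep in 1:50) {
    x <- matrix(rnorm(12, sd = runif(1, 0.5, 3)), 6, 2)
    expect_equal(icc(x)$icc, oracle_icc_anova(x), tolerance = 1e-10)
  }
  # and the one-way form against its own oracle
  for (rep in 1:10) {
    x <- matrix(rnorm(12), 6, 2)
    expect_equal(icc(x, model = "one-way")$icc, oracle_icc_oneway(x),
                 tolerance = 1e-10)
  }
})

test_that("consistency ICC is exactly 1 for identical or shifted measurements", {
  x <- rnorm(8, 100, 10)
  expect_equal(icc(cbind(x, x))$icc, 1)
  r <- icc(cbind(x, x + 12.5))  # additive bias between scans
  expect_equal(r$icc, 1)
  expect_equal(r$ci95, c(1, 1))
  expect_equal(r$p, 0)
  # the one-way (absolute) form is penalised by the same shift
  expect_lt(icc(cbind(x, x + 12.5), model = "one-way")$icc, 1)
})

test_that("ICC never exceeds 1 and recovers the generating variance ratio", {
  set.seed(31)
  for (rep in 1:20) {
    x <- matrix(rnorm(20), 10, 2) + rnorm(10)
    expect_lte(icc(x)$icc, 1)
  }
  # subjects with variance 4, residual noise with variance 1:
  # expected consistency = 4 / (4 + 1) = 0.8
  n <- 500
  subj <- rnorm(n, 0, 2)
  x <- cbind(subj + rnorm(n), subj + rnorm(n))
  expect_lt(abs(icc(x)$icc - 0.8), 0.02)
})

test_that("ICC confidence interval brackets the estimate and respects the F quantiles", {
  set.seed(32)
  subj <- rnorm(12, 0, 3)
  x <- cbind(subj + rnorm(12), subj + rnorm(12))
  r <- icc(x)
  expect_lte(r$ci95[1], r$icc)
  expect_gte(r$ci95[2], r$icc)
  f_upper <- qf(0.975, r$df1, r$df2)
  expect_equal(r$ci95[1],
               (r$f_value / f_upper - 1) / (r$f_value / f_upper + 1))
  expect_error(icc(matrix(5, 4, 2)), "degenerate")
  expect_error(icc(matrix(1:4, 1, 4)), "at least 2 subjects")
})

test_that("voxel-wise ICC maps agree with the scalar computation per voxel", {
  n <- 8
  a <- rand_map_set(n, dims = c(4L, 4L, 4L), seed = 33)
  b <- rand_map_set(n, dims = c(4L, 4L, 4L), seed = 34)
  b$values <- a$values + 0.3 * b$values
  mask <- inclusion_mask(a, 0, 0.5)
  m <- icc_map(a, b, mask)
  for (v in list(c(1, 1, 1), c(3, 2, 4), c(4, 4, 4))) {
    expect_equal(m[v[1], v[2], v[3]],
                 icc(cbind(a$values[v[1], v[2], v[3], ],
                           b$values[v[1], v[2], v[3], ]))$icc,
                 tolerance = 1e-10)
  }
  # retest identical to test: 1 everywhere in the mask
  self <- icc_map(a, a, mask)
  expect_true(all(abs(self[!is.na(self)] - 1) < 1e-12))
})

test_that("degenerate voxels in ICC maps are missing, counted by brute force", {
  n <- 6
  a <- rand_map_set(n, dims = c(3L, 3L, 3L), seed = 35)
  b <- rand_map_set(n, dims = c(3L, 3L, 3L), seed = 36)
  # make a few voxels exactly constant across participants and scans
  for (v in list(c(1, 1, 1), c(2, 2, 2), c(3, 1, 2))) {
    a$values[v[1], v[2], v[3], ] <- 4
    b$values[v[1], v[2], v[3], ] <- 4
  }
  mask <- inclusion_mask(a, 0, 0.5)
  m <- icc_map(a, b, mask)
  brute_degenerate <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    tab <- cbind(a$values[i, j, k, ], b$values[i, j, k, ])
    if (isTRUE(all.equal(var(as.vector(tab)), 0))) {
      brute_degenerate <- brute_degenerate + 1
    }
  }
  expect_equal(sum(is.na(m)), brute_degenerate)
  expect_error(icc_map(rand_map_set(1), rand_map_set(1), mask), "fewer than 2")
})
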