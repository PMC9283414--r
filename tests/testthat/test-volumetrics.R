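test_that("global volumes equal an exhaustive scalar-loop summation", {
  maps <- rand_map_set(3, dims = c(8L, 8L, 8L), seed = 11)
  got <- global_volumes(maps)$volume
  for (p in 1:3) {
    acc <- 0
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      acc <- acc + maps$values[i, j, k, p]
    expect_equal(got[p], acc, tolerance = 1e-9)
  }
})

test_that("global volumes handle trivial cases and scale linearly", {
  zeros <- tissue_map_set(array(0, c(2, 2, 2, 3)), "GM", "s", c(1, 1, 1),
                          paste0("p", 1:3))
  expect_equal(global_volumes(zeros)$volume, c(0, 0, 0))

  one <- tissue_map_set(array(c(1, 2.5, 0.5, 0, 0, 0, 0, 0), c(2, 2, 2, 1)),
                        "GM", "s", c(1, 1, 1), "p1")
  expect_equal(global_volumes(one)$volume, 4.0)

  maps <- rand_map_set(4, seed = 2)
  scaled <- maps
  scaled$values <- 2.5 * maps$values
  expect_equal(global_volumes(scaled)$volume, 2.5 * global_volumes(maps)$volume)
})

test_that("map sets reject non-finite voxels, naming the culprit", {
  vals <- array(1, c(2, 2, 2, 2))
  vals[1, 2, 1, 2] <- NaN
  expect_error(tissue_map_set(vals, "GM", "s", c(1, 1, 1), c("pA", "pB")),
               "participant pB.*\\[1, 2, 1\\]")
})

test_that("inclusion mask uses the ceiling participant-count rule", {
  # one voxel, 4 participants: required count is ceiling(0.95 * 4) = 4,
  # only 3 reach the threshold -> excluded
  vals <- array(c(0.0009, 0.002, 0.002, 0.002), c(1, 1, 1, 4))
  maps <- tissue_map_set(vals, "GM", "s", c(1, 1, 1), paste0("p", 1:4))
  m <- inclusion_mask(maps, threshold = 0.001, fraction = 0.95)
  expect_equal(m$required_count, 4)
  expect_false(m$mask[1, 1, 1])
  # relaxing the fraction to 0.75 admits it
  expect_true(inclusion_mask(maps, 0.001, 0.75)$mask[1, 1, 1])

  all_in <- rand_map_set(5, seed = 3)
  all_in$values <- all_in$values + 1
  expect_true(all(inclusion_mask(all_in, 0.001, 0.95)$mask))

  # fraction 1: a single sub-threshold participant excludes the voxel
  vals2 <- array(1, c(2, 1, 1, 3)); vals2[1, 1, 1, 2] <- 0
  maps2 <- tissue_map_set(vals2, "GM", "s", c(1, 1, 1), paste0("p", 1:3))
  m2 <- inclusion_mask(maps2, 0.5, 1.0)
  expect_false(m2$mask[1, 1, 1])
  expect_true(m2$mask[2, 1, 1])

  expect_error(inclusion_mask(maps2, 0.5, 0), "fraction")
  expect_error(inclusion_mask(maps2, 0.5, 1.2), "fraction")
})

test_that("raising the inclusion threshold never adds voxels", {
  maps <- rand_map_set(10, seed = 4)
  prev <- inclusion_mask(maps, 0, 0.9)$mask
  for (thr in c(0.2, 0.5, 0.8)) {
    cur <- inclusion_mask(maps, thr, 0.9)$mask
    expect_false(any(cur & !prev))  # no voxel appears as the rule tightens
    prev <- cur
  }
})

test_that("voxel-wise correlation matches a per-voxel rank oracle and flags degeneracy", {
  a <- rand_map_set(12, dims = c(4L, 4L, 4L), seed = 5)
  b <- rand_map_set(12, dims = c(4L, 4L, 4L), seed = 6)
  b$values <- 0.5 * a$values + 0.5 * b$values
  mask <- inclusion_mask(a, 0, 0.5)
  cmap <- voxelwise_correlation(a, b, mask, method = "spearman")
  for (v in list(c(1, 1, 1), c(2, 3, 4), c(4, 4, 4))) {
    expect_equal(cmap[v[1], v[2], v[3]],
                 cor(rank(a$values[v[1], v[2], v[3], ]),
                     rank(b$values[v[1], v[2], v[3], ])),
                 tolerance = 1e-12)
  }
  # identical inputs: correlation 1 inside the mask
  self <- voxelwise_correlation(a, a, mask)
  expect_true(all(abs(self[!is.na(self)] - 1) < 1e-12))

  # a constant voxel yields NA, not zero
  a2 <- a
  a2$values[2, 2, 2, ] <- 7
  cmap2 <- voxelwise_correlation(a2, b, mask)
  expect_true(is.na(cmap2[2, 2, 2]))
})

test_that("Spearman voxel maps are symmetric and monotone-transform invariant", {
  a <- rand_map_set(9, dims = c(3L, 3L, 3L), seed = 7)
  b <- rand_map_set(9, dims = c(3L, 3L, 3L), seed = 8)
  mask <- inclusion_mask(a, 0, 0.5)
  ab <- voxelwise_correlation(a, b, mask)
  ba <- voxelwise_correlation(b, a, mask)
  expect_equal(unclass(ab), unclass(ba), tolerance = 1e-12)
  bt <- b
  bt$values <- exp(3 * b$values)  # strictly monotone per-voxel transform
  expect_equal(unclass(voxelwise_correlation(a, bt, mask)), unclass(ab),
               tolerance = 1e-12)
})

test_that("FoV reduction zeroes outside the mask, is idempotent and monotone", {
  maps <- rand_map_set(5, dims = c(6L, 6L, 6L), seed = 9)
  all_true <- array(TRUE, c(6, 6, 6))
  expect_equal(reduce_fov(maps, all_true)$values, maps$values)

  uniform <- tissue_map_set(array(2, c(6, 6, 6, 2)), "GM", "s", c(1, 1, 1),
                            c("p1", "p2"))
  half <- array(TRUE, c(6, 6, 6)); half[, , 4:6] <- FALSE
  expect_equal(global_volumes(reduce_fov(uniform, half))$volume,
               global_volumes(uniform)$volume / 2)

  # nested masks: m1 within m2 implies volumes under m1 <= volumes under m2,
  # participant by participant
  set.seed(10)
  m2 <- array(runif(216) > 0.3, c(6, 6, 6))
  m1 <- m2 & array(runif(216) > 0.3, c(6, 6, 6))
  m1[1, 1, 1] <- m2[1, 1, 1] <- TRUE
  v1 <- global_volumes(reduce_fov(maps, m1))$volume
  v2 <- global_volumes(reduce_fov(maps, m2))$volume
  expect_true(all(v1 <= v2 + 1e-12))

  once <- reduce_fov(maps, m2)
  twice <- reduce_fov(once, m2)
  expect_equal(twice$values, once$values)

  expect_error(reduce_fov(maps, array(FALSE, c(6, 6, 6))), "empty")
  expect_error(reduce_fov(maps, array(TRUE, c(5, 6, 6))), "shape")
})

test_that("distribution summaries follow the linear-interpolation convention", {
  expect_equal(summarize_distribution(c(1, 2, 3))[["median"]], 2)
  expect_equal(summarize_distribution(c(1, 2, 3, 4))[["median"]], 2.5)
  set.seed(11)
  x <- rnorm(101)
  s <- summarize_distribution(x)
  expect_equal(s[["median"]], oracle_quantile(x, 0.5), tolerance = 1e-12)
  expect_equal(s[["q1"]], oracle_quantile(x, 0.25), tolerance = 1e-12)
  expect_equal(s[["q3"]], oracle_quantile(x, 0.75), tolerance = 1e-12)
  expect_equal(summarize_distribution(c(1, NA, 3))[["median"]], 2)
  expect_error(summarize_distribution(c(NA_real_, NA_real_)), "data error")
})
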