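# Independent oracles used across the suite: deliberately naive loop/sort
# implementations, kept separate from the package's vectorised code paths.

# Two-way ANOVA ICC(3,1) by explicit sum-of-squares loops.
oracle_icc_anova <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssb <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (mean(x[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - grand)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (x[i, j] - grand)^2
  msb <- ssb / (n - 1)
  mse <- (sst - ssb - ssc) / ((n - 1) * (k - 1))
  (msb - mse) / (msb + (k - 1) * mse)
}

# One-way ICC(1,1) by the same explicit route.
oracle_icc_oneway <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssb <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (mean(x[i, ]) - grand)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (x[i, j] - grand)^2
  msb <- ssb / (n - 1)
  msw <- (sst - ssb) / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# Tie-free Spearman via the classical d^2 formula.
oracle_spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Quantile by explicit sort-and-index linear interpolation (type-7 rule).
oracle_quantile <- function(values, p) {
  s <- sort(values)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Mean of a truncated normal by numerical integration.
oracle_truncnorm_mean <- function(mean, sd, lo, hi) {
  z <- stats::integrate(function(x) stats::dnorm(x, mean, sd), lo, hi)$value
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd), lo, hi)$value / z
}

# Leave-one-out OLS by refitting from scratch with explicit sums.
oracle_loo_ols <- function(x, y, i) {
  xi <- x[-i]; yi <- y[-i]
  m <- length(xi)
  sxy <- sum(xi * yi) - sum(xi) * sum(yi) / m
  sxx <- sum(xi^2) - sum(xi)^2 / m
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(yi) - slope * mean(xi))
}

# Small-footprint generator configuration for structural tests.
tiny_cfg <- function(...) {
  args <- list(n_participants = 8, n_retest = 3, grid_shape = c(8L, 8L, 8L),
               voxel_dims = c(2, 2, 2), fov_drop_slices = 1L, seed = 42L)
  do.call(rapid_config, utils::modifyList(args, list(...)))
}

# A map set filled with reproducible uniform noise.
rand_map_set <- function(n, dims = c(6L, 6L, 6L), seed = 1L, tissue = "GM",
                         sequence = "test") {
  set.seed(seed)
  tissue_map_set(array(stats::runif(prod(dims) * n), dim = c(dims, n)),
                 tissue, sequence, c(1, 1, 1), sprintf("p%02d", seq_len(n)))
}
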