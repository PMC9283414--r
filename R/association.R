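#' Spearman rank correlation with a t-approximation p-value
#'
#' `rs` is the Pearson correlation of average-ranked values (ties receive the
#' mean rank). The two-sided p-value uses the transform
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` with `n - 2` degrees of freedom;
#' `|rs| = 1` reports the limiting value 0.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite, non-constant.
#' @return A list of class `association_result`: `rs`, `p`, `n` (and `r2`,
#'   `NA` here; see [assoc()]).
#' @examples
#' r <- spearman_test(1:10, (1:10)^3)
#' r$rs  # 1: invariant under monotone transformation
#' @export
spearman_test <- function(x, y) {
  check_assoc_input(x, y)
  rs <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rs) >= 1) 0 else {
    t_stat <- rs * sqrt((n - 2) / (1 - rs^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  structure(list(rs = rs, p = p, r2 = NA_real_, n = n),
            class = "association_result")
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, finite, non-constant.
#' @return The square of the sample Pearson coefficient, in `[0, 1]`.
#' @export
pearson_r2 <- function(x, y) {
  check_assoc_input(x, y)
  stats::cor(x, y)^2
}

#' Association summary: Spearman rs, p, and Pearson r-squared
#'
#' The standard per-comparison record of this package: rank correlation with
#' its t-approximation p-value plus the proportion of variance explained.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite, non-constant.
#' @return A list of class `association_result`: `rs`, `p`, `r2`, `n`.
#' @export
assoc <- function(x, y) {
  out <- spearman_test(x, y)
  out$r2 <- pearson_r2(x, y)
  out
}

check_assoc_input <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  invisible(NULL)
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("rs = %.3f, p = %.3g, r2 = %s (n = %d)\n", x$rs, x$p,
              ifelse(is.na(x$r2), "-", sprintf("%.3f", x$r2)), x$n))
  invisible(x)
}

## rs / r2 of already-resampled columns; NA where either column is constant.
boot_statistic <- function(age_cols, contrast_cols, statistic) {
  if (statistic == "rs") {
    age_cols <- col_ranks(age_cols)
    contrast_cols <- col_ranks(contrast_cols)
  }
  r <- col_correlation(age_cols, contrast_cols)
  if (statistic == "r2") r^2 else r
}

#' Bootstrap test for differences in association strength
#'
#' Assesses whether the strength of the association between `age` and each of
#' several contrasts differs, by resampling participants with replacement.
#' In every replicate the *same* resampled participant indices are applied to
#' all contrasts (the comparison is paired), the statistic (`rs` or `r2`) of
#' each contrast against `age` is re-estimated, and pairwise differences are
#' formed. The percentile 2.5th/97.5th points of each difference distribution
#' give its CI95; a CI covering 0 means no evidence that the two association
#' strengths differ. Replicates where any statistic is undefined (a constant
#' resample) are redrawn, so exactly `n_boot` replicates contribute.
#'
#' @param age Numeric vector (the shared variable of every association).
#' @param contrasts Named list of >= 2 numeric vectors, each the same length
#'   as `age`.
#' @param statistic `"rs"` (Spearman) or `"r2"` (squared Pearson).
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param conf_level Confidence level of the percentile interval.
#' @return An object of class `bootstrap_diff`: `statistic`, `n_boot`,
#'   `seed`, `n`, `n_redrawn`, and `pairs`, a data frame with one row per
#'   contrast pair (`median`, `lower`, `upper`, `ci_includes_zero`).
#' @export
bootstrap_corr_difference <- function(age, contrasts, statistic = c("rs", "r2"),
                                      n_boot = 10000L, seed = 1L,
                                      conf_level = 0.95) {
  statistic <- match.arg(statistic)
  if (n_boot < 1L)
    stop("parameter error: n_boot must be at least 1", call. = FALSE)
  if (!is.list(contrasts) || length(contrasts) < 2L || is.null(names(contrasts)))
    stop("contrasts must be a named list of at least 2 vectors", call. = FALSE)
  n <- length(age)
  if (any(vapply(contrasts, length, 1L) != n))
    stop("all contrast vectors must match the length of age", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)

  set.seed(seed)
  labels <- names(contrasts)
  stat_mat <- matrix(NA_real_, n_boot, length(contrasts),
                     dimnames = list(NULL, labels))
  pending <- seq_len(n_boot)
  n_redrawn <- 0L
  while (length(pending)) {
    idx <- matrix(sample.int(n, n * length(pending), replace = TRUE), n)
    age_cols <- matrix(age[idx], n)
    for (j in seq_along(contrasts))
      stat_mat[pending, j] <- boot_statistic(
        age_cols, matrix(contrasts[[j]][idx], n), statistic)
    bad <- pending[rowSums(is.na(stat_mat[pending, , drop = FALSE])) > 0L]
    n_redrawn <- n_redrawn + length(bad)
    pending <- bad
  }

  pair_idx <- utils::combn(seq_along(contrasts), 2L)
  alpha <- (1 - conf_level) / 2
  pairs <- do.call(rbind, lapply(seq_len(ncol(pair_idx)), function(k) {
    i <- pair_idx[1L, k]; j <- pair_idx[2L, k]
    d <- stat_mat[, i] - stat_mat[, j]
    ci <- stats::quantile(d, c(alpha, 1 - alpha), type = 7, names = FALSE)
    data.frame(contrast_a = labels[i], contrast_b = labels[j],
               median = stats::median(d), lower = ci[1L], upper = ci[2L],
               ci_includes_zero = ci[1L] <= 0 && 0 <= ci[2L],
               stringsAsFactors = FALSE)
  }))
  structure(list(statistic = statistic, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), conf_level = conf_level, n = n,
                 n_redrawn = n_redrawn, pairs = pairs),
            class = "bootstrap_diff")
}

#' @export
print.bootstrap_diff <- function(x, ...) {
  cat(sprintf(
    "Bootstrap difference in %s (%d resamples of %d, paired; seed %d)\n",
    x$statistic, x$n_boot, x$n, x$seed))
  if (x$n_redrawn > 0L)
    cat(sprintf("  %d degenerate replicate(s) redrawn\n", x$n_redrawn))
  for (k in seq_len(nrow(x$pairs))) {
    row <- x$pairs[k, ]
    cat(sprintf("  %s - %s: %+0.3f, CI95 [%+0.3f, %+0.3f]%s\n",
                row$contrast_a, row$contrast_b, row$median, row$lower,
                row$upper,
                if (row$ci_includes_zero) " (includes 0)" else ""))
  }
  invisible(x)
}
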