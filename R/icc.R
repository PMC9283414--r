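#' Intraclass correlation for test-retest consistency
#'
#' Computes the consistency-of-single-measurements intraclass correlation
#' ICC(3,1) from a subjects-by-measurements table via the two-way ANOVA
#' decomposition:
#' \deqn{ICC = (MS_B - MS_E) / (MS_B + (k - 1) MS_E)}
#' with `MS_B` the between-subjects and `MS_E` the residual mean square.
#' Consistency is invariant to an additive shift between measurements (a
#' constant bias between scans does not reduce it). The CI95 comes from the
#' F statistic `MS_B / MS_E` with `(n - 1)` and `(n - 1)(k - 1)` degrees of
#' freedom:
#' `lower = (F/Fu - 1) / (F/Fu + k - 1)` with `Fu` the upper F quantile, and
#' analogously for the upper bound. The one-way random-effects form ICC(1,1)
#' is available via `model = "one-way"`.
#'
#' @param ratings Numeric matrix, subjects in rows (n >= 2), measurements in
#'   columns (k >= 2), no missing cells.
#' @param model `"two-way"` (consistency, ICC(3,1); default) or `"one-way"`
#'   (absolute one-way random effects, ICC(1,1)).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci95` (lower, upper),
#'   `f_value`, `df1`, `df2`, `p`, `n`, `k`, `model`.
#' @examples
#' x <- cbind(1:6, (1:6) + 2)  # constant shift
#' icc(x)$icc  # 1: consistency ignores additive bias
#' @export
icc <- function(ratings, model = c("two-way", "one-way"), conf_level = 0.95) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 measurements", call. = FALSE)
  if (any(!is.finite(ratings)))
    stop("ratings must be complete and finite", call. = FALSE)

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_between <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((ratings - grand)^2)
  ms_between <- ss_between / (n - 1)

  if (model == "two-way") {
    df2 <- (n - 1L) * (k - 1L)
    ms_error <- (ss_total - ss_between - ss_cols) / df2
  } else {
    df2 <- n * (k - 1L)
    ms_error <- (ss_total - ss_between) / df2
  }
  if (ms_between <= 0 && ms_error <= 0)
    stop("degenerate data: no subject or residual variance", call. = FALSE)

  est <- (ms_between - ms_error) / (ms_between + (k - 1) * ms_error)
  alpha <- (1 - conf_level) / 2
  df1 <- n - 1L
  if (ms_error > 0) {
    f_value <- ms_between / ms_error
    p <- stats::pf(f_value, df1, df2, lower.tail = FALSE)
    f_upper <- stats::qf(1 - alpha, df1, df2)
    f_lower <- stats::qf(alpha, df1, df2)
    ci <- c((f_value / f_upper - 1) / (f_value / f_upper + k - 1),
            (f_value / f_lower - 1) / (f_value / f_lower + k - 1))
  } else {
    # perfect agreement: ICC 1 with a point interval
    f_value <- Inf
    p <- 0
    ci <- c(1, 1)
  }
  structure(list(icc = est, ci95 = ci, f_value = f_value, df1 = df1,
                 df2 = df2, p = p, n = n, k = k, model = model,
                 conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  label <- if (x$model == "two-way") "ICC(3,1)" else "ICC(1,1)"
  cat(sprintf("%s = %.3f, CI%.0f [%.3f, %.3f] (n = %d, k = %d, F(%d, %d) = %.2f, p = %.3g)\n",
              label, x$icc, 100 * x$conf_level, x$ci95[1L], x$ci95[2L],
              x$n, x$k, x$df1, x$df2, x$f_value, x$p))
  invisible(x)
}

#' Voxel-wise test-retest reliability map
#'
#' Applies the consistency ICC to every voxel inside the inclusion mask,
#' across the retest participants' two acquisitions. Degenerate voxels (no
#' subject and no residual variance) yield `NA`.
#'
#' @param maps_test,maps_retest [tissue_map_set()]s with the same retest
#'   participants in the same order (at least 2).
#' @param mask An [inclusion_mask()].
#' @param model Passed to [icc()].
#' @return A 3-D array of class `correlation_map` holding ICC values.
#' @export
icc_map <- function(maps_test, maps_retest, mask,
                    model = c("two-way", "one-way")) {
  model <- match.arg(model)
  stopifnot(inherits(maps_test, "tissue_map_set"),
            inherits(maps_retest, "tissue_map_set"),
            inherits(mask, "inclusion_mask"))
  if (!identical(maps_test$participant_id, maps_retest$participant_id))
    stop("alignment error: retest participants differ between map sets",
         call. = FALSE)
  n <- dim(maps_test$values)[4L]
  if (n < 2L)
    stop("data error: fewer than 2 retest participants", call. = FALSE)
  sel <- which(as.vector(mask$mask))
  x1 <- t(matrix(maps_test$values, ncol = n)[sel, , drop = FALSE])   # n x V
  x2 <- t(matrix(maps_retest$values, ncol = n)[sel, , drop = FALSE])
  k <- 2L
  grand <- (colMeans(x1) + colMeans(x2)) / 2
  row_m <- (x1 + x2) / 2
  ss_between <- k * colSums(sweep(row_m, 2L, grand)^2)
  ss_cols <- n * ((colMeans(x1) - grand)^2 + (colMeans(x2) - grand)^2)
  ss_total <- colSums(sweep(x1, 2L, grand)^2) + colSums(sweep(x2, 2L, grand)^2)
  ms_between <- ss_between / (n - 1)
  if (model == "two-way") {
    ms_error <- (ss_total - ss_between - ss_cols) / ((n - 1) * (k - 1))
  } else {
    ms_error <- (ss_total - ss_between) / (n * (k - 1))
  }
  ms_error <- pmax(ms_error, 0)  # guard tiny negative rounding
  denom <- ms_between + (k - 1) * ms_error
  vals <- ifelse(denom > 0, (ms_between - ms_error) / denom, NA_real_)
  out <- array(NA_real_, dim = dim(mask$mask))
  out[sel] <- vals
  structure(out, class = "correlation_map", method = paste0("icc-", model))
}
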