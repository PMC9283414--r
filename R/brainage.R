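#' Median absolute error of an age prediction
#'
#' The headline error metric is the *median* of the absolute prediction
#' errors (robust to the systematic offsets this package studies); the mean
#' is available as an option. The median uses the same linear-interpolation
#' quantile convention as [summarize_distribution()].
#'
#' @param predicted,chronological Numeric vectors of equal, positive length
#'   (years).
#' @param type `"median"` (default) or `"mean"`.
#' @return The error in years.
#' @export
mae <- function(predicted, chronological, type = c("median", "mean")) {
  type <- match.arg(type)
  if (length(predicted) == 0L)
    stop("data error: empty input", call. = FALSE)
  if (length(predicted) != length(chronological))
    stop("predicted and chronological must have equal length", call. = FALSE)
  err <- abs(predicted - chronological)
  if (type == "median") stats::median(err) else mean(err)
}

#' Null-benchmark error: predict one constant age for everyone
#'
#' The worst-possible-model benchmark: the error of predicting the same age
#' (by default 40.6 y, the mean age of the training sample of a widely used
#' reference brain-age model) for every participant.
#'
#' @param chronological Ages in years (non-empty).
#' @param reference_age The constant prediction, years.
#' @param type Passed to [mae()].
#' @return The null error in years.
#' @export
null_mae <- function(chronological, reference_age = 40.6,
                     type = c("median", "mean")) {
  mae(rep(reference_age, length(chronological)), chronological, type = type)
}

#' Fold-improvement of a model over the null benchmark
#'
#' @param null_mae Error of the constant-prediction null model, years.
#' @param mae Error of the model under evaluation, years (> 0).
#' @return `null_mae / mae` (dimensionless; > 1 means better than null, which
#'   is not guaranteed).
#' @examples
#' null_mae_ratio(15.6, 3.72)  # ~4.2-fold better than the null model
#' @export
null_mae_ratio <- function(null_mae, mae) {
  if (mae == 0)
    stop("null MAE ratio undefined: model error is exactly zero", call. = FALSE)
  null_mae / mae
}

#' Leave-one-out regression correction of offset predictions
#'
#' Corrects a systematically offset prediction (`pred_rapid`) by regressing
#' the reference prediction (`pred_standard`) on it. For each participant
#' `i`, an ordinary-least-squares line is fitted on the other `n - 1`
#' participants and the left-out prediction is adjusted to
#' `intercept + slope * pred_rapid[i]`; the overall adjusted error is the
#' [mae()] of these adjusted values against chronological age.
#'
#' @param pred_rapid Predictions to be corrected, years.
#' @param pred_standard Reference predictions regressed on `pred_rapid`,
#'   years.
#' @param chronological Chronological ages, years.
#' @param mae_type Passed to [mae()].
#' @return An object of class `loo_adjustment`: `folds` (data frame with one
#'   row per left-out participant: `slope`, `intercept`, `adjusted`),
#'   `adjusted_mae` and `n`.
#' @export
loo_adjust <- function(pred_rapid, pred_standard, chronological,
                       mae_type = c("median", "mean")) {
  n <- length(pred_rapid)
  if (n < 3L) stop("need at least 3 participants", call. = FALSE)
  if (length(pred_standard) != n || length(chronological) != n)
    stop("all vectors must have equal length", call. = FALSE)
  x <- pred_rapid
  y <- pred_standard
  # leave-one-out OLS via downdated sums
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  m <- n - 1L
  sx_i <- sx - x; sy_i <- sy - y
  sxx_i <- sxx - x^2; sxy_i <- sxy - x * y
  denom <- sxx_i - sx_i^2 / m
  if (any(denom <= .Machine$double.eps * pmax(1, sxx_i)))
    stop("degenerate fit: pred_rapid has (near-)zero variance in a fold",
         call. = FALSE)
  slope <- (sxy_i - sx_i * sy_i / m) / denom
  intercept <- sy_i / m - slope * sx_i / m
  adjusted <- intercept + slope * x
  structure(
    list(folds = data.frame(slope = slope, intercept = intercept,
                            adjusted = adjusted),
         adjusted_mae = mae(adjusted, chronological, type = match.arg(mae_type)),
         n = n),
    class = "loo_adjustment")
}

#' @export
print.loo_adjustment <- function(x, ...) {
  cat(sprintf("Leave-one-out regression adjustment (%d folds)\n", x$n))
  cat(sprintf("  slope: median %.3f; intercept: median %.2f\n",
              stats::median(x$folds$slope), stats::median(x$folds$intercept)))
  cat(sprintf("  adjusted MAE: %.2f years\n", x$adjusted_mae))
  invisible(x)
}

#' Brain-age evaluation metrics for one sequence
#'
#' Assembles the standard per-sequence record: Spearman rs and p against
#' chronological age, Pearson r-squared, the median absolute error, the
#' constant-prediction null error and the null/model error ratio. When the
#' model error is exactly zero the ratio is reported as `NA` with
#' `zero_mae = TRUE`.
#'
#' @param table An `age_prediction_table` (see
#'   [generate_age_predictions()]): must contain `age` and a
#'   `pred_<sequence_label>` column.
#' @param sequence_label E.g. `"standard"`, `"rapid"`,
#'   `"standard_fovreduced"`.
#' @param reference_age Constant prediction of the null benchmark, years.
#' @param mae_type Passed to [mae()].
#' @return A list of class `brainage_metrics`: `sequence`, `rs`, `p`, `r2`,
#'   `mae`, `null_mae`, `null_mae_ratio`, `zero_mae`, `n`.
#' @export
evaluate_sequence <- function(table, sequence_label, reference_age = 40.6,
                              mae_type = c("median", "mean")) {
  mae_type <- match.arg(mae_type)
  column <- paste0("pred_", sequence_label)
  if (!column %in% names(table))
    stop("unknown sequence label '", sequence_label, "': no column ", column,
         call. = FALSE)
  pred <- table[[column]]
  age <- table$age
  a <- assoc(age, pred)
  model_mae <- mae(pred, age, type = mae_type)
  bench <- null_mae(age, reference_age, type = mae_type)
  structure(
    list(sequence = sequence_label, rs = a$rs, p = a$p, r2 = a$r2,
         mae = model_mae, null_mae = bench,
         null_mae_ratio = if (model_mae > 0) bench / model_mae else NA_real_,
         zero_mae = model_mae == 0, n = a$n,
         reference_age = reference_age),
    class = "brainage_metrics")
}

#' @export
print.brainage_metrics <- function(x, ...) {
  cat(sprintf("Brain-age metrics, sequence '%s' (n = %d)\n", x$sequence, x$n))
  cat(sprintf("  rs = %.2f (p = %.3g), r2 = %.2f\n", x$rs, x$p, x$r2))
  cat(sprintf("  MAE = %.2f y; null MAE (ref %.1f y) = %.2f y; ratio = %s\n",
              x$mae, x$reference_age, x$null_mae,
              ifelse(is.na(x$null_mae_ratio), "- (zero MAE)",
                     sprintf("%.2f", x$null_mae_ratio))))
  invisible(x)
}

#' Brain-age summary table across sequences
#'
#' @param table An `age_prediction_table`.
#' @param sequence_labels Labels to evaluate (default: every `pred_*`
#'   column).
#' @param reference_age,mae_type Passed to [evaluate_sequence()].
#' @return A data frame with one row per sequence and columns `sequence`,
#'   `rs`, `p`, `r2`, `mae`, `null_mae`, `null_mae_ratio`, `n`.
#' @export
brainage_table <- function(table, sequence_labels = NULL, reference_age = 40.6,
                           mae_type = c("median", "mean")) {
  if (is.null(sequence_labels))
    sequence_labels <- sub("^pred_", "", grep("^pred_", names(table),
                                              value = TRUE))
  rows <- lapply(sequence_labels, function(lab) {
    m <- evaluate_sequence(table, lab, reference_age, mae_type)
    data.frame(sequence = m$sequence, rs = m$rs, p = m$p, r2 = m$r2,
               mae = m$mae, null_mae = m$null_mae,
               null_mae_ratio = m$null_mae_ratio, n = m$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
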