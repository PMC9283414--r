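#' Generate simulated brain-age prediction tables
#'
#' Emulates the output of a brain-age model applied to the three contrasts:
#' standard-sequence predictions track chronological age with noise
#' (`pred = age + N(0, brainage_noise_sd)`), rapid-sequence predictions carry
#' a systematic affine offset
#' (`pred = brainage_offset_intercept + brainage_offset_slope * age + noise`),
#' and reduced-FoV standard-sequence predictions use their own offset
#' parameters. Reproducible from `config$seed`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config The matching [rapid_config()].
#' @return A data frame of class `age_prediction_table` with columns
#'   `participant_id`, `age`, `pred_standard`, `pred_rapid`,
#'   `pred_standard_fovreduced` (all ages in years).
#' @export
generate_age_predictions <- function(cohort, config = rapid_config()) {
  validate_config(config)
  validate_cohort(cohort)
  set.seed(config$seed + 3L)
  n <- nrow(cohort)
  age <- cohort$age
  tab <- data.frame(
    participant_id = cohort$participant_id,
    age = age,
    pred_standard = age + stats::rnorm(n, 0, config$brainage_noise_sd),
    pred_rapid = config$brainage_offset_intercept +
      config$brainage_offset_slope * age +
      stats::rnorm(n, 0, config$brainage_noise_sd),
    pred_standard_fovreduced = config$fovred_offset_intercept +
      config$fovred_offset_slope * age +
      stats::rnorm(n, 0, config$fovred_noise_sd),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("age_prediction_table", "data.frame")
  tab
}

#' Scatter plots of predicted against chronological age
#'
#' One panel per sequence, with the identity line; the systematic offset of
#' the rapid sequence shows as a displacement from the diagonal.
#'
#' @param x An `age_prediction_table`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.age_prediction_table <- function(x, ...) {
  labels <- grep("^pred_", names(x), value = TRUE)
  old <- graphics::par(mfrow = c(1, length(labels)))
  on.exit(graphics::par(old))
  rng <- range(x$age, unlist(x[labels]))
  for (lab in labels) {
    graphics::plot(x$age, x[[lab]], xlim = rng, ylim = rng,
                   xlab = "chronological age (y)", ylab = "predicted age (y)",
                   main = sub("^pred_", "", lab), ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
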