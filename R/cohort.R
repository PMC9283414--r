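#' Generate a synthetic cohort
#'
#' Draws participant ages from a normal distribution truncated to
#' `[age_min, age_max]` (by rejection sampling) and flags the first
#' `n_retest` participants as having a retest acquisition. Fully reproducible
#' from `config$seed`.
#'
#' @param config A [rapid_config()] object.
#' @return A data frame of class `cohort` with columns `participant_id`
#'   (unique), `age` (years) and `has_retest` (logical).
#' @examples
#' cohort <- generate_cohort(rapid_config(n_participants = 6, n_retest = 2))
#' cohort
#' @export
generate_cohort <- function(config = rapid_config()) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  ages <- numeric(0)
  while (length(ages) < n) {
    draw <- stats::rnorm(n, config$age_mean, config$age_sd)
    draw <- draw[draw >= config$age_min & draw <= config$age_max]
    ages <- c(ages, draw)
  }
  ages <- ages[seq_len(n)]
  cohort <- data.frame(
    participant_id = sprintf("sub-%04d", seq_len(n)),
    age = ages,
    has_retest = seq_len(n) <= config$n_retest,
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort) ||
      !all(c("participant_id", "age", "has_retest") %in% names(cohort)))
    stop("cohort must have columns participant_id, age, has_retest", call. = FALSE)
  if (nrow(cohort) == 0L)
    stop("cohort is empty", call. = FALSE)
  if (anyDuplicated(cohort$participant_id))
    stop("participant_id values must be unique", call. = FALSE)
  if (any(!is.finite(cohort$age)))
    stop("ages must be finite", call. = FALSE)
  invisible(cohort)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%d with retest)\n",
              nrow(x), sum(x$has_retest)))
  cat(sprintf("  age: mean %.1f, sd %.1f, range [%.1f, %.1f] years\n",
              mean(x$age), stats::sd(x$age), min(x$age), max(x$age)))
  NextMethod()
}
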