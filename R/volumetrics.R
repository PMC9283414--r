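#' Global tissue volumes
#'
#' Sums voxel values (already in mm^3 per voxel) over the grid for each
#' participant.
#'
#' @param maps A [tissue_map_set()].
#' @return A data frame with columns `participant_id`, `tissue_class`,
#'   `sequence` and `volume` (mm^3), one row per participant.
#' @examples
#' m <- tissue_map_set(array(1, c(2, 2, 2, 3)), "GM", "demo", c(1, 1, 1),
#'                     paste0("p", 1:3))
#' global_volumes(m)$volume  # 8 mm^3 each
#' @export
global_volumes <- function(maps) {
  stopifnot(inherits(maps, "tissue_map_set"))
  n <- dim(maps$values)[4L]
  data.frame(
    participant_id = maps$participant_id,
    tissue_class = maps$tissue_class,
    sequence = maps$sequence_label,
    volume = colSums(matrix(maps$values, ncol = n)),
    stringsAsFactors = FALSE
  )
}

#' Voxel inclusion mask from participant coverage
#'
#' A voxel is included when at least `fraction` of participants have at least
#' `threshold` mm^3 of tissue there: the observed count of participants with
#' `value >= threshold` must reach `ceiling(fraction * n)`. This restricts
#' voxel-wise comparisons to voxels inside the rapid sequence's effective
#' field of view for (nearly) everyone.
#'
#' @param maps A [tissue_map_set()] with at least 2 participants.
#' @param threshold Minimum tissue volume, mm^3 (default 0.001).
#' @param fraction Required participant fraction in (0, 1] (default 0.95).
#' @return An object of class `inclusion_mask`: list with the 3-D logical
#'   `mask`, `threshold`, `fraction`, `required_count` and `n_participants`.
#' @export
inclusion_mask <- function(maps, threshold = 0.001, fraction = 0.95) {
  stopifnot(inherits(maps, "tissue_map_set"))
  n <- dim(maps$values)[4L]
  if (n < 2L)
    stop("inclusion mask needs at least 2 participants", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("parameter error: fraction must lie in (0, 1]", call. = FALSE)
  required <- ceiling(fraction * n)
  count <- rowSums(matrix(maps$values, ncol = n) >= threshold)
  structure(
    list(mask = array(count >= required, dim = dim(maps$values)[1:3]),
         threshold = threshold, fraction = fraction,
         required_count = required, n_participants = n),
    class = "inclusion_mask")
}

#' @export
print.inclusion_mask <- function(x, ...) {
  cat(sprintf(
    "Inclusion mask: %d of %d voxels (>= %g mm^3 in >= %d of %d participants)\n",
    sum(x$mask), length(x$mask), x$threshold, x$required_count,
    x$n_participants))
  invisible(x)
}

## Column-wise ranks (ties -> mean rank) of a matrix.
col_ranks <- function(m) apply(m, 2L, rank)

## Column-wise Pearson correlation of two conformable matrices; columns with
## zero variance in either argument yield NA.
col_correlation <- function(a, b) {
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2) * colSums(b^2))
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Voxel-wise cross-participant correlation map
#'
#' For every voxel inside the inclusion mask, correlates the two sequences'
#' values across participants. Voxels with zero variance in either sequence
#' yield `NA` (an undefined, not a zero, correlation).
#'
#' @param maps_a,maps_b Two [tissue_map_set()]s on the same grid with the
#'   same participants in the same order.
#' @param mask An [inclusion_mask()].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A 3-D array of class `correlation_map`: correlation values inside
#'   the mask, `NA` outside.
#' @export
voxelwise_correlation <- function(maps_a, maps_b, mask,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(maps_a, "tissue_map_set"), inherits(maps_b, "tissue_map_set"),
            inherits(mask, "inclusion_mask"))
  if (!identical(dim(maps_a$values), dim(maps_b$values)))
    stop("alignment error: map grids/participant counts differ", call. = FALSE)
  if (!identical(maps_a$participant_id, maps_b$participant_id))
    stop("alignment error: participants differ between map sets", call. = FALSE)
  if (!identical(dim(mask$mask), dim(maps_a$values)[1:3]))
    stop("alignment error: mask shape does not match maps", call. = FALSE)
  n <- dim(maps_a$values)[4L]
  sel <- which(as.vector(mask$mask))
  a <- t(matrix(maps_a$values, ncol = n)[sel, , drop = FALSE])
  b <- t(matrix(maps_b$values, ncol = n)[sel, , drop = FALSE])
  if (method == "spearman") {
    a <- col_ranks(a)
    b <- col_ranks(b)
  }
  vals <- col_correlation(a, b)
  out <- array(NA_real_, dim = dim(mask$mask))
  out[sel] <- vals
  structure(out, class = "correlation_map", method = method)
}

#' @export
print.correlation_map <- function(x, ...) {
  v <- x[!is.na(x)]
  cat(sprintf("Correlation map (%s): %d voxels", attr(x, "method") %||% "?",
              length(v)))
  if (length(v)) {
    s <- summarize_distribution(v)
    cat(sprintf("; Md [Q1, Q3] = %.2f [%.2f, %.2f]", s[["median"]],
                s[["q1"]], s[["q3"]]))
  }
  cat("\n")
  invisible(x)
}

#' Apply a field-of-view mask to a map set
#'
#' Sets voxel values outside `fov_mask` to zero and records the mask on the
#' result (intersected with any existing mask). Idempotent; per participant,
#' the reduced global volume never exceeds the original.
#'
#' @param maps A [tissue_map_set()].
#' @param fov_mask 3-D logical array matching the map grid; must select at
#'   least one voxel.
#' @return A [tissue_map_set()] with the reduced field of view.
#' @export
reduce_fov <- function(maps, fov_mask) {
  stopifnot(inherits(maps, "tissue_map_set"))
  if (!identical(dim(fov_mask), dim(maps$values)[1:3]))
    stop("parameter error: fov_mask shape does not match maps", call. = FALSE)
  if (!any(fov_mask))
    stop("parameter error: fov_mask is empty", call. = FALSE)
  combined <- if (is.null(maps$fov_mask)) fov_mask else maps$fov_mask & fov_mask
  tissue_map_set(maps$values * as.vector(combined), maps$tissue_class,
                 paste0(maps$sequence_label, "-fovreduced"), maps$voxel_dims,
                 maps$participant_id, fov_mask = combined)
}

#' Median and quartiles of a distribution
#'
#' Median, first and third quartile by linear interpolation between order
#' statistics (the convention shared by every distribution summary in this
#' package). Missing values are dropped.
#'
#' @param values Numeric vector or `correlation_map`.
#' @return Named numeric vector `median`, `q1`, `q3`.
#' @export
summarize_distribution <- function(values) {
  values <- as.vector(values)
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop("data error: no finite values to summarise", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}
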