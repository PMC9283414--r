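#' Container for per-participant voxel-wise tissue-volume maps
#'
#' A `tissue_map_set` holds one 3-D map per participant for a single tissue
#' class and acquisition sequence. Values are tissue volume in mm^3 per voxel
#' (non-negative), stored as a 4-D array with the participant axis last.
#'
#' @param values 4-D numeric array, `grid_shape x n_participants`, all values
#'   finite and >= 0.
#' @param tissue_class One of `"GM"`, `"WM"`, `"CSF"`.
#' @param sequence_label Character label of the acquisition sequence.
#' @param voxel_dims Voxel edge lengths in mm (metadata; values are already
#'   volumes).
#' @param participant_id Character vector, one id per participant.
#' @param fov_mask Optional 3-D logical array marking valid voxels.
#' @return An object of class `tissue_map_set`.
#' @export
tissue_map_set <- function(values, tissue_class, sequence_label, voxel_dims,
                           participant_id, fov_mask = NULL) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("values must be a 4-D array (x, y, z, participant)", call. = FALSE)
  tissue_class <- match.arg(tissue_class, c("GM", "WM", "CSF"))
  if (length(participant_id) != dim(values)[4L])
    stop("participant_id length must match the participant axis", call. = FALSE)
  if (!is.null(fov_mask)) {
    if (!identical(dim(fov_mask), dim(values)[1:3]))
      stop("fov_mask shape must match the map grid", call. = FALSE)
    storage.mode(fov_mask) <- "logical"
  }
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "data error: invalid voxel value for participant %s at voxel [%d, %d, %d]",
      participant_id[idx[4L]], idx[1L], idx[2L], idx[3L]), call. = FALSE)
  }
  structure(
    list(values = values, tissue_class = tissue_class,
         sequence_label = sequence_label, voxel_dims = as.numeric(voxel_dims),
         participant_id = as.character(participant_id), fov_mask = fov_mask),
    class = "tissue_map_set")
}

#' @export
print.tissue_map_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Tissue map set: %s, sequence '%s'\n", x$tissue_class, x$sequence_label))
  cat(sprintf("  %d participants on a %dx%dx%d grid (%s mm voxels)\n",
              d[4L], d[1L], d[2L], d[3L], paste(x$voxel_dims, collapse = "x")))
  if (!is.null(x$fov_mask))
    cat(sprintf("  FoV mask: %d of %d voxels valid\n",
                sum(x$fov_mask), prod(d[1:3])))
  tot <- colSums(matrix(x$values, ncol = d[4L]))
  cat(sprintf("  global volume: median %.0f mm^3 [%.0f, %.0f]\n",
              stats::median(tot), min(tot), max(tot)))
  invisible(x)
}

#' Plot a mid-axial slice of one participant's map
#'
#' @param x A `tissue_map_set`.
#' @param participant Index of the participant to display.
#' @param slice Axial slice index (defaults to the middle slice).
#' @param ... Passed to [graphics::image()].
#' @export
plot.tissue_map_set <- function(x, participant = 1L,
                                slice = ceiling(dim(x$values)[3L] / 2), ...) {
  graphics::image(x$values[, , slice, participant],
                  main = sprintf("%s %s: %s, slice %d", x$sequence_label,
                                 x$tissue_class, x$participant_id[participant],
                                 slice),
                  xlab = "x", ylab = "y", ...)
  invisible(x)
}

## Noise-free tissue templates: concentric radial profiles on the voxel grid,
## each scaled to the configured total volume. The templates' effective
## support (n_eff = (sum t)^2 / sum t^2) sets how strongly independent
## per-voxel noise is amplified relative to the between-participant signal,
## so the concentration of each profile is part of the statistical design,
## not just cosmetics (see tissue_variance_components).
tissue_templates <- function(config) {
  gs <- config$grid_shape
  vd <- config$voxel_dims
  centre <- (gs + 1) / 2
  ax <- (seq_len(gs[1L]) - centre[1L]) * vd[1L]
  ay <- (seq_len(gs[2L]) - centre[2L]) * vd[2L]
  az <- (seq_len(gs[3L]) - centre[3L]) * vd[3L]
  extent <- gs * vd
  radius <- function(semi_frac) {
    semi <- semi_frac * extent
    sqrt(outer(outer((ax / semi[1L])^2, (ay / semi[2L])^2, `+`),
               (az / semi[3L])^2, `+`))
  }
  # GM is a cortical shell elongated axially so that it, alone, reaches the
  # slices removed by the FoV truncation (mirroring truncated cortex); WM a
  # compact central blob; CSF mostly a ventricle blob plus a thin outer shell
  # that stays inside the truncated FoV.
  r_gm <- radius(c(0.44, 0.44, 0.60))
  r_wm <- radius(c(0.44, 0.44, 0.40))
  r_csf <- radius(c(0.44, 0.44, 0.42))
  ventricle <- exp(-(r_csf / 0.16)^2)
  outer_csf <- exp(-((r_csf - 0.80) / 0.05)^2)
  profiles <- list(
    GM = exp(-((r_gm - 0.72) / 0.08)^2),
    WM = exp(-(r_wm / 0.34)^2),
    # 60% of CSF mass in the compact ventricle blob, 40% in the outer sheet
    CSF = 0.60 * ventricle / sum(ventricle) + 0.40 * outer_csf / sum(outer_csf)
  )
  lapply(c(GM = "GM", WM = "WM", CSF = "CSF"), function(tissue) {
    t <- profiles[[tissue]]
    t * (config$template_volumes[[tissue]] / sum(t))
  })
}

#' Build the rapid sequence's field-of-view mask
#'
#' The reduced FoV of the rapid acquisition is emulated as symmetric axial
#' truncation: the top and bottom `fov_drop_slices` axial slices are marked
#' invalid.
#'
#' @param config A [rapid_config()].
#' @return A 3-D logical array, `TRUE` where the voxel is inside the FoV.
#' @examples
#' mask <- make_fov_mask(rapid_config(grid_shape = c(8, 8, 8), fov_drop_slices = 1))
#' sum(mask) # 8 * 8 * 6 valid voxels
#' @export
make_fov_mask <- function(config) {
  validate_config(config)
  gs <- config$grid_shape
  d <- config$fov_drop_slices
  mask <- array(TRUE, dim = gs)
  if (d > 0L) {
    mask[, , c(seq_len(d), gs[3L] - seq_len(d) + 1L)] <- FALSE
  }
  if (!any(mask))
    stop("configuration error: FoV mask is empty", call. = FALSE)
  mask
}

## Mass-preserving separable Gaussian smoothing of a 4-D map array.
## Each source voxel redistributes its tissue volume with weights summing to
## one (kernel columns renormalised at the boundary), so every participant's
## global volume is exactly preserved. sigma = fwhm / 2.355 per axis,
## truncated at 4 sigma.
smooth_maps <- function(values, fwhm, voxel_dims) {
  if (fwhm <= 0) return(values)
  d <- dim(values)
  for (axis in 1:3) {
    sigma <- fwhm / 2.355 / voxel_dims[axis]
    half <- max(1L, floor(4 * sigma))  # sub-voxel kernels still reach neighbours
    offsets <- -half:half
    w <- stats::dnorm(offsets, sd = sigma)
    n <- d[axis]
    k <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + offsets
      ok <- j >= 1L & j <= n
      k[j[ok], i] <- w[ok] / sum(w[ok])  # column sums to 1: mass preserved
    }
    perm <- c(axis, setdiff(1:4, axis))
    values <- aperm(values, perm)
    dp <- dim(values)
    values <- array(k %*% matrix(values, nrow = n), dim = dp)
    values <- aperm(values, order(perm))
  }
  values
}

#' Generate paired tissue-volume maps for both sequences
#'
#' For each tissue class, every participant's latent map is the tissue
#' template scaled by a participant random effect (and, for GM, a linear age
#' effect of `gm_age_slope` mm^3/year distributed over GM voxels). The
#' standard-sequence map adds measurement error; the rapid-sequence map adds
#' a larger error split into a stable within-session component and
#' per-acquisition noise, is smoothed with a mass-preserving Gaussian kernel
#' at `smoothing_fwhm`, and has voxels outside the FoV mask set to zero.
#'
#' Error variances are solved from `cross_sequence_corr_target` at the
#' global-volume level (see [tissue_variance_components()]). Each error
#' source is realised as a participant-level multiplicative term (a global
#' scaling error, proportional to the template) carrying a
#' `1 - voxel_noise_share` fraction of its variance, plus independent
#' per-voxel noise with SD proportional to the template value carrying the
#' remaining `voxel_noise_share`. The split leaves all global-volume variance
#' algebra exact while setting the *voxel-level* signal-to-noise ratio, so a
#' small share reproduces the empirical pattern of voxel-wise cross-sequence
#' correlations somewhat below the global one, ordered by the tissues'
#' template concentration. All voxel values are clamped at zero (inactive in
#' practice at the default noise levels).
#'
#' Expected voxel-level correlations are available from
#' [tissue_variance_components()].
#'
#' @param cohort A [generate_cohort()] result (non-empty).
#' @param config The same [rapid_config()] used for the cohort.
#' @return A list with elements `standard` and `rapid`, each a named list of
#'   [tissue_map_set()] objects for GM, WM and CSF, plus `fov_mask`.
#' @export
generate_tissue_maps <- function(cohort, config = rapid_config()) {
  validate_config(config)
  validate_cohort(cohort)
  n <- nrow(cohort)
  templates <- tissue_templates(config)
  fov_mask <- make_fov_mask(config)
  gs <- config$grid_shape
  set.seed(config$seed + 1L)
  out <- list(standard = list(), rapid = list(), fov_mask = fov_mask)
  share <- config$voxel_noise_share
  for (tissue in c("GM", "WM", "CSF")) {
    tpl <- as.vector(templates[[tissue]])
    v_total <- sum(tpl)
    s2 <- sum(tpl^2)
    nv <- length(tpl)
    vc <- tissue_variance_components(config, tissue)
    subject_effect <- stats::rnorm(n, 0, config$subject_cv * v_total)
    if (tissue == "GM")
      subject_effect <- subject_effect +
        config$gm_age_slope * (cohort$age - config$age_mean)
    latent <- outer(tpl, 1 + subject_effect / v_total)

    # one error draw = participant-level multiplicative term plus independent
    # per-voxel noise, together carrying the requested global variance
    draw_error <- function(variance, n_draw) {
      mult <- stats::rnorm(n_draw, 0, sqrt((1 - share) * variance))
      outer(tpl / v_total, mult) +
        stats::rnorm(nv * n_draw, 0, sqrt(share * variance / s2) * tpl)
    }

    standard <- pmax(latent + draw_error(vc$var_noise_standard, n), 0)
    stable <- latent + draw_error(vc$var_stable, n)
    rapid <- pmax(stable + draw_error(vc$var_acquisition, n), 0)

    standard <- array(standard, dim = c(gs, n))
    rapid <- array(rapid, dim = c(gs, n))
    rapid <- smooth_maps(rapid, config$smoothing_fwhm, config$voxel_dims)
    rapid <- rapid * as.vector(fov_mask)

    out$standard[[tissue]] <- tissue_map_set(
      standard, tissue, "standard", config$voxel_dims, cohort$participant_id)
    rapid_set <- tissue_map_set(
      rapid, tissue, "rapid", config$voxel_dims, cohort$participant_id,
      fov_mask = fov_mask)
    # stable component retained so a retest acquisition can redraw only the
    # per-acquisition noise
    attr(rapid_set, "generator") <- list(
      stable = array(stable, dim = c(gs, n)),
      template = tpl,
      var_acquisition = vc$var_acquisition,
      voxel_noise_share = share,
      tissue_index = match(tissue, c("GM", "WM", "CSF")),
      seed = config$seed)
    out$rapid[[tissue]] <- rapid_set
  }
  out
}

#' Generate within-session retest maps for the rapid sequence
#'
#' Produces a second rapid acquisition for the participants flagged
#' `has_retest`: the same stable map (latent plus the participant's stable
#' sequence-specific deviation) with fresh per-acquisition noise at
#' `retest_noise_sd` (global-volume scale), the same smoothing and the same
#' FoV mask as the first acquisition.
#'
#' @param rapid_maps A rapid-sequence [tissue_map_set()] produced by
#'   [generate_tissue_maps()].
#' @param cohort The cohort the maps were generated for.
#' @param config The same [rapid_config()].
#' @return A [tissue_map_set()] for the retest participants only.
#' @export
generate_retest_maps <- function(rapid_maps, cohort, config = rapid_config()) {
  stopifnot(inherits(rapid_maps, "tissue_map_set"))
  validate_cohort(cohort)
  gen <- attr(rapid_maps, "generator")
  if (is.null(gen))
    stop("rapid_maps must come from generate_tissue_maps() ",
         "(missing generator state)", call. = FALSE)
  keep <- which(cohort$has_retest)
  if (length(keep) == 0L)
    stop("no retest participants in this cohort", call. = FALSE)
  set.seed(gen$seed + 100L + gen$tissue_index)
  gs <- dim(rapid_maps$values)[1:3]
  stable <- gen$stable[, , , keep, drop = FALSE]
  nv <- prod(gs)
  n_keep <- length(keep)
  tpl <- gen$template
  share <- gen$voxel_noise_share
  mult <- stats::rnorm(n_keep, 0, sqrt((1 - share) * gen$var_acquisition))
  noise <- outer(tpl / sum(tpl), mult) +
    stats::rnorm(nv * n_keep, 0,
                 sqrt(share * gen$var_acquisition / sum(tpl^2)) * tpl)
  retest <- pmax(stable + array(noise, dim = dim(stable)), 0)
  retest <- smooth_maps(retest, config$smoothing_fwhm, config$voxel_dims)
  retest <- retest * as.vector(rapid_maps$fov_mask %||% array(TRUE, gs))
  tissue_map_set(retest, rapid_maps$tissue_class, "rapid-retest",
                 rapid_maps$voxel_dims, rapid_maps$participant_id[keep],
                 fov_mask = rapid_maps$fov_mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
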