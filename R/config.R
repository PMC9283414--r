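#' Generator configuration for a synthetic paired-sequence cohort
#'
#' Bundles every tunable of the synthetic cohort generator: cohort size and
#' age distribution, the voxel grid, per-tissue cross-sequence correlation
#' targets, retest noise, field-of-view (FoV) truncation, and the parameters
#' of the simulated brain-age predictions.
#'
#' The defaults emulate the study conditions the package is designed around:
#' 64 participants (10 with a within-session retest scan) aged 18--59 with
#' mean 28.2 y and SD 9.2 y; cross-sequence global-volume correlations of
#' 0.84 (GM), 0.84 (WM) and 0.56 (CSF); a linear decline of total grey-matter
#' volume with age; near-unity within-sequence retest reliability; and a
#' rapid-sequence brain-age prediction with a systematic offset.
#'
#' @param n_participants Number of participants.
#' @param n_retest Number of participants (the first `n_retest`) with a
#'   second, within-session rapid acquisition.
#' @param grid_shape Integer vector of length 3: voxels per axis (x, y, z);
#'   the third axis is axial and is the one truncated by the FoV mask.
#' @param voxel_dims Voxel edge lengths in mm per axis.
#' @param age_mean,age_sd,age_min,age_max Parameters of the truncated-normal
#'   age distribution, in years.
#' @param gm_age_slope Change in total grey-matter volume per year of age, in
#'   mm^3/year (negative: GM declines with age).
#' @param cross_sequence_corr_target Named numeric (GM, WM, CSF) in (0, 1]:
#'   target expected cross-participant correlation of global tissue volume
#'   between the standard and rapid sequences.
#' @param subject_cv Between-participant SD of global tissue volume as a
#'   fraction of the template volume (coefficient of variation).
#' @param rapid_noise_ratio Ratio of total rapid-sequence to standard-sequence
#'   measurement-noise variance at the global-volume level (> 0; the rapid
#'   sequence is the noisier one for ratios > 1).
#' @param retest_noise_sd Per-acquisition noise SD of the rapid sequence at
#'   the global-volume level, in mm^3. This is the only component redrawn for
#'   a retest scan; the remainder of the rapid sequence's deviation from the
#'   standard sequence is stable within a session, which is what lets retest
#'   reliability approach 1 while the cross-sequence correlation stays at its
#'   target.
#' @param voxel_noise_share Fraction in `[0, 1]` of each measurement-error
#'   variance realised as independent per-voxel noise; the remainder is a
#'   participant-level multiplicative (global scaling) error. The global
#'   variance algebra is unaffected by the split, but the voxel-level
#'   signal-to-noise ratio -- and hence the voxel-wise cross-sequence
#'   correlations and reliability -- falls as the share rises. The small
#'   default keeps voxel-wise correlations somewhat below the global targets,
#'   ordered GM/WM above CSF, as observed empirically.
#' @param fov_drop_slices Number of axial slices removed at each extreme of
#'   the rapid sequence's FoV.
#' @param brainage_noise_sd SD (years) of the noise on simulated brain-age
#'   predictions from the standard sequence.
#' @param brainage_offset_intercept,brainage_offset_slope Affine distortion of
#'   the rapid sequence's brain-age predictions:
#'   `pred = intercept + slope * age + noise`. The defaults give a large
#'   systematic offset (median absolute error on the order of 14 y) while the
#'   rank correlation with age stays high.
#' @param fovred_offset_intercept,fovred_offset_slope,fovred_noise_sd Same,
#'   for predictions from the standard sequence with artificially reduced FoV.
#' @param smoothing_fwhm Full width at half maximum, in mm, of the
#'   mass-preserving Gaussian kernel applied to rapid-sequence maps (0 for
#'   none).
#' @param template_volumes Named numeric (GM, WM, CSF): total tissue volume of
#'   the noise-free template, mm^3.
#' @param seed Integer seed from which all generator randomness is derived.
#'
#' @return An object of class `rapid_config` (a validated list).
#' @examples
#' cfg <- rapid_config(n_participants = 8, n_retest = 2)
#' cfg$grid_shape
#' @export
rapid_config <- function(n_participants = 64,
                         n_retest = 10,
                         grid_shape = c(24L, 24L, 16L),
                         voxel_dims = c(4, 4, 6),
                         age_mean = 28.2,
                         age_sd = 9.2,
                         age_min = 18,
                         age_max = 59,
                         gm_age_slope = -350,
                         cross_sequence_corr_target = c(GM = 0.84, WM = 0.84, CSF = 0.56),
                         subject_cv = 0.025,
                         rapid_noise_ratio = 2,
                         retest_noise_sd = 750,
                         voxel_noise_share = 0.001,
                         fov_drop_slices = 2L,
                         brainage_noise_sd = 5.5,
                         brainage_offset_intercept = 26,
                         brainage_offset_slope = 0.6,
                         fovred_offset_intercept = 31,
                         fovred_offset_slope = 0.35,
                         fovred_noise_sd = 7,
                         smoothing_fwhm = 4,
                         template_volumes = c(GM = 250000, WM = 200000, CSF = 120000),
                         seed = 1L) {
  config <- list(
    n_participants = as.integer(n_participants),
    n_retest = as.integer(n_retest),
    grid_shape = as.integer(grid_shape),
    voxel_dims = as.numeric(voxel_dims),
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    gm_age_slope = gm_age_slope,
    cross_sequence_corr_target = cross_sequence_corr_target,
    subject_cv = subject_cv,
    rapid_noise_ratio = rapid_noise_ratio,
    retest_noise_sd = retest_noise_sd,
    voxel_noise_share = voxel_noise_share,
    fov_drop_slices = as.integer(fov_drop_slices),
    brainage_noise_sd = brainage_noise_sd,
    brainage_offset_intercept = brainage_offset_intercept,
    brainage_offset_slope = brainage_offset_slope,
    fovred_offset_intercept = fovred_offset_intercept,
    fovred_offset_slope = fovred_offset_slope,
    fovred_noise_sd = fovred_noise_sd,
    smoothing_fwhm = smoothing_fwhm,
    template_volumes = template_volumes,
    seed = as.integer(seed)
  )
  class(config) <- "rapid_config"
  validate_config(config)
  config
}

#' Validate a generator configuration
#'
#' @param config A `rapid_config` object.
#' @return `config`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "rapid_config"))
  if (config$n_participants < 1L)
    stop("n_participants must be positive", call. = FALSE)
  if (config$n_retest < 0L)
    stop("n_retest must be non-negative", call. = FALSE)
  if (config$n_retest > config$n_participants)
    stop("configuration error: n_retest (", config$n_retest,
         ") exceeds n_participants (", config$n_participants, ")", call. = FALSE)
  if (length(config$grid_shape) != 3L || any(config$grid_shape < 1L))
    stop("grid_shape must be 3 positive integers", call. = FALSE)
  if (length(config$voxel_dims) != 3L || any(config$voxel_dims <= 0))
    stop("voxel_dims must be 3 positive lengths (mm)", call. = FALSE)
  if (config$age_sd <= 0 || config$age_min >= config$age_max)
    stop("age distribution parameters invalid", call. = FALSE)
  rho <- config$cross_sequence_corr_target
  if (!all(c("GM", "WM", "CSF") %in% names(rho)))
    stop("cross_sequence_corr_target must name GM, WM and CSF", call. = FALSE)
  if (any(rho <= 0) || any(rho > 1))
    stop("configuration error: cross_sequence_corr_target must lie in (0, 1]",
         call. = FALSE)
  if (config$subject_cv <= 0)
    stop("subject_cv must be positive", call. = FALSE)
  if (config$rapid_noise_ratio <= 0)
    stop("rapid_noise_ratio must be positive", call. = FALSE)
  if (config$retest_noise_sd < 0 || config$brainage_noise_sd < 0 ||
      config$fovred_noise_sd < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  if (config$voxel_noise_share < 0 || config$voxel_noise_share > 1)
    stop("voxel_noise_share must lie in [0, 1]", call. = FALSE)
  if (config$fov_drop_slices < 0L)
    stop("fov_drop_slices must be non-negative", call. = FALSE)
  if (2L * config$fov_drop_slices >= config$grid_shape[3L])
    stop("configuration error: 2 * fov_drop_slices (", 2L * config$fov_drop_slices,
         ") must be smaller than the axial extent (", config$grid_shape[3L], ")",
         call. = FALSE)
  if (config$smoothing_fwhm < 0)
    stop("smoothing_fwhm must be non-negative", call. = FALSE)
  if (!all(c("GM", "WM", "CSF") %in% names(config$template_volumes)) ||
      any(config$template_volumes <= 0))
    stop("template_volumes must be positive and name GM, WM and CSF", call. = FALSE)
  # the per-acquisition retest noise cannot exceed the total rapid-sequence
  # noise implied by the correlation target
  for (tissue in c("GM", "WM", "CSF")) {
    vc <- tissue_variance_components(config, tissue)
    if (config$retest_noise_sd^2 > vc$var_noise_rapid + 1e-9)
      stop("configuration error: retest_noise_sd^2 exceeds the rapid-sequence ",
           "noise variance implied by the ", tissue,
           " correlation target; lower retest_noise_sd or the target",
           call. = FALSE)
  }
  invisible(config)
}

#' @export
print.rapid_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat(sprintf("  participants: %d (%d with retest)\n", x$n_participants, x$n_retest))
  cat(sprintf("  ages: truncated normal(%.1f, %.1f) on [%g, %g] years\n",
              x$age_mean, x$age_sd, x$age_min, x$age_max))
  cat(sprintf("  grid: %s voxels at %s mm\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_dims, collapse = "x")))
  cat(sprintf("  correlation targets: GM %.2f, WM %.2f, CSF %.2f\n",
              x$cross_sequence_corr_target[["GM"]],
              x$cross_sequence_corr_target[["WM"]],
              x$cross_sequence_corr_target[["CSF"]]))
  cat(sprintf("  FoV truncation: %d axial slice(s) at each extreme\n",
              x$fov_drop_slices))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

## Moments of a normal(mean, sd) truncated to [lo, hi]; closed form.
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / z
  v <- sd^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, var = v)
}

#' Variance components implied by a generator configuration
#'
#' Solves the measurement-noise variances of the two sequences from the
#' cross-sequence correlation target, at the global-volume level. Writing
#' `vl` for the between-participant (latent) variance of global volume,
#' `a * vl` for the standard-sequence noise variance and `k * a * vl` for the
#' rapid-sequence noise variance (with `k = rapid_noise_ratio`), the expected
#' cross-participant correlation of global volumes is
#' `rho = 1 / sqrt((1 + a) (1 + k a))`, and `a` is the positive root of
#' `k a^2 + (k + 1) a + 1 - rho^-2 = 0`. The rapid-sequence noise further
#' splits into a stable (within-session) component and a per-acquisition
#' component of variance `retest_noise_sd^2`; the expected retest consistency
#' ICC is `(vl + var_stable) / (vl + var_stable + retest_noise_sd^2)`.
#'
#' For grey matter, `vl` includes the age-driven variance
#' `gm_age_slope^2 * var(age)` with the truncated-normal age variance in
#' closed form.
#'
#' At the voxel level, each error variance is amplified relative to the
#' between-participant signal by `mu = (1 - s) + s * n_eff`, where
#' `s = voxel_noise_share` and `n_eff = (sum t)^2 / sum t^2` is the
#' template's effective support in voxels: the multiplicative error component
#' tracks the template exactly while the independent component concentrates
#' its variance per voxel. The expected voxel-level cross-sequence
#' correlation and retest consistency are therefore
#' `vl / sqrt((vl + mu vn_std)(vl + mu vn_rapid))` and
#' `(vl + mu vb) / (vl + mu vb + mu ve)`.
#'
#' @param config A `rapid_config`.
#' @param tissue One of `"GM"`, `"WM"`, `"CSF"`.
#' @return A list with elements `var_latent`, `var_noise_standard`,
#'   `var_noise_rapid`, `var_stable`, `var_acquisition`,
#'   `expected_correlation`, `expected_retest_icc` (all at the global-volume
#'   level, mm^6 for variances), plus the voxel-level expectations
#'   `expected_voxel_correlation` and `expected_voxel_icc`.
#' @export
tissue_variance_components <- function(config, tissue = c("GM", "WM", "CSF")) {
  tissue <- match.arg(tissue)
  v_total <- config$template_volumes[[tissue]]
  var_latent <- (config$subject_cv * v_total)^2
  if (tissue == "GM") {
    age_var <- truncnorm_moments(config$age_mean, config$age_sd,
                                 config$age_min, config$age_max)$var
    var_latent <- var_latent + config$gm_age_slope^2 * age_var
  }
  rho <- config$cross_sequence_corr_target[[tissue]]
  k <- config$rapid_noise_ratio
  if (rho == 1) {
    a <- 0
  } else {
    a <- (-(k + 1) + sqrt((k + 1)^2 - 4 * k * (1 - rho^-2))) / (2 * k)
  }
  var_noise_standard <- a * var_latent
  var_noise_rapid <- k * a * var_latent
  var_acq <- min(config$retest_noise_sd^2, var_noise_rapid)
  var_stable <- var_noise_rapid - var_acq

  tpl <- tissue_templates(config)[[tissue]]
  n_eff <- sum(tpl)^2 / sum(tpl^2)
  s <- config$voxel_noise_share
  mu <- (1 - s) + s * n_eff
  list(
    var_latent = var_latent,
    var_noise_standard = var_noise_standard,
    var_noise_rapid = var_noise_rapid,
    var_stable = var_stable,
    var_acquisition = var_acq,
    expected_correlation = 1 / sqrt((1 + a) * (1 + k * a)),
    expected_retest_icc = (var_latent + var_stable) /
      (var_latent + var_stable + var_acq),
    expected_voxel_correlation = var_latent /
      sqrt((var_latent + mu * var_noise_standard) *
             (var_latent + mu * var_noise_rapid)),
    expected_voxel_icc = (var_latent + mu * var_stable) /
      (var_latent + mu * var_stable + mu * var_acq)
  )
}
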