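test_that("identical config and seed reproduce the cohort and maps bit for bit", {
  cfg <- tiny_cfg()
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$cohort, d2$cohort)
  expect_identical(d1$maps$standard$GM$values, d2$maps$standard$GM$values)
  expect_identical(d1$maps$rapid$CSF$values, d2$maps$rapid$CSF$values)
  expect_identical(d1$maps$retest$WM$values, d2$maps$retest$WM$values)
  expect_identical(d1$predictions, d2$predictions)
})

test_that("cohort ages respect the configured truncation interval and flags", {
  cfg <- tiny_cfg(n_participants = 50, n_retest = 7)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 50)
  expect_true(all(cohort$age >= cfg$age_min & cohort$age <= cfg$age_max))
  expect_equal(sum(cohort$has_retest), 7)
  expect_true(all(cohort$has_retest[1:7]))
  expect_false(anyDuplicated(cohort$participant_id) > 0)
})

test_that("study defaults describe the emulated cohort", {
  cfg <- rapid_config()
  expect_equal(cfg$n_participants, 64L)
  expect_equal(cfg$n_retest, 10L)
  expect_equal(c(cfg$age_mean, cfg$age_sd, cfg$age_min, cfg$age_max),
               c(28.2, 9.2, 18, 59))
  expect_equal(unname(cfg$cross_sequence_corr_target[c("GM", "WM", "CSF")]),
               c(0.84, 0.84, 0.56))
})

test_that("large-sample age mean matches the truncated-normal quadrature oracle", {
  cfg <- rapid_config(n_participants = 10000, n_retest = 0)
  cohort <- generate_cohort(cfg)
  target <- oracle_truncnorm_mean(cfg$age_mean, cfg$age_sd, cfg$age_min,
                                  cfg$age_max)
  expect_lt(abs(mean(cohort$age) - target), 0.3)
  # the closed-form moments the generator's variance algebra uses agree too
  cf <- rapidvol:::truncnorm_moments(cfg$age_mean, cfg$age_sd, cfg$age_min,
                                     cfg$age_max)
  expect_equal(cf$mean, target, tolerance = 1e-6)
})

test_that("invalid configurations are rejected", {
  expect_error(rapid_config(n_retest = 9, n_participants = 4), "n_retest")
  expect_error(rapid_config(cross_sequence_corr_target =
                              c(GM = 0, WM = 0.8, CSF = 0.5)), "\\(0, 1\\]")
  expect_error(rapid_config(cross_sequence_corr_target =
                              c(GM = 1.2, WM = 0.8, CSF = 0.5)), "\\(0, 1\\]")
  expect_error(rapid_config(grid_shape = c(8, 8, 8), fov_drop_slices = 4),
               "axial extent")
  # a perfect-correlation target leaves no room for acquisition noise
  expect_error(rapid_config(cross_sequence_corr_target =
                              c(GM = 1, WM = 1, CSF = 1)), "retest_noise_sd")
})

test_that("in the zero-noise limit both sequences carry identical global volumes", {
  cfg <- tiny_cfg(cross_sequence_corr_target = c(GM = 1, WM = 1, CSF = 1),
                  retest_noise_sd = 0, fov_drop_slices = 0L)
  d <- generate_tissue_maps(generate_cohort(cfg), cfg)
  for (tissue in c("GM", "WM", "CSF")) {
    expect_equal(global_volumes(d$standard[[tissue]])$volume,
                 global_volumes(d$rapid[[tissue]])$volume, tolerance = 1e-9)
  }
})

test_that("zero retest noise reproduces the first rapid acquisition exactly", {
  cfg <- tiny_cfg(retest_noise_sd = 0)
  cohort <- generate_cohort(cfg)
  maps <- generate_tissue_maps(cohort, cfg)
  retest <- generate_retest_maps(maps$rapid$GM, cohort, cfg)
  keep <- which(cohort$has_retest)
  expect_identical(retest$values, maps$rapid$GM$values[, , , keep, drop = FALSE])
  expect_identical(retest$participant_id, cohort$participant_id[keep])
})

test_that("retest maps share the first acquisition's FoV mask and differ only by noise", {
  cfg <- tiny_cfg()
  cohort <- generate_cohort(cfg)
  maps <- generate_tissue_maps(cohort, cfg)
  retest <- generate_retest_maps(maps$rapid$GM, cohort, cfg)
  expect_identical(retest$fov_mask, maps$rapid$GM$fov_mask)
  out_of_fov <- !retest$fov_mask
  expect_true(all(retest$values[rep(as.vector(out_of_fov), sum(cohort$has_retest))] == 0))
  expect_false(identical(retest$values,
                         maps$rapid$GM$values[, , , which(cohort$has_retest)]))
})

test_that("FoV mask drops exactly the outermost axial slices", {
  expect_true(all(make_fov_mask(tiny_cfg(fov_drop_slices = 0L))))
  cfg <- rapid_config(grid_shape = c(10L, 12L, 32L), fov_drop_slices = 4L)
  mask <- make_fov_mask(cfg)
  expect_equal(sum(apply(mask, 3, any)), 24)  # 32 - 2 * 4 valid slices
  # brute-force count: grid volume minus 2 * drop * slice area
  expect_equal(sum(mask), 10 * 12 * 32 - 2 * 4 * 10 * 12)
  expect_true(all(mask[, , 5:28]))
  expect_false(any(mask[, , c(1:4, 29:32)]))
})

test_that("mass-preserving smoothing leaves each participant's global volume unchanged", {
  set.seed(1)
  arr <- array(runif(8 * 8 * 8 * 4), dim = c(8, 8, 8, 4))
  sm <- rapidvol:::smooth_maps(arr, fwhm = 6, voxel_dims = c(2, 2, 2))
  expect_equal(colSums(matrix(sm, ncol = 4)), colSums(matrix(arr, ncol = 4)),
               tolerance = 1e-12)
  expect_false(identical(sm, arr))
})

test_that("identity prediction parameters give errorless predictions and the closed form holds", {
  cfg <- tiny_cfg(brainage_noise_sd = 0, brainage_offset_intercept = 0,
                  brainage_offset_slope = 1, fovred_offset_intercept = 0,
                  fovred_offset_slope = 1, fovred_noise_sd = 0)
  cohort <- generate_cohort(cfg)
  tab <- generate_age_predictions(cohort, cfg)
  expect_equal(tab$pred_standard, cohort$age)
  expect_equal(mae(tab$pred_rapid, tab$age), 0)

  # with zero noise the rapid-sequence error is the affine offset evaluated
  # on the drawn ages
  cfg2 <- tiny_cfg(brainage_noise_sd = 0)
  tab2 <- generate_age_predictions(generate_cohort(cfg2), cfg2)
  expect_equal(mae(tab2$pred_rapid, tab2$age),
               median(abs(cfg2$brainage_offset_intercept +
                            (cfg2$brainage_offset_slope - 1) * tab2$age)))
})
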