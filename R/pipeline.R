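#' Run the full cross-sequence comparison pipeline
#'
#' Orchestrates the whole analysis on a synthetic (or externally supplied)
#' dataset: global-volume agreement between sequences per tissue, voxel-wise
#' correlation maps inside the coverage inclusion mask, the GM-age
#' association per contrast with paired bootstrap difference intervals, the
#' brain-age metrics table with the leave-one-out adjustment of the rapid
#' sequence, and test-retest reliability (global ICCs and voxel-wise ICC
#' summaries). All randomness derives from `config$seed` (the generator
#' stages use fixed per-stage offsets, the bootstrap `seed + 4`), so an
#' identical configuration yields an identical report.
#'
#' @param config A [rapid_config()].
#' @param data Optional pipeline inputs (from [generate_dataset()] or
#'   [load_external()]); generated from `config` when `NULL`.
#' @param n_boot Bootstrap replicates for the difference-in-correlation test.
#' @param correlation_method Voxel-wise correlation method
#'   (`"spearman"`/`"pearson"`).
#' @param icc_model Passed to [icc()]/[icc_map()].
#' @param reference_age Null-benchmark constant prediction, years.
#' @param inclusion_threshold,inclusion_fraction Passed to
#'   [inclusion_mask()].
#' @param conf_level Confidence level for bootstrap and ICC intervals.
#' @param out_dir Optional directory; when given, the report is written as
#'   JSON/TSV and the correlation/ICC maps as NIfTI.
#' @return An object of class `pipeline_report` (a list of result tables;
#'   see `print()`).
#' @export
run_pipeline <- function(config = rapid_config(), data = NULL,
                         n_boot = 10000L,
                         correlation_method = c("spearman", "pearson"),
                         icc_model = c("two-way", "one-way"),
                         reference_age = 40.6,
                         inclusion_threshold = 0.001,
                         inclusion_fraction = 0.95,
                         conf_level = 0.95,
                         out_dir = NULL) {
  correlation_method <- match.arg(correlation_method)
  icc_model <- match.arg(icc_model)
  validate_config(config)
  if (is.null(data)) data <- generate_dataset(config)
  cohort <- data$cohort
  tissues <- c("GM", "WM", "CSF")

  fov_mask <- data$fov_mask %||% make_fov_mask(config)
  standard_fovred <- lapply(data$maps$standard, reduce_fov, fov_mask = fov_mask)

  ## --- global volumes and cross-sequence agreement -----------------------
  globals <- list()
  for (tissue in tissues) {
    globals[[tissue]] <- data.frame(
      participant_id = cohort$participant_id,
      standard = global_volumes(data$maps$standard[[tissue]])$volume,
      rapid = global_volumes(data$maps$rapid[[tissue]])$volume,
      standard_fovreduced = global_volumes(standard_fovred[[tissue]])$volume,
      stringsAsFactors = FALSE)
  }
  contrast_pairs <- list(c("standard", "rapid"),
                         c("rapid", "standard_fovreduced"))
  global_associations <- do.call(rbind, lapply(tissues, function(tissue) {
    do.call(rbind, lapply(contrast_pairs, function(pair) {
      a <- assoc(globals[[tissue]][[pair[1L]]], globals[[tissue]][[pair[2L]]])
      data.frame(tissue = tissue, contrast_a = pair[1L], contrast_b = pair[2L],
                 rs = a$rs, p = a$p, r2 = a$r2, n = a$n,
                 stringsAsFactors = FALSE)
    }))
  }))

  ## --- voxel-wise agreement inside the coverage mask ---------------------
  masks <- lapply(tissues, function(tissue)
    inclusion_mask(data$maps$rapid[[tissue]], inclusion_threshold,
                   inclusion_fraction))
  names(masks) <- tissues
  voxelwise <- do.call(rbind, lapply(tissues, function(tissue) {
    cmap <- voxelwise_correlation(data$maps$standard[[tissue]],
                                  data$maps$rapid[[tissue]], masks[[tissue]],
                                  method = correlation_method)
    s <- summarize_distribution(cmap)
    data.frame(tissue = tissue, n_voxels = sum(!is.na(cmap)),
               median = s[["median"]], q1 = s[["q1"]], q3 = s[["q3"]],
               stringsAsFactors = FALSE)
  }))
  voxelwise_maps <- lapply(tissues, function(tissue)
    voxelwise_correlation(data$maps$standard[[tissue]],
                          data$maps$rapid[[tissue]], masks[[tissue]],
                          method = correlation_method))
  names(voxelwise_maps) <- tissues

  ## --- GM volume against age, with bootstrap contrast comparison ---------
  gm <- globals$GM
  gm_contrasts <- list(standard = gm$standard, rapid = gm$rapid,
                       standard_fovreduced = gm$standard_fovreduced)
  gm_age <- do.call(rbind, lapply(names(gm_contrasts), function(lab) {
    a <- assoc(cohort$age, gm_contrasts[[lab]])
    data.frame(contrast = lab, rs = a$rs, p = a$p, r2 = a$r2, n = a$n,
               stringsAsFactors = FALSE)
  }))
  gm_age_boot <- list(
    rs = bootstrap_corr_difference(cohort$age, gm_contrasts, "rs",
                                   n_boot = n_boot, seed = config$seed + 4L,
                                   conf_level = conf_level),
    r2 = bootstrap_corr_difference(cohort$age, gm_contrasts, "r2",
                                   n_boot = n_boot, seed = config$seed + 4L,
                                   conf_level = conf_level))

  ## --- brain-age evaluation ---------------------------------------------
  brainage <- brainage_table(data$predictions, reference_age = reference_age)
  loo <- loo_adjust(data$predictions$pred_rapid, data$predictions$pred_standard,
                    data$predictions$age)

  ## --- test-retest reliability ------------------------------------------
  reliability <- NULL
  reliability_maps <- NULL
  if (!is.null(data$maps$retest)) {
    retest_ids <- data$maps$retest$GM$participant_id
    keep <- match(retest_ids, cohort$participant_id)
    reliability <- do.call(rbind, lapply(tissues, function(tissue) {
      test_vol <- globals[[tissue]]$rapid[keep]
      retest_vol <- global_volumes(data$maps$retest[[tissue]])$volume
      r <- icc(cbind(test_vol, retest_vol), model = icc_model,
               conf_level = conf_level)
      data.frame(tissue = tissue, icc = r$icc, lower = r$ci95[1L],
                 upper = r$ci95[2L], p = r$p, n = r$n,
                 stringsAsFactors = FALSE)
    }))
    rapid_subset <- lapply(tissues, function(tissue) {
      m <- data$maps$rapid[[tissue]]
      tissue_map_set(m$values[, , , keep, drop = FALSE], m$tissue_class,
                     m$sequence_label, m$voxel_dims, m$participant_id[keep],
                     fov_mask = m$fov_mask)
    })
    names(rapid_subset) <- tissues
    reliability_maps <- lapply(tissues, function(tissue)
      icc_map(rapid_subset[[tissue]], data$maps$retest[[tissue]],
              masks[[tissue]], model = icc_model))
    names(reliability_maps) <- tissues
    reliability_voxelwise <- do.call(rbind, lapply(tissues, function(tissue) {
      s <- summarize_distribution(reliability_maps[[tissue]])
      data.frame(tissue = tissue,
                 n_voxels = sum(!is.na(reliability_maps[[tissue]])),
                 median = s[["median"]], q1 = s[["q1"]], q3 = s[["q3"]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    reliability_voxelwise <- NULL
  }

  report <- structure(list(
    global_volumes = globals,
    global_associations = global_associations,
    voxelwise = voxelwise,
    voxelwise_maps = voxelwise_maps,
    gm_age = gm_age,
    gm_age_bootstrap = gm_age_boot,
    brainage = brainage,
    loo = loo,
    reliability = reliability,
    reliability_voxelwise = reliability_voxelwise,
    reliability_maps = reliability_maps,
    provenance = list(
      seed = config$seed,
      n_participants = config$n_participants,
      n_retest = config$n_retest,
      n_boot = as.integer(n_boot),
      correlation_method = correlation_method,
      icc_model = icc_model,
      reference_age = reference_age,
      inclusion_threshold = inclusion_threshold,
      inclusion_fraction = inclusion_fraction,
      package_version = as.character(utils::packageVersion("rapidvol")))),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir, config)
  report
}

boot_pairs_df <- function(b) b$pairs

write_report <- function(report, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    global_associations = report$global_associations,
    voxelwise = report$voxelwise,
    gm_age = report$gm_age,
    gm_age_bootstrap = lapply(report$gm_age_bootstrap, boot_pairs_df),
    brainage = report$brainage,
    loo_adjusted_mae = report$loo$adjusted_mae,
    reliability = report$reliability,
    reliability_voxelwise = report$reliability_voxelwise,
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.table(report$brainage, file.path(out_dir, "brainage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$global_associations,
                     file.path(out_dir, "global_associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (tissue in names(report$voxelwise_maps))
    write_nifti_map(unclass(report$voxelwise_maps[[tissue]]),
                    config$voxel_dims,
                    file.path(out_dir, sprintf("correlation_%s.nii.gz", tissue)))
  for (tissue in names(report$reliability_maps %||% list()))
    write_nifti_map(unclass(report$reliability_maps[[tissue]]),
                    config$voxel_dims,
                    file.path(out_dir, sprintf("icc_%s.nii.gz", tissue)))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Cross-sequence comparison report\n")
  cat(sprintf("  %d participants, seed %d\n\n",
              x$provenance$n_participants, x$provenance$seed))
  cat("Global cross-sequence associations:\n")
  print(x$global_associations, row.names = FALSE, digits = 3)
  cat("\nVoxel-wise correlation summaries (Md [Q1, Q3]):\n")
  print(x$voxelwise, row.names = FALSE, digits = 3)
  cat("\nGM volume vs age:\n")
  print(x$gm_age, row.names = FALSE, digits = 3)
  cat("\nBrain-age metrics:\n")
  print(x$brainage, row.names = FALSE, digits = 3)
  cat(sprintf("\nLOO-adjusted rapid-sequence MAE: %.2f years\n",
              x$loo$adjusted_mae))
  if (!is.null(x$reliability)) {
    cat("\nTest-retest reliability (global ICC):\n")
    print(x$reliability, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Load externally supplied pipeline inputs
#'
#' Reads a directory in the layout of [write_dataset()] and validates it into
#' the structure [run_pipeline()] consumes. Components may also be supplied
#' directly (e.g. external maps combined with generated predictions); all
#' components are aligned on the intersection of participant ids, which must
#' be non-empty.
#'
#' @param dir Directory following the documented layout.
#' @param predictions Optional replacement `age_prediction_table`.
#' @param cohort Optional replacement cohort table.
#' @return A list (`cohort`, `maps`, `fov_mask`, `predictions`, `config`)
#'   interchangeable with [generate_dataset()] output.
#' @export
load_external <- function(dir, predictions = NULL, cohort = NULL) {
  data <- read_dataset(dir)
  if (!is.null(cohort)) {
    class(cohort) <- c("cohort", "data.frame")
    data$cohort <- validate_cohort(cohort)
  }
  if (!is.null(predictions)) data$predictions <- predictions
  if (is.null(data$maps$standard) || is.null(data$maps$rapid))
    stop("schema error: dataset must provide standard and rapid map sets",
         call. = FALSE)
  if (!is.null(data$predictions)) {
    ids <- intersect(data$cohort$participant_id,
                     data$predictions$participant_id)
    if (length(ids) == 0L)
      stop("schema error: no participant ids shared between cohort and ",
           "predictions", call. = FALSE)
    data$cohort <- data$cohort[match(ids, data$cohort$participant_id), ]
    data$predictions <-
      data$predictions[match(ids, data$predictions$participant_id), ]
    data$maps <- lapply(data$maps, function(seq_maps) {
      if (is.null(seq_maps)) return(NULL)
      lapply(seq_maps, function(m) {
        keep <- match(ids, m$participant_id)
        if (anyNA(keep)) return(m)  # retest sets cover a subset only
        tissue_map_set(m$values[, , , keep, drop = FALSE], m$tissue_class,
                       m$sequence_label, m$voxel_dims, m$participant_id[keep],
                       fov_mask = m$fov_mask)
      })
    })
  }
  data
}
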