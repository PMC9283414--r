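#' Write a generated dataset to disk
#'
#' Stores tissue maps as NIfTI-1 (`.nii.gz`, voxel dimensions in the header),
#' the cohort as `participants.tsv`, predictions as `predictions.tsv`, the
#' FoV mask as `fov_mask.nii.gz` and the generator configuration as
#' `config.yaml`.
#'
#' Layout under `dir`:
#' \preformatted{
#'   participants.tsv          participant_id, age, has_retest
#'   predictions.tsv           participant_id, age, pred_<sequence>...
#'   config.yaml               generator configuration (if supplied)
#'   fov_mask.nii.gz           rapid-sequence FoV (if present)
#'   maps/<sequence>_<tissue>.nii.gz   4-D, participant axis last
#' }
#'
#' @param dataset A list with elements `cohort`, and optionally `predictions`,
#'   `maps` (a list `standard`/`rapid`/`retest` of per-tissue
#'   [tissue_map_set()]s), `fov_mask` and `config`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [read_dataset()], [generate_dataset()]
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  validate_cohort(dataset$cohort)
  utils::write.table(dataset$cohort, file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$predictions))
    utils::write.table(dataset$predictions, file.path(dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$config)) {
    cfg <- unclass(dataset$config)
    # yaml drops the names of named atomic vectors; store those as maps
    for (field in c("cross_sequence_corr_target", "template_volumes"))
      cfg[[field]] <- as.list(cfg[[field]])
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  if (!is.null(dataset$fov_mask))
    write_nifti_map(dataset$fov_mask + 0, dataset$config$voxel_dims %||% c(1, 1, 1),
                    file.path(dir, "fov_mask.nii.gz"))
  if (!is.null(dataset$maps)) {
    dir.create(file.path(dir, "maps"), showWarnings = FALSE)
    for (seq_label in names(dataset$maps)) {
      if (seq_label == "fov_mask") next
      for (tissue in names(dataset$maps[[seq_label]])) {
        maps <- dataset$maps[[seq_label]][[tissue]]
        write_nifti_map(maps$values, maps$voxel_dims,
                        file.path(dir, "maps",
                                  sprintf("%s_%s.nii.gz", seq_label, tissue)))
      }
    }
  }
  invisible(dir)
}

write_nifti_map <- function(values, voxel_dims, path) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- c(voxel_dims, rep(1, length(dim(values)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_map <- function(path) {
  if (!file.exists(path))
    stop("I/O error: missing file ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  list(values = unclass(as.array(img)), voxel_dims = RNifti::pixdim(img)[1:3])
}

read_table_checked <- function(path, required) {
  if (!file.exists(path))
    stop("I/O error: missing file ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop(sprintf("schema error in %s: missing column(s) %s", basename(path),
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  tab
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory produced by [write_dataset()].
#' @return A list with the same structure: `cohort`, `predictions` (if
#'   present), `maps`, `fov_mask`, `config`.
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir))
    stop("I/O error: missing directory ", dir, call. = FALSE)
  out <- list()
  out$cohort <- read_table_checked(file.path(dir, "participants.tsv"),
                                   c("participant_id", "age", "has_retest"))
  out$cohort$has_retest <- as.logical(out$cohort$has_retest)
  class(out$cohort) <- c("cohort", "data.frame")
  validate_cohort(out$cohort)

  pred_path <- file.path(dir, "predictions.tsv")
  if (file.exists(pred_path)) {
    out$predictions <- read_table_checked(pred_path, c("participant_id", "age"))
    class(out$predictions) <- c("age_prediction_table", "data.frame")
  }

  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    # yaml flattens named vectors to lists; restore the numeric fields
    for (field in c("cross_sequence_corr_target", "template_volumes"))
      if (!is.null(cfg[[field]])) cfg[[field]] <- unlist(cfg[[field]])
    for (field in c("grid_shape", "voxel_dims"))
      if (!is.null(cfg[[field]])) cfg[[field]] <- unlist(cfg[[field]])
    out$config <- do.call(rapid_config, cfg)
  }

  mask_path <- file.path(dir, "fov_mask.nii.gz")
  if (file.exists(mask_path))
    out$fov_mask <- read_nifti_map(mask_path)$values > 0.5

  maps_dir <- file.path(dir, "maps")
  if (dir.exists(maps_dir)) {
    out$maps <- list()
    for (path in list.files(maps_dir, pattern = "\\.nii(\\.gz)?$",
                            full.names = TRUE)) {
      stem <- sub("\\.nii(\\.gz)?$", "", basename(path))
      parts <- strsplit(stem, "_")[[1L]]
      tissue <- parts[length(parts)]
      seq_label <- paste(parts[-length(parts)], collapse = "_")
      nii <- read_nifti_map(path)
      n <- dim(nii$values)[4L]
      ids <- if (seq_label == "retest" || grepl("retest", seq_label))
        out$cohort$participant_id[out$cohort$has_retest][seq_len(n)]
      else out$cohort$participant_id[seq_len(n)]
      if (n > nrow(out$cohort))
        stop(sprintf("schema error in %s: %d volumes but %d participants",
                     basename(path), n, nrow(out$cohort)), call. = FALSE)
      out$maps[[seq_label]][[tissue]] <- tissue_map_set(
        nii$values, tissue, seq_label, nii$voxel_dims, ids,
        fov_mask = if (!is.null(out$fov_mask) && grepl("rapid", seq_label))
          out$fov_mask)
    }
  }
  out
}

#' Generate a complete synthetic dataset in memory
#'
#' Convenience wrapper running [generate_cohort()],
#' [generate_tissue_maps()], [generate_retest_maps()] and
#' [generate_age_predictions()] with one configuration.
#'
#' @param config A [rapid_config()].
#' @return A list with `cohort`, `maps` (`standard`, `rapid`, `retest` per
#'   tissue), `fov_mask`, `predictions` and `config`.
#' @export
generate_dataset <- function(config = rapid_config()) {
  cohort <- generate_cohort(config)
  maps <- generate_tissue_maps(cohort, config)
  retest <- if (config$n_retest > 0L)
    lapply(maps$rapid, generate_retest_maps, cohort = cohort, config = config)
  list(cohort = cohort,
       maps = list(standard = maps$standard, rapid = maps$rapid, retest = retest),
       fov_mask = maps$fov_mask,
       predictions = generate_age_predictions(cohort, config),
       config = config)
}
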