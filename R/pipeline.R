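# End-to-end orchestration: phantom simulation (or ingestion), topographic
# segmentation, radiomics, Model-I and Model-II cross-validated scoring,
# the four fusion models, and the comparison report.  Every intermediate
# is persisted under the output directory and a structured log records
# per-stage seeds.

pipeline_defaults <- function() {
  list(
    rng_seed = 1L,
    output_dir = "mammocad-out",
    dataset = list(n_malignant = 100L, n_benign = 100L),
    phantom = unclass(phantom_spec()),
    segmentation = list(alpha = 0.1, beta = 0.5, size_growth_limit = 2.0,
                        circularity_reduction_limit = 0.5, connectivity = 8,
                        max_layers = 20L, seed_window = 3L),
    radiomics = list(band_width = 5L, glcm_levels = 32L, wavelet_levels = 2L),
    classical = list(k = 10L, variance_target = 0.95, kernel_degree = 3L,
                     regularisation = 1.0),
    dl = list(enabled = TRUE, input_size = 224L, channels = 3L,
              batch_size = 4L, initial_learning_rate = 1e-4,
              lr_decay_gamma = 0.4, epochs = 10L,
              augmentation_flip_prob = 0.5),
    fusion = list(w1 = 0.5),
    evaluation = list(threshold = 0.5, n_bins = 10L)
  )
}

merge_checked <- function(defaults, overrides, path = "") {
  for (nm in names(overrides)) {
    if (!nm %in% names(defaults))
      stop(sprintf("unknown configuration key '%s%s'", path, nm))
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- merge_checked(defaults[[nm]], overrides[[nm]],
                                      paste0(path, nm, "."))
    } else {
      tmpl <- defaults[[nm]]
      val <- overrides[[nm]]
      if (is.integer(tmpl)) val <- as.integer(val)
      else if (is.numeric(tmpl)) val <- as.numeric(val)
      defaults[[nm]] <- val
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Defaults carry the reference parameter set (alpha 0.1, beta 0.5,
#' termination limits 2.0 / 0.5, 10 folds, 95% PCA variance, batch 4,
#' learning rate 1e-4, decay 0.4, 10 epochs, fusion weight 0.5,
#' operating threshold 0.5).  Unknown keys are rejected.
#'
#' @param overrides nested list of overrides, or a YAML file path
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(overrides = list()) {
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  cfg <- merge_checked(pipeline_defaults(), overrides)
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#'
#' The written file reloads (via [pipeline_config()]) to an identical
#' configuration.
#'
#' @param config a `pipeline_config`
#' @param path YAML output path
#' @return `path`, invisibly
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("mammocad pipeline configuration\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

log_line <- function(log_path, ...) {
  msg <- sprintf(...)
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg))
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE)
  invisible(msg)
}

#' Run the full two-branch CAD pipeline
#'
#' simulate (or ingest) -> segment -> radiomics -> Model-I scores ->
#' Model-II scores -> four fusions -> comparison report.  Intermediates
#' (images, masks, layer table, feature CSV, score CSVs, report, the
#' effective configuration) are written under `config$output_dir`.
#'
#' @param config a [pipeline_config()]
#' @param rois optional pre-built `lesion_roi_set` (skips simulation)
#' @param persist write intermediates to disk
#' @return list with `report`, `scores` (named list of score tables),
#'   `segmentations`, `features`, `config`
#' @export
run_pipeline <- function(config = pipeline_config(), rois = NULL,
                         persist = TRUE) {
  out_dir <- config$output_dir
  log_path <- NULL
  if (persist) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(out_dir, "pipeline.log")
    write_pipeline_config(config, file.path(out_dir, "effective-config.yaml"))
  }

  if (is.null(rois)) {
    spec <- do.call(phantom_spec, config$phantom)
    log_line(log_path, "stage simulate: %d malignant + %d benign phantoms (seed %d)",
             config$dataset$n_malignant, config$dataset$n_benign, config$rng_seed)
    rois <- generate_dataset(spec, config$dataset$n_malignant,
                             config$dataset$n_benign, config$rng_seed)
  } else {
    log_line(log_path, "stage ingest: %d provided ROIs", length(rois))
  }
  if (persist) write_roi_dataset(rois, file.path(out_dir, "rois"))
  labels <- roi_labels(rois)

  sp <- do.call(seg_params, config$segmentation)
  log_line(log_path, "stage segment: %d ROIs", length(rois))
  segs <- lapply(rois, segment_lesion, params = sp)
  if (persist) {
    dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
    layer_rows <- lapply(seq_along(rois), function(i) {
      png::writePNG(segs[[i]]$final_mask * 1.0,
                    file.path(out_dir, "masks",
                              paste0(rois[[i]]$sample_id, "_mask.png")))
      cbind(sample_id = rois[[i]]$sample_id, summary(segs[[i]]))
    })
    utils::write.csv(do.call(rbind, layer_rows),
                     file.path(out_dir, "layers.csv"), row.names = FALSE)
  }

  log_line(log_path, "stage features: schema v%s", feature_schema()$version)
  rcfg <- radiomics_config(band_width = config$radiomics$band_width,
                           glcm_levels = config$radiomics$glcm_levels,
                           wavelet_levels = config$radiomics$wavelet_levels)
  features <- extract_features_dataset(rois, sp, rcfg, segs = segs)
  if (persist) write_feature_table(features, file.path(out_dir, "features.csv"))

  folds <- make_folds(labels, k = config$classical$k,
                      rng_seed = derive_seed(config$rng_seed, 17L),
                      sample_ids = roi_ids(rois))
  log_line(log_path, "stage train-classical: %d-fold CV (fold seed %d)",
           folds$k, folds$rng_seed)
  s1 <- cross_validated_scores(features, folds = folds,
                               model_config = list(
                                 variance_target = config$classical$variance_target,
                                 kernel_degree = config$classical$kernel_degree,
                                 regularisation = config$classical$regularisation))

  scores <- list("Model-I" = s1)
  if (isTRUE(config$dl$enabled)) {
    dcfg <- dl_config(input_size = config$dl$input_size,
                      channels = config$dl$channels,
                      batch_size = config$dl$batch_size,
                      initial_learning_rate = config$dl$initial_learning_rate,
                      lr_decay_gamma = config$dl$lr_decay_gamma,
                      epochs = config$dl$epochs,
                      augmentation_flip_prob = config$dl$augmentation_flip_prob,
                      rng_seed = derive_seed(config$rng_seed, 23L))
    log_line(log_path, "stage train-dl: surrogate backbone, input %d, %d epochs (seed %d)",
             dcfg$input_size, dcfg$epochs, dcfg$rng_seed)
    s2 <- finetune_cv(rois, folds, dcfg)
    scores[["Model-II"]] <- s2
    log_line(log_path, "stage fuse: four fusion models (w1 = %g)",
             config$fusion$w1)
    scores <- c(scores, fuse_all(s1, s2, w1 = config$fusion$w1))
  } else {
    log_line(log_path, "stage train-dl skipped (disabled); fusion stage skipped")
  }

  if (persist) {
    for (nm in names(scores)) {
      write_score_table(scores[[nm]],
                        file.path(out_dir, paste0("scores-", gsub("[^A-Za-z0-9.]", "_", nm), ".csv")))
    }
  }

  log_line(log_path, "stage evaluate: %d models", length(scores))
  report <- summarize_models(scores, threshold = config$evaluation$threshold,
                             n_bins = config$evaluation$n_bins)
  if (persist) write_report(report, file.path(out_dir, "report"))
  list(report = report, scores = scores, segmentations = segs,
       features = features, config = config)
}
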