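# Experiment orchestration: a nested configuration object (YAML-compatible),
# and a driver that runs generate -> train detector -> train embedder ->
# build bank -> score -> metrics from one global seed.

#' Experiment configuration
#'
#' Bundles every stage's specification. All stage seeds are derived from the
#' single global `seed`, so two runs with an equal config are bit-identical.
#'
#' @param seed global integer seed.
#' @param dataset a [dataset_spec()]; its own seed is overridden by `seed`.
#' @param scene a [scene_spec()].
#' @param detector a [detector_config()].
#' @param embedder an [embedder_config()].
#' @param shift a [shift_spec()].
#' @param k neighbours for the frame anomaly score.
#' @param target_tpr validation sensitivity at which the operating threshold
#'   is chosen.
#' @param output_dir directory for artifacts, or `NULL` to keep everything in
#'   memory.
#' @param write_dataset also write the generated PNG + JSON dataset (slow).
#' @return a list of class `scad_config`.
#' @export
experiment_config <- function(seed = 1L,
                              dataset = dataset_spec(),
                              scene = scene_spec(),
                              detector = detector_config(),
                              embedder = embedder_config(),
                              shift = shift_spec("cj-wf"),
                              k = 2L,
                              target_tpr = 0.9,
                              output_dir = NULL,
                              write_dataset = FALSE) {
  if (!inherits(dataset, "scad_dataset_spec")) stop_spec("`dataset` must be a dataset_spec()")
  validate_scene(scene)
  if (!inherits(detector, "scad_detector_config")) stop_spec("`detector` must be a detector_config()")
  if (!inherits(embedder, "scad_embedder_config")) stop_spec("`embedder` must be an embedder_config()")
  if (!inherits(shift, "scad_shift_spec")) stop_spec("`shift` must be a shift_spec()")
  if (k < 1L) stop_spec("`k` must be >= 1")
  structure(list(seed = as.integer(seed), dataset = dataset, scene = scene,
                 detector = detector, embedder = embedder, shift = shift,
                 k = as.integer(k), target_tpr = target_tpr,
                 output_dir = output_dir, write_dataset = isTRUE(write_dataset)),
            class = "scad_config")
}

#' Load an experiment configuration from YAML
#'
#' Recognised keys mirror the constructor arguments; nested blocks
#' (`scene:`, `dataset:`, `detector:`, `embedder:`, `shift:`, `scoring:`)
#' override the corresponding defaults field by field. `shift$kind` uses the
#' strings `cj-rc`, `cj-rr`, `cj-wf`; `embedder$objective` selects the
#' training-objective ablation.
#'
#' @param path YAML file path.
#' @return a `scad_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  merge_args <- function(fn, block) {
    if (is.null(block)) return(fn())
    do.call(fn, block)
  }
  experiment_config(
    seed = if (is.null(y$seed)) 1L else y$seed,
    dataset = merge_args(dataset_spec, y$dataset),
    scene = merge_args(scene_spec, y$scene),
    detector = merge_args(detector_config, y$detector),
    embedder = merge_args(embedder_config, y$embedder),
    shift = merge_args(shift_spec, y$shift),
    k = if (is.null(y$scoring$k)) 2L else y$scoring$k,
    target_tpr = if (is.null(y$scoring$target_tpr)) 0.9 else y$scoring$target_tpr,
    output_dir = y$output_dir,
    write_dataset = isTRUE(y$write_dataset)
  )
}

split_labels <- function(videos) vapply(videos, `[[`, character(1), "label")

# Detection accuracy of a trained detector over a list of videos.
detection_accuracy <- function(detector, videos, iou_threshold = 0.5,
                               class_threshold = 0.5) {
  frames <- collect_frames(videos)
  preds <- predict(detector, frames)
  evaluate_detection(preds, frames, iou_threshold, class_threshold)
}

#' Run the full screening experiment
#'
#' Executes the whole pipeline from one seed: synthetic dataset generation,
#' detector training on the normal training split, embedder training on
#' ground-truth training patches, feature-bank construction, video scoring of
#' the validation and test splits with detected boxes, ranking metrics on the
#' test split, and operating-point metrics at the target validation
#' sensitivity. Returns (and optionally writes) a manifest with the config
#' snapshot and all metric results.
#'
#' @param config an [experiment_config()].
#' @param dry_run validate the configuration and return the stage plan
#'   without computing.
#' @return a manifest list: `config`, `version`, `metrics`, `scores`,
#'   `artifacts`.
#' @export
run_experiment <- function(config, dry_run = FALSE) {
  if (!inherits(config, "scad_config")) stop_spec("`config` must be an experiment_config()")
  stages <- c("generate", "train_detector", "train_embedder", "build_bank",
              "score", "evaluate")
  if (dry_run) {
    return(list(config = config, stages = stages, dry_run = TRUE))
  }
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  stage <- "generate"
  manifest <- tryCatch({
    dspec <- config$dataset
    dspec$seed <- derive_seed(config$seed, 1L)
    dataset <- generate_dataset(dspec, config$scene)
    if (config$write_dataset && !is.null(out_dir)) {
      artifacts$dataset <- file.path(out_dir, "dataset")
      write_dataset(dataset, artifacts$dataset)
    }

    stage <- "train_detector"
    det_cfg <- config$detector
    det_cfg$seed <- derive_seed(config$seed, 2L)
    detector <- train_detector(dataset$train, det_cfg)
    test_labels_by_video <- split_labels(dataset$test)
    det_acc <- list(
      overall = detection_accuracy(detector, dataset$test),
      normal = detection_accuracy(detector,
                                  dataset$test[test_labels_by_video == "normal"]),
      abnormal = detection_accuracy(detector,
                                    dataset$test[test_labels_by_video == "abnormal"])
    )

    stage <- "train_embedder"
    emb_cfg <- config$embedder
    emb_cfg$seed <- derive_seed(config$seed, 3L)
    embedder <- train_embedder(dataset$train, emb_cfg, config$shift)

    stage <- "build_bank"
    bank <- build_feature_bank(embedder, dataset$train)
    if (!is.null(out_dir)) {
      artifacts$feature_bank <- file.path(out_dir, "feature_bank.csv")
      save_feature_bank(bank, artifacts$feature_bank)
    }

    stage <- "score"
    val_scores <- score_videos(dataset$val, detector, embedder, bank, config$k)
    test_scores <- score_videos(dataset$test, detector, embedder, bank, config$k)
    if (!is.null(out_dir)) {
      artifacts$val_scores <- file.path(out_dir, "val_scores.csv")
      artifacts$test_scores <- file.path(out_dir, "test_scores.csv")
      write_scores(val_scores, artifacts$val_scores)
      write_scores(test_scores, artifacts$test_scores)
    }

    stage <- "evaluate"
    vs <- val_scores[!is.na(val_scores$video_score), ]
    ts <- test_scores[!is.na(test_scores$video_score), ]
    rank <- ranking_metrics(ts$video_score, ts$label)
    op <- operating_point(vs$video_score, vs$label, config$target_tpr,
                          ts$video_score, ts$label)
    metrics <- list(
      detection_accuracy_iou50 = det_acc,
      auroc = unname(rank["auroc"]),
      auprc = unname(rank["auprc"]),
      operating_point = op,
      n_unscorable = sum(is.na(val_scores$video_score)) +
        sum(is.na(test_scores$video_score))
    )
    manifest <- list(
      config = config,
      version = as.character(utils::packageVersion("otoscad")),
      objective = config$embedder$objective,
      shift_kind = config$shift$kind,
      metrics = metrics,
      scores = list(val = val_scores, test = test_scores),
      artifacts = artifacts
    )
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(version = manifest$version, seed = config$seed,
             objective = manifest$objective, shift_kind = manifest$shift_kind,
             metrics = metrics, artifacts = artifacts),
        file.path(out_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    manifest
  }, scad_error = function(e) {
    stop_spec(sprintf("experiment failed at stage '%s': %s", stage,
                      conditionMessage(e)))
  })
  manifest
}
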