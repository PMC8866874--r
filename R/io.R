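# Dataset and artifact input/output. Datasets live on disk as one PNG
# directory per video plus a single annotations.json; feature banks and score
# tables as CSV; metric reports and manifests as JSON.

#' Write a dataset to the PNG + JSON layout
#'
#' Frames go to `<dir>/<video_id>/frame_%05d.png`; `<dir>/annotations.json`
#' lists every video with its label, split, and per-frame
#' `{has_eardrum, box: [x_min, y_min, x_max, y_max]}` in normalized
#' coordinates (x right, y down, edges inclusive).
#'
#' @param dataset a `scad_dataset` (or plain list of video records).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  videos <- if (inherits(dataset, "scad_dataset")) all_videos(dataset) else dataset
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- lapply(videos, function(v) {
    vdir <- file.path(dir, v$video_id)
    dir.create(vdir, showWarnings = FALSE)
    frames <- lapply(seq_along(v$frames), function(i) {
      fr <- v$frames[[i]]
      png::writePNG(fr$image, file.path(vdir, sprintf("frame_%05d.png", i)))
      rec <- list(has_eardrum = fr$has_eardrum)
      if (fr$has_eardrum) rec$box <- as.numeric(fr$box)
      rec
    })
    list(video_id = v$video_id, label = v$label, split = v$split,
         frames = frames)
  })
  jsonlite::write_json(ann, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset from the PNG + JSON layout
#'
#' Validates the annotation structure (box present iff `has_eardrum`, frames
#' on disk matching the annotation) and reports offending video/frame ids.
#'
#' @param dir dataset directory as written by [write_dataset()].
#' @return a split-keyed `scad_dataset`.
#' @export
read_dataset <- function(dir) {
  ann_path <- file.path(dir, "annotations.json")
  if (!file.exists(ann_path)) {
    if (!dir.exists(dir) || !length(list.files(dir))) {
      warning(sprintf("'%s' holds no dataset; returning an empty collection", dir))
      return(structure(list(train = list(), val = list(), test = list()),
                       class = "scad_dataset"))
    }
    stop_validation(sprintf("missing annotations.json in '%s'", dir))
  }
  ann <- jsonlite::read_json(ann_path)
  out <- list(train = list(), val = list(), test = list())
  for (va in ann) {
    vid <- va$video_id
    if (!va$split %in% names(out)) {
      stop_validation(sprintf("video '%s': unknown split '%s'", vid, va$split))
    }
    frames <- lapply(seq_along(va$frames), function(i) {
      fa <- va$frames[[i]]
      has <- isTRUE(fa$has_eardrum)
      if (!has && !is.null(fa$box)) {
        stop_validation(sprintf(
          "video '%s' frame %d: box present but has_eardrum is false", vid, i))
      }
      if (has && is.null(fa$box)) {
        stop_validation(sprintf(
          "video '%s' frame %d: has_eardrum without a box", vid, i))
      }
      path <- file.path(dir, vid, sprintf("frame_%05d.png", i))
      if (!file.exists(path)) {
        stop_validation(sprintf("video '%s': missing frame file '%s'", vid, path))
      }
      img <- png::readPNG(path)
      box <- if (has) as_box(unlist(fa$box)) else NULL
      new_frame_record(img, has, box)
    })
    if (!length(frames)) stop_validation(sprintf("video '%s' has no frames", vid))
    out[[va$split]][[length(out[[va$split]]) + 1L]] <-
      new_video_record(vid, frames, va$label, va$split)
  }
  structure(out, class = "scad_dataset")
}

#' Save a feature bank (embeddings + identifiers) to CSV
#'
#' @param bank a [feature_bank()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_feature_bank <- function(bank, path) {
  if (!inherits(bank, "scad_feature_bank")) stop_spec("`bank` must be a feature_bank()")
  df <- data.frame(video_id = bank$video_ids, frame_idx = bank$frame_idx)
  emb <- as.data.frame(bank$embeddings)
  names(emb) <- sprintf("e%03d", seq_len(ncol(emb)))
  data.table::fwrite(cbind(df, emb), path)
  invisible(path)
}

#' Load a feature bank from CSV, validating shape and norms
#'
#' @param path CSV path written by [save_feature_bank()].
#' @return a [feature_bank()].
#' @export
load_feature_bank <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  ecols <- grep("^e[0-9]+$", names(df))
  if (!nrow(df) || !length(ecols)) {
    stop_validation("feature bank file is empty or malformed")
  }
  emb <- as.matrix(df[, ecols, drop = FALSE])
  n <- sqrt(rowSums(emb^2))
  if (any(abs(n - 1) > 1e-5)) {
    stop_validation("feature bank rows are not unit norm")
  }
  feature_bank(emb, df$video_id, df$frame_idx)
}

#' Export per-video scores as CSV
#' @param scores data.frame from [score_videos()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  data.table::fwrite(scores, path)
  invisible(path)
}

#' Export detections of one or more videos as CSV
#' @param detections named list (by video id) of [run_detector()] outputs, or
#'   a single such data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  if (is.data.frame(detections)) detections <- list(video = detections)
  rows <- lapply(names(detections), function(vid) {
    d <- detections[[vid]]
    if (!nrow(d)) return(NULL)
    cbind(data.frame(video_id = vid), d)
  })
  data.table::fwrite(do.call(rbind, Filter(Negate(is.null), rows)), path)
  invisible(path)
}
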