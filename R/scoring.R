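# Anomaly scoring: kNN cosine-distance frame scores against a bank of normal
# training embeddings, mean aggregation to the video level, threshold-free
# ranking metrics, and operating-point selection at a target validation
# sensitivity.

#' Feature bank of normal training embeddings
#'
#' @param embeddings matrix of unit-norm embeddings, one row per training
#'   patch.
#' @param video_ids,frame_idx optional per-row provenance identifiers.
#' @return an object of class `scad_feature_bank`.
#' @export
feature_bank <- function(embeddings, video_ids = NULL, frame_idx = NULL) {
  if (!is.matrix(embeddings) || nrow(embeddings) == 0L) {
    stop_validation("feature bank needs a non-empty embedding matrix")
  }
  check_unit_rows(embeddings, "bank embeddings")
  if (is.null(video_ids)) video_ids <- rep(NA_character_, nrow(embeddings))
  if (is.null(frame_idx)) frame_idx <- rep(NA_integer_, nrow(embeddings))
  if (length(video_ids) != nrow(embeddings) || length(frame_idx) != nrow(embeddings)) {
    stop_validation("bank identifiers must match the number of rows")
  }
  structure(list(embeddings = embeddings,
                 video_ids = as.character(video_ids),
                 frame_idx = as.integer(frame_idx)),
            class = "scad_feature_bank")
}

#' Build the feature bank from ground-truth training patches
#'
#' Embeds the ground-truth-box patch of every annotated frame of the training
#' videos (optionally capped per video).
#'
#' @param embedder a trained `scad_embedder`.
#' @param train_videos list of training video records.
#' @param per_video_cap optional maximum number of patches per video (evenly
#'   spaced frames are kept).
#' @return a [feature_bank()].
#' @export
build_feature_bank <- function(embedder, train_videos, per_video_cap = Inf) {
  patches <- list()
  vids <- character(0)
  fidx <- integer(0)
  for (v in train_videos) {
    ann <- which(vapply(v$frames, function(f) isTRUE(f$has_eardrum), logical(1)))
    if (length(ann) > per_video_cap) {
      ann <- ann[unique(round(seq(1, length(ann), length.out = per_video_cap)))]
    }
    for (i in ann) {
      fr <- v$frames[[i]]
      patches[[length(patches) + 1L]] <-
        extract_patch(fr$image, fr$box, embedder$config$patch_size)
      vids <- c(vids, v$video_id)
      fidx <- c(fidx, i)
    }
  }
  if (!length(patches)) stop_validation("no annotated training patches found")
  feature_bank(embed_patches(embedder, patches), vids, fidx)
}

#' kNN frame-level anomaly score
#'
#' Sum over the `k` bank embeddings nearest in cosine similarity of
#' `1 - phi(x) . phi(y)`; ties in neighbour selection are broken by bank row
#' order. Ranges over \[0, 2k\].
#'
#' @param feat unit-norm embedding of the query patch.
#' @param bank a [feature_bank()].
#' @param k number of neighbours (default 2).
#' @return non-negative scalar.
#' @examples
#' b <- feature_bank(rbind(c(1, 0), c(0, 1), c(-1, 0)))
#' frame_anomaly_score(c(1, 0), b, k = 2)  # 1.0
#' @export
frame_anomaly_score <- function(feat, bank, k = 2L) {
  if (!inherits(bank, "scad_feature_bank")) stop_spec("`bank` must be a feature_bank()")
  if (k < 1L || k > nrow(bank$embeddings)) {
    stop_spec("`k` must lie between 1 and the bank size")
  }
  feat <- as.numeric(feat)
  if (abs(sqrt(sum(feat^2)) - 1) > 1e-5) stop_spec("`feat` must be unit norm")
  sims <- as.numeric(bank$embeddings %*% feat)
  nn <- order(-sims)[seq_len(k)]  # stable: ties resolved by row order
  sum(1 - sims[nn])
}

# Vectorized scoring of many query embeddings.
frame_anomaly_scores <- function(feats, bank, k = 2L) {
  apply(feats, 1, frame_anomaly_score, bank = bank, k = k)
}

#' Video-level anomaly score
#'
#' Arithmetic mean of the frame scores of all detected eardrum frames. A video
#' with no detections carries no evidence and raises a distinct
#' `scad_no_evidence_error` so callers can route it to "unscorable".
#'
#' @param frame_scores numeric vector of frame-level scores.
#' @return scalar mean score.
#' @export
video_anomaly_score <- function(frame_scores) {
  if (length(frame_scores) == 0L) {
    stop_no_evidence("no detected eardrum frames; video is unscorable")
  }
  if (anyNA(frame_scores)) stop_numeric("frame scores contain NA")
  mean(frame_scores)
}

#' Score a set of videos end to end
#'
#' For each video: run the detector, extract the detected patches, embed them,
#' compute kNN frame scores against the bank, and average. Videos without
#' detections are reported with `NA` score rather than aborting the batch.
#'
#' @param videos list of video records.
#' @param detector a trained `scad_detector`.
#' @param embedder a trained `scad_embedder`.
#' @param bank a [feature_bank()] built from training patches.
#' @param k neighbours for the frame score.
#' @param class_threshold detector score cutoff.
#' @return data.frame with `video_id`, `n_frames_scored`, `video_score`,
#'   `label`.
#' @export
score_videos <- function(videos, detector, embedder, bank, k = 2L,
                         class_threshold = NULL) {
  rows <- lapply(videos, function(v) {
    det <- run_detector(detector, v, class_threshold)
    score <- NA_real_
    n <- nrow(det)
    if (n > 0L) {
      patches <- lapply(seq_len(n), function(i) {
        extract_patch(v$frames[[det$frame_idx[i]]]$image,
                      bounding_box(det$x_min[i], det$y_min[i],
                                   det$x_max[i], det$y_max[i]),
                      embedder$config$patch_size)
      })
      feats <- embed_patches(embedder, patches)
      score <- video_anomaly_score(frame_anomaly_scores(feats, bank, k))
    }
    data.frame(video_id = v$video_id, n_frames_scored = n,
               video_score = score, label = v$label)
  })
  do.call(rbind, rows)
}

as_positive_label <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "abnormal"
  } else {
    as.numeric(labels) == 1
  }
}

#' Ranking metrics: AUROC and AUPRC
#'
#' AUROC follows the Mann-Whitney pairwise formulation with ties counted as
#' one half; AUPRC integrates the precision-recall curve stepwise over
#' distinct score thresholds. The abnormal class is positive.
#'
#' @param scores numeric anomaly scores (higher = more anomalous).
#' @param labels `"normal"`/`"abnormal"` strings or 0/1 numerics.
#' @return named vector `c(auroc, auprc)`, both percentages.
#' @export
ranking_metrics <- function(scores, labels) {
  pos <- as_positive_label(labels)
  if (length(scores) != length(pos)) stop_spec("scores and labels differ in length")
  if (anyNA(scores)) stop_numeric("scores contain NA")
  if (!any(pos) || all(pos)) stop_spec("both classes must be present")
  sp <- scores[pos]
  sn <- scores[!pos]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  auroc <- mean(cmp)

  # step-integrated precision-recall over distinct thresholds, ties grouped
  ord <- order(-scores)
  s <- scores[ord]
  y <- pos[ord]
  grp_last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(!y)[grp_last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(pos)
  auprc <- sum(diff(c(0, rec)) * prec)

  c(auroc = 100 * auroc, auprc = 100 * auprc)
}

#' Choose an operating threshold at a target validation sensitivity
#'
#' Scans candidate thresholds (midpoints between adjacent distinct validation
#' scores, plus one below the minimum) and picks the largest threshold whose
#' validation true-positive rate under the strictly-greater decision rule
#' `score > psi` still reaches `target_tpr`; then evaluates accuracy,
#' sensitivity, specificity and precision on the test scores at that fixed
#' threshold.
#'
#' @param val_scores,val_labels validation anomaly scores and labels (both
#'   classes required).
#' @param target_tpr required validation sensitivity (default 0.9).
#' @param test_scores,test_labels test-set scores and labels.
#' @return list with `threshold` and percentage metrics `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, plus the achieved
#'   `val_sensitivity`.
#' @export
operating_point <- function(val_scores, val_labels, target_tpr = 0.9,
                            test_scores, test_labels) {
  vpos <- as_positive_label(val_labels)
  if (!any(vpos) || all(vpos)) stop_spec("validation needs both classes")
  if (target_tpr < 0 || target_tpr > 1) stop_spec("target_tpr must be in [0, 1]")
  u <- sort(unique(val_scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)
  tpr <- vapply(cand, function(psi) mean(val_scores[vpos] > psi), numeric(1))
  ok <- which(tpr >= target_tpr)
  if (!length(ok)) stop_spec("target validation sensitivity is unreachable")
  psi <- max(cand[ok])

  tpos <- as_positive_label(test_labels)
  pred <- test_scores > psi
  tp <- sum(pred & tpos)
  fp <- sum(pred & !tpos)
  tn <- sum(!pred & !tpos)
  fn <- sum(!pred & tpos)
  list(threshold = psi,
       accuracy = 100 * (tp + tn) / length(test_scores),
       sensitivity = 100 * tp / max(1, tp + fn),
       specificity = 100 * tn / max(1, tn + fp),
       precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
       val_sensitivity = 100 * mean(val_scores[vpos] > psi))
}
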