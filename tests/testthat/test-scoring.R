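# kNN scoring, aggregation, ranking metrics and operating-point selection.

test_that("frame anomaly score: closed cases and the brute-force oracle", {
  d <- 8
  u <- runit(1, d)[1, ]
  bank_dup <- feature_bank(rbind(u, u, u))
  expect_equal(frame_anomaly_score(u, bank_dup, k = 3), 0)

  # orthogonal bank: every neighbour contributes 1 - 0 = 1
  e <- diag(4)
  expect_equal(frame_anomaly_score(e[1, ], feature_bank(e[2:4, ]), k = 2), 2)

  b3 <- feature_bank(rbind(c(1, 0), c(0, 1), c(-1, 0)))
  expect_equal(frame_anomaly_score(c(1, 0), b3, k = 2), 1.0)

  expect_error(frame_anomaly_score(c(1, 0), b3, k = 4), class = "scad_spec_error")
  expect_error(feature_bank(matrix(numeric(0), 0, 2)),
               class = "scad_validation_error")

  set.seed(41)
  bank <- feature_bank(runit(50, d))
  for (i in 1:200) {
    q <- runit(1, d)[1, ]
    k <- sample(1:5, 1)
    expect_equal(frame_anomaly_score(q, bank, k),
                 oracle_knn_score(q, bank$embeddings, k), tolerance = 1e-10)
  }
})

test_that("frame score is bounded by [0, 2k] and non-decreasing in angular
           distance to the bank", {
  set.seed(42)
  bank <- feature_bank(runit(30, 6))
  for (i in 1:50) {
    q <- runit(1, 6)[1, ]
    s <- frame_anomaly_score(q, bank, 2)
    expect_gte(s, 0); expect_lte(s, 4)
  }
  # against a single reference, the score grows with the angular distance
  b1 <- bank$embeddings[1, ]
  single <- feature_bank(matrix(b1, 1))
  v2 <- runit(1, 6)[1, ]
  perp <- l2_normalize(v2 - sum(v2 * b1) * b1)
  scores <- vapply(seq(0, pi, length.out = 7), function(ang) {
    frame_anomaly_score(cos(ang) * b1 + sin(ang) * perp, single, 1)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("video score is the frame mean, order-invariant, and empty input
           raises a distinct no-evidence error", {
  expect_equal(video_anomaly_score(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(video_anomaly_score(0.7), 0.7)
  set.seed(43)
  s <- runif(9)
  expect_equal(video_anomaly_score(s), video_anomaly_score(sample(s)))
  expect_error(video_anomaly_score(numeric(0)),
               class = "scad_no_evidence_error")
})

test_that("mixing in anomalous frames raises the video score linearly", {
  lo <- rep(0.1, 8)
  hi <- rep(1.5, 8)
  fracs <- seq(0, 1, by = 0.25)
  scores <- vapply(fracs, function(f) {
    n_hi <- round(f * 8)
    video_anomaly_score(c(hi[seq_len(n_hi)], lo[seq_len(8 - n_hi)]))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_equal(diff(scores), rep(diff(scores)[1], 4), tolerance = 1e-12)
})

test_that("ranking metrics: anchors, tie convention, and the exhaustive
           pairwise oracle on all small label patterns", {
  expect_equal(unname(ranking_metrics(c(1, 2, 3, 4), c(0, 0, 1, 1))["auroc"]),
               100)
  expect_equal(unname(ranking_metrics(rep(0.5, 6),
                                      c(0, 0, 0, 1, 1, 1))["auroc"]), 50)
  expect_equal(unname(ranking_metrics(c(0.1, 0.4, 0.35, 0.8),
                                      c(0, 0, 1, 1))["auroc"]), 75)
  expect_error(ranking_metrics(1:3, c(1, 1, 1)), class = "scad_spec_error")

  set.seed(44)
  for (n in 2:8) {
    for (rep in 1:8) {
      labels <- sample(c(0, 1), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- sample(seq(0.1, 0.8, by = 0.1), n, replace = TRUE)  # with ties
      expect_equal(unname(ranking_metrics(scores, labels)["auroc"]),
                   oracle_auroc(scores, labels), tolerance = 1e-10)
    }
  }
})

test_that("ranking metrics agree with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(45)
  scores <- runif(40)
  labels <- sample(c(0, 1), 40, replace = TRUE)
  got <- ranking_metrics(scores, labels)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(unname(got["auroc"]), 100 * ref, tolerance = 1e-10)
})

test_that("auprc behaves at its anchors", {
  r <- ranking_metrics(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(unname(r["auprc"]), 100)
  # random scores on balanced labels: AUPRC near the positive prevalence
  set.seed(46)
  r2 <- ranking_metrics(runif(2000), rep(c(0, 1), 1000))
  expect_gt(unname(r2["auprc"]), 40)
  expect_lt(unname(r2["auprc"]), 60)
})

test_that("operating point hits the target validation sensitivity by
           construction", {
  # worked set: both abnormal validation scores must be flagged at TPR 0.9
  op <- operating_point(val_scores = c(0.8, 0.6, 0.3, 0.4),
                        val_labels = c(1, 1, 0, 0),
                        target_tpr = 0.9,
                        test_scores = c(0.7, 0.45, 0.2, 0.55),
                        test_labels = c(1, 1, 0, 0))
  expect_lt(op$threshold, 0.6)
  expect_gte(op$threshold, 0.4)
  expect_equal(op$val_sensitivity, 100)
  # at psi = 0.5: one hit, one miss, one false alarm, one rejection
  expect_equal(op$accuracy, 50)
  expect_equal(op$sensitivity, 50)
  expect_equal(op$specificity, 50)
  expect_equal(op$precision, 50)
  # target 1.0 forces the threshold just under the lowest abnormal score
  op2 <- operating_point(c(0.8, 0.6, 0.3, 0.4), c(1, 1, 0, 0), 1.0,
                         c(0.7, 0.1), c(1, 0))
  expect_lt(op2$threshold, 0.6)
  expect_equal(op2$sensitivity, 100)
  expect_equal(op2$specificity, 100)
  expect_error(operating_point(c(1, 2), c(0, 0), 0.9, 1, 1),
               class = "scad_spec_error")
  expect_error(operating_point(c(1, 2), c(0, 1), 1.5, 1, 1),
               class = "scad_spec_error")
})

test_that("end-to-end scoring on the tiny fixture produces valid, bounded
           per-video scores", {
  # class separability is asserted at study scale in the acceptance file;
  # the 6-video fixture only checks the plumbing contracts
  ds <- tiny_dataset()
  det <- tiny_detector()
  emb <- tiny_embedder("final")
  bank <- build_feature_bank(emb, ds$train)
  sc <- score_videos(c(ds$val, ds$test), det, emb, bank, k = 2L)
  expect_equal(nrow(sc), 12L)
  expect_true(all(c("video_id", "n_frames_scored", "video_score", "label")
                  %in% names(sc)))
  ok <- !is.na(sc$video_score)
  expect_gt(sum(ok), 0L)
  expect_true(all(sc$video_score[ok] >= 0 & sc$video_score[ok] <= 4))
  expect_true(all(sc$n_frames_scored[!ok] == 0L))
})

test_that("a training video scored against its own bank is near zero", {
  ds <- tiny_dataset()
  emb <- tiny_embedder("final")
  bank <- build_feature_bank(emb, ds$train)
  v <- ds$train[[1]]
  idx <- which(vapply(v$frames, function(f) isTRUE(f$has_eardrum), logical(1)))
  patches <- lapply(idx, function(i) {
    extract_patch(v$frames[[i]]$image, v$frames[[i]]$box, 32L)
  })
  feats <- embed_patches(emb, patches)
  s <- video_anomaly_score(otoscad:::frame_anomaly_scores(feats, bank, k = 1))
  expect_lt(s, 1e-8)
})
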