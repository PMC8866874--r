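# Detection geometry, loss, evaluation protocol and the detector model
# contracts at unit scale.

test_that("iou handles identity, disjoint and analytic half-overlap cases", {
  a <- bounding_box(0.1, 0.2, 0.6, 0.8)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(bounding_box(0, 0, 0.3, 0.3),
                   bounding_box(0.5, 0.5, 0.9, 0.9)), 0.0)
  expect_equal(iou(c(0, 0, 1, 1), c(0, 0, 0.5, 1)), 0.5)
  expect_error(iou(a, c(0.2, 0.2, 0.2, 0.4)), class = "scad_spec_error")
})

test_that("iou is symmetric, bounded and matches the rasterization oracle", {
  set.seed(101)
  for (i in 1:25) {
    # grid-aligned corners make the raster oracle exact (see acceptance file)
    mk2 <- function() sort(sample(seq(0, 250, by = 5), 2))
    ca <- mk2(); cb <- mk2(); ra <- mk2(); rb <- mk2()
    a <- bounding_box(ca[1] / 250, ra[1] / 250, ca[2] / 250, ra[2] / 250)
    b <- bounding_box(cb[1] / 250, rb[1] / 250, cb[2] / 250, rb[2] / 250)
    v <- iou(a, b)
    expect_equal(v, iou(b, a))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_lt(abs(v - oracle_iou_raster(a, b)), 1e-3)
  }
})

test_that("detection loss combines cross entropy with masked box L1", {
  box <- bounding_box(0.2, 0.2, 0.8, 0.8)
  pos <- list(has_eardrum = TRUE, box = box)
  neg <- list(has_eardrum = FALSE, box = NULL)
  # perfect prediction
  expect_equal(detection_loss(list(class_prob = 1, box = box), pos), 0)
  # uninformative classifier, exact box -> ln 2
  expect_equal(detection_loss(list(class_prob = c(0.5, 0.5), box = box), pos),
               log(2))
  # negative frame: box term masked regardless of the predicted box
  expect_equal(detection_loss(list(class_prob = 0,
                                   box = bounding_box(0, 0, 1, 1)), neg), 0)
  expect_equal(detection_loss(list(class_prob = 0.25, box = NULL), neg),
               -log(0.75))
  # positive frame: L1 averaged over the 4 coordinates (two off by 0.1)
  shifted <- bounding_box(0.3, 0.2, 0.9, 0.8)
  expect_equal(detection_loss(list(class_prob = 1, box = shifted), pos), 0.05)
  expect_error(detection_loss(list(class_prob = NaN, box = box), pos),
               class = "scad_numeric_error")
})

test_that("evaluate_detection follows the protocol and is monotone in IoU", {
  truth_box <- bounding_box(0.2, 0.2, 0.8, 0.8)
  truths <- list(
    list(has_eardrum = TRUE, box = truth_box),
    list(has_eardrum = TRUE, box = truth_box),
    list(has_eardrum = FALSE, box = NULL))
  preds <- list(
    list(class_score = 0.9, box = truth_box),                       # correct
    list(class_score = 0.9, box = bounding_box(0.5, 0.5, 0.9, 0.9)), # bad box
    list(class_score = 0.2, box = NULL))                             # correct
  acc <- evaluate_detection(preds, truths, iou_threshold = 0.5)
  expect_equal(round(acc, 1), 66.7)
  expect_equal(evaluate_detection(list(preds[[1]]), list(truths[[1]])), 100)
  # slightly offset boxes: accuracy cannot increase with the IoU threshold
  off <- list(class_score = 0.9, box = bounding_box(0.25, 0.2, 0.85, 0.8))
  accs <- vapply(c(0.3, 0.5, 0.75, 0.9, 0.99), function(th) {
    evaluate_detection(list(off, preds[[1]], preds[[3]]), truths, th)
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_error(evaluate_detection(list(), list()), class = "scad_spec_error")
})

test_that("extract_patch crops exactly and resizes deterministically", {
  set.seed(7)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  # identity crop
  expect_equal(extract_patch(img, c(0, 0, 1, 1), 32L), img, tolerance = 1e-12)
  # integer-aligned quarter crop at native size: bit-identical copy
  quarter <- extract_patch(img, c(0, 0, 0.5, 0.5), 16L)
  expect_equal(quarter, img[1:16, 1:16, , drop = FALSE], tolerance = 1e-12)
  # constant image stays constant under any crop/resize
  const <- array(0.3, c(32, 32, 3))
  expect_equal(extract_patch(const, c(0.1, 0.2, 0.6, 0.9), 24L),
               array(0.3, c(24, 24, 3)), tolerance = 1e-12)
  expect_warning(extract_patch(img, bounding_box(-0.1, 0, 0.5, 0.5), 8L),
                 "clipping")
})

test_that("detector training reduces the loss and is seed-reproducible", {
  det <- tiny_detector()
  h <- det$loss_history
  expect_lt(mean(tail(h, 20)), 0.4 * mean(head(h, 5)))
  det2 <- train_detector(tiny_dataset()$train,
                         detector_config(steps = 120L, batch_size = 32L,
                                         seed = 5L))
  expect_identical(det$params, det2$params)
  expect_error(train_detector(list(), detector_config()),
               class = "scad_spec_error")
})

test_that("run_detector respects thresholds and box invariants", {
  det <- tiny_detector()
  v <- tiny_dataset()$val[[1]]
  all_frames <- run_detector(det, v, class_threshold = 0)
  expect_equal(nrow(all_frames), length(v$frames))
  none <- run_detector(det, v, class_threshold = 1 + 1e-9)
  expect_equal(nrow(none), 0L)
  d <- run_detector(det, v)
  expect_true(all(d$x_min < d$x_max & d$y_min < d$y_max))
  expect_true(all(d$score >= det$config$class_threshold))
  expect_true(all(d$frame_idx %in% seq_along(v$frames)))
})
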