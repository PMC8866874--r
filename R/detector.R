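# Detector model: a compact fully-connected encoder over mean-pooled pixel
# features with two heads -- a 2-logit eardrum classifier and a 4-output box
# regressor squashed to [0,1] by a sigmoid. The single-instance framing (at
# most one eardrum per frame) makes anchors/NMS unnecessary.

#' Detector configuration
#'
#' @param input_size frame side length in pixels the detector expects.
#' @param pool mean-pooling factor applied before the dense encoder.
#' @param hidden hidden layer width.
#' @param steps number of SGD steps.
#' @param batch_size minibatch size.
#' @param lr,momentum,weight_decay SGD hyperparameters.
#' @param augment apply training augmentation (random resized crop with
#'   box-consistent re-annotation, mild color jitter, cutout).
#' @param class_threshold default score cutoff for declaring an eardrum frame.
#' @param seed integer seed for weight init and batch sampling.
#' @return a list of class `scad_detector_config`.
#' @export
detector_config <- function(input_size = 64L, pool = 4L, hidden = 96L,
                            steps = 250L, batch_size = 48L, lr = 0.05,
                            momentum = 0.9, weight_decay = 1e-4,
                            augment = TRUE, class_threshold = 0.5,
                            seed = 1L) {
  structure(list(input_size = as.integer(input_size), pool = as.integer(pool),
                 hidden = as.integer(hidden), steps = as.integer(steps),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 augment = isTRUE(augment), class_threshold = class_threshold,
                 seed = as.integer(seed)),
            class = "scad_detector_config")
}

detector_feature_dim <- function(config) {
  3L * (config$input_size %/% config$pool)^2
}

detector_init <- function(config) {
  p <- detector_feature_dim(config)
  model <- list(
    trunk = nn_dense_init(p, config$hidden),
    cls = nn_dense_init(config$hidden, 2L, scale = sqrt(1 / config$hidden)),
    box = nn_dense_init(config$hidden, 4L, scale = sqrt(1 / config$hidden))
  )
  structure(list(params = model, config = config, loss_history = numeric(0)),
            class = "scad_detector")
}

detector_featurize <- function(frames_images, config) {
  t(vapply(frames_images, function(img) {
    if (!all(dim(img)[1:2] == config$input_size)) {
      img <- resize_bilinear(img, config$input_size, config$input_size)
    }
    flatten_features(img, config$pool)
  }, numeric(detector_feature_dim(config))))
}

detector_forward <- function(model, X) {
  pr <- model$params
  H <- relu(sweep(X %*% pr$trunk$W, 2, pr$trunk$b, "+"))
  logits <- sweep(H %*% pr$cls$W, 2, pr$cls$b, "+")
  boxes <- sigmoid(sweep(H %*% pr$box$W, 2, pr$box$b, "+"))
  list(H = H, logits = logits, P = softmax_rows(logits), boxes = boxes)
}

# Joint loss and parameter gradients for one featurized minibatch.
# y: logical eardrum flags; B_gt: n x 4 box targets (rows of negatives ignored).
detector_loss_grad <- function(model, X, y, B_gt) {
  fw <- detector_forward(model, X)
  n <- nrow(X)
  Y <- cbind(!y, y) * 1
  p_true <- fw$P[cbind(seq_len(n), y + 1L)]
  loss_cls <- mean(-log(pmax(p_true, 1e-12)))
  dlogits <- (fw$P - Y) / n

  pos <- which(y)
  loss_box <- 0
  dbox_pre <- matrix(0, n, 4)
  if (length(pos)) {
    diffs <- fw$boxes[pos, , drop = FALSE] - B_gt[pos, , drop = FALSE]
    loss_box <- mean(abs(diffs))
    dsig <- sign(diffs) / (4 * length(pos))
    dbox_pre[pos, ] <- dsig * fw$boxes[pos, , drop = FALSE] *
      (1 - fw$boxes[pos, , drop = FALSE])
  }

  pr <- model$params
  dH <- dlogits %*% t(pr$cls$W) + dbox_pre %*% t(pr$box$W)
  dH[fw$H <= 0] <- 0
  grads <- list(
    trunk = list(W = t(X) %*% dH, b = colSums(dH)),
    cls = list(W = t(fw$H) %*% dlogits, b = colSums(dlogits)),
    box = list(W = t(fw$H) %*% dbox_pre, b = colSums(dbox_pre))
  )
  list(loss = loss_cls + loss_box, grads = grads)
}

# Box-consistent training augmentation of one frame record.
augment_detection_frame <- function(fr, size) {
  s_y <- stats::runif(1, 0.85, 1)
  s_x <- stats::runif(1, 0.85, 1)
  y0 <- stats::runif(1, 0, 1 - s_y)
  x0 <- stats::runif(1, 0, 1 - s_x)
  img <- resize_bilinear(fr$image, size, size,
                         y0 = y0, y1 = y0 + s_y, x0 = x0, x1 = x0 + s_x)
  has <- FALSE
  box <- NULL
  if (isTRUE(fr$has_eardrum)) {
    b <- fr$box
    nx <- c(max(0, (b[["x_min"]] - x0) / s_x), min(1, (b[["x_max"]] - x0) / s_x))
    ny <- c(max(0, (b[["y_min"]] - y0) / s_y), min(1, (b[["y_max"]] - y0) / s_y))
    if (nx[2] - nx[1] >= ANNOTATION_MIN_EXTENT &&
        ny[2] - ny[1] >= ANNOTATION_MIN_EXTENT) {
      has <- TRUE
      box <- bounding_box(nx[1], ny[1], nx[2], ny[2])
    }
  }
  img <- color_jitter(img, list(brightness = 0.2, contrast = 0.2,
                                saturation = 0.2, hue = 0.05))
  if (stats::runif(1) < 0.5) {  # cutout
    side <- stats::runif(1, 0.1, 0.25)
    cy <- stats::runif(1, 0, 1 - side)
    cx <- stats::runif(1, 0, 1 - side)
    ry <- max(1L, ceiling(cy * size)):min(size, ceiling((cy + side) * size))
    rx <- max(1L, ceiling(cx * size)):min(size, ceiling((cx + side) * size))
    img[ry, rx, ] <- 0
  }
  list(image = img, has_eardrum = has, box = box)
}

# Flatten videos into per-frame training records.
collect_frames <- function(videos) {
  out <- list()
  for (v in videos) for (fr in v$frames) out[[length(out) + 1L]] <- fr
  out
}

#' Train the eardrum detector on normal videos
#'
#' Minibatch SGD on the joint cross-entropy + masked-L1 objective, using every
#' frame of the supplied (normal) training videos. Fully deterministic for a
#' fixed `config$seed`.
#'
#' @param train_videos list of video records (normal split).
#' @param config a [detector_config()].
#' @return a trained model of class `scad_detector` (with `loss_history`).
#' @export
train_detector <- function(train_videos, config = detector_config()) {
  frames <- collect_frames(train_videos)
  if (!length(frames)) stop_spec("no training frames supplied")
  if (!any(vapply(frames, function(f) isTRUE(f$has_eardrum), logical(1)))) {
    stop_spec("training data contains no eardrum-positive frames")
  }
  with_seed(config$seed, {
    model <- detector_init(config)
    state <- rapply(model$params, function(p) p * 0, how = "replace")
    losses <- numeric(config$steps)
    n <- length(frames)
    for (step in seq_len(config$steps)) {
      idx <- sample.int(n, min(config$batch_size, n))
      recs <- frames[idx]
      if (config$augment) {
        recs <- lapply(recs, augment_detection_frame, size = config$input_size)
      }
      X <- detector_featurize(lapply(recs, `[[`, "image"), config)
      y <- vapply(recs, function(r) isTRUE(r$has_eardrum), logical(1))
      B <- matrix(0.5, length(recs), 4)
      for (i in seq_along(recs)) if (y[i]) B[i, ] <- as.numeric(recs[[i]]$box)
      lg <- detector_loss_grad(model, X, y, B)
      losses[step] <- lg$loss
      for (part in names(model$params)) {
        upd <- sgd_step(model$params[[part]], lg$grads[[part]],
                        state[[part]], config$lr, config$momentum,
                        config$weight_decay)
        model$params[[part]] <- upd$params
        state[[part]] <- upd$state
      }
    }
    model$loss_history <- losses
    model
  })
}

#' Per-frame detector predictions
#'
#' @param object a trained `scad_detector`.
#' @param frames list of frame records or raw image arrays.
#' @param ... unused.
#' @return list of detection outputs, each `list(class_score, box)`; the box
#'   is meaningful only when the frame is classified positive.
#' @export
predict.scad_detector <- function(object, frames, ...) {
  imgs <- lapply(frames, function(f) if (is.list(f)) f$image else f)
  X <- detector_featurize(imgs, object$config)
  fw <- detector_forward(object, X)
  lapply(seq_len(nrow(X)), function(i) {
    bx <- fw$boxes[i, ]
    box <- if (bx[1] < bx[3] && bx[2] < bx[4]) {
      bounding_box(bx[1], bx[2], bx[3], bx[4])
    } else NULL
    list(class_score = fw$P[i, 2], box = box)
  })
}

#' Run the detector over a video
#'
#' @param model a trained `scad_detector`.
#' @param video a video record.
#' @param class_threshold minimum class score to report a frame (default from
#'   the model config).
#' @return data.frame with one row per detected eardrum frame:
#'   `frame_idx`, `score`, `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
run_detector <- function(model, video, class_threshold = NULL) {
  if (is.null(class_threshold)) class_threshold <- model$config$class_threshold
  preds <- predict(model, video$frames)
  keep <- which(vapply(preds, function(p) {
    p$class_score >= class_threshold && !is.null(p$box)
  }, logical(1)))
  out <- data.frame(frame_idx = integer(0), score = numeric(0),
                    x_min = numeric(0), y_min = numeric(0),
                    x_max = numeric(0), y_max = numeric(0))
  for (i in keep) {
    b <- preds[[i]]$box
    out[nrow(out) + 1L, ] <- list(i, preds[[i]]$class_score,
                                  b[["x_min"]], b[["y_min"]],
                                  b[["x_max"]], b[["y_max"]])
  }
  out
}
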