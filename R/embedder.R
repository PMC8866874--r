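# Self-supervised embedder: a dense encoder over mean-pooled patch pixels
# whose l2-normalized output lives on the unit sphere. Trained with the
# mean-shifted contrastive objective plus the distributional-shift angular
# loss; shifted views are manufactured on the fly by the configured shift
# transformation and enter the contrastive term as additional instances.

#' Embedder configuration
#'
#' @param patch_size patch side length in pixels fed to the encoder.
#' @param pool mean-pooling factor applied before the dense encoder.
#' @param hidden hidden layer width; 0 selects a linear projection head,
#'   whose random initialisation is a near-isometry of the pooled pixel
#'   space (the stand-in for a pretrained backbone's already-informative
#'   features).
#' @param dim embedding dimension.
#' @param tau contrastive temperature (default 0.25).
#' @param margin hinge margin of the shift angular term (default 1).
#' @param steps number of SGD steps.
#' @param batch_size videos per minibatch; one patch is sampled per video per
#'   batch so near-duplicate frames of one video never meet as negatives.
#' @param lr,momentum,weight_decay SGD hyperparameters.
#' @param warmup_steps linear learning-rate warmup from 0 over this many
#'   steps (0 disables).
#' @param clip_norm clip the global gradient norm to this value
#'   (`Inf` disables).
#' @param standardize center and scale the pooled pixel features by their
#'   training-set statistics (computed once at initialisation and stored with
#'   the model). Off by default: equalising per-feature variance amplifies
#'   pixel noise relative to the low-dimensional color signal that carries
#'   the diagnostic information.
#' @param crop_scale minimum retained axis fraction in view augmentation.
#' @param objective training objective: `"final"` (mean-shifted contrastive +
#'   shift angular), `"msc"` (mean-shifted contrastive + angular, no shifted
#'   samples), `"angular"`, or `"shift_angular"`.
#' @param center_recompute_per_epoch recompute the center from current
#'   embeddings every epoch instead of holding the initial center fixed.
#' @param seed integer seed for weight init and batch sampling.
#' @return a list of class `scad_embedder_config`.
#' @export
embedder_config <- function(patch_size = 32L, pool = 2L, hidden = 64L,
                            dim = 16L, tau = 0.25, margin = 1,
                            steps = 250L, batch_size = 60L, lr = 0.1,
                            momentum = 0.9, weight_decay = 1e-5,
                            warmup_steps = 0L, clip_norm = Inf,
                            standardize = FALSE,
                            crop_scale = 0.7,
                            objective = c("final", "msc", "angular",
                                          "shift_angular"),
                            center_recompute_per_epoch = FALSE,
                            seed = 1L) {
  if (tau <= 0) stop_spec("`tau` must be positive")
  structure(list(patch_size = as.integer(patch_size), pool = as.integer(pool),
                 hidden = as.integer(hidden), dim = as.integer(dim),
                 tau = tau, margin = margin, steps = as.integer(steps),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 warmup_steps = as.integer(warmup_steps),
                 clip_norm = clip_norm,
                 standardize = isTRUE(standardize),
                 crop_scale = crop_scale,
                 objective = match.arg(objective),
                 center_recompute_per_epoch = isTRUE(center_recompute_per_epoch),
                 seed = as.integer(seed)),
            class = "scad_embedder_config")
}

embedder_feature_dim <- function(config) {
  3L * (config$patch_size %/% config$pool)^2
}

embedder_init <- function(config) {
  p <- embedder_feature_dim(config)
  if (config$hidden == 0L) {
    # linear projection head: keeps the pixel-space geometry at
    # initialisation (random near-isometry) and lets the objective reshape it
    list(enc2 = nn_dense_init(p, config$dim, scale = sqrt(1 / p)))
  } else {
    list(enc1 = nn_dense_init(p, config$hidden),
         enc2 = nn_dense_init(config$hidden, config$dim,
                              scale = sqrt(1 / config$hidden)))
  }
}

embedder_featurize <- function(patches, config) {
  t(vapply(patches, function(img) {
    if (!all(dim(img)[1:2] == config$patch_size)) {
      img <- resize_bilinear(img, config$patch_size, config$patch_size)
    }
    flatten_features(img, config$pool)
  }, numeric(embedder_feature_dim(config))))
}

# Forward pass to the unit sphere; keeps intermediates for backprop.
embedder_forward <- function(params, X) {
  H <- if (is.null(params$enc1)) X else {
    relu(sweep(X %*% params$enc1$W, 2, params$enc1$b, "+"))
  }
  U <- sweep(H %*% params$enc2$W, 2, params$enc2$b, "+")
  r <- sqrt(rowSums(U^2))
  if (any(r < NORM_EPS)) stop_degenerate("encoder produced a (near-)zero embedding")
  list(H = H, U = U, r = r, phi = U / r)
}

# Chain a gradient w.r.t. phi back to parameter gradients.
embedder_backprop <- function(params, X, fw, grad_phi) {
  dU <- (grad_phi - rowSums(grad_phi * fw$phi) * fw$phi) / fw$r
  out <- list(enc2 = list(W = t(fw$H) %*% dU, b = colSums(dU)))
  if (!is.null(params$enc1)) {
    dH <- dU %*% t(params$enc2$W)
    dH[fw$H <= 0] <- 0
    out$enc1 <- list(W = t(X) %*% dH, b = colSums(dH))
  }
  out
}

#' Embed patches with a trained embedder
#'
#' @param embedder a trained `scad_embedder`.
#' @param patches list of patch image arrays.
#' @return matrix of unit-norm embeddings, one row per patch.
#' @export
embed_patches <- function(embedder, patches) {
  X <- embedder_featurize(patches, embedder$config)
  X <- apply_standardizer(X, embedder$standardizer)
  embedder_forward(embedder$params, X)$phi
}

# Feature standardization, fitted once on the training patches.
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- pmax(apply(X, 2, stats::sd), 1e-6)
  list(mean = mu, sd = sd)
}

apply_standardizer <- function(X, std) {
  if (is.null(std)) return(X)
  sweep(sweep(X, 2, std$mean), 2, std$sd, "/")
}

# Ground-truth-box patches of every annotated frame, grouped by video.
training_patches <- function(videos, patch_size) {
  lapply(videos, function(v) {
    keep <- Filter(function(f) isTRUE(f$has_eardrum), v$frames)
    lapply(keep, function(f) extract_patch(f$image, f$box, patch_size))
  })
}

#' Train the shift-contrastive embedder
#'
#' Each step samples `batch_size` training videos and one eardrum patch per
#' video. Every patch contributes two benign augmented views; under the
#' `"final"` and `"shift_angular"` objectives a shift-transformed copy of the
#' patch contributes two further views, so a batch of N videos holds 4N
#' instances. The center is computed from the initial encoder over all
#' training patches and held fixed unless `center_recompute_per_epoch` is set.
#'
#' @param patch_sets list (one element per video) of lists of patch arrays,
#'   e.g. from ground-truth boxes; or a list of video records, from which
#'   ground-truth patches are extracted.
#' @param config an [embedder_config()].
#' @param shift a [shift_spec()] defining the distributional shift.
#' @return an object of class `scad_embedder`: `params`, `center`, `config`,
#'   `shift`, `loss_history`.
#' @export
train_embedder <- function(patch_sets, config = embedder_config(),
                           shift = shift_spec("cj-wf")) {
  if (length(patch_sets) && inherits(patch_sets[[1]], "scad_video")) {
    patch_sets <- training_patches(patch_sets, config$patch_size)
  }
  patch_sets <- Filter(length, patch_sets)
  if (length(patch_sets) < 2L) stop_spec("need patches from at least 2 videos")
  if (config$batch_size > length(patch_sets)) {
    warning(sprintf("batch size %d exceeds %d available videos; clamping",
                    config$batch_size, length(patch_sets)))
    config$batch_size <- length(patch_sets)
  }
  use_shift <- config$objective %in% c("final", "shift_angular")

  with_seed(config$seed, {
    params <- embedder_init(config)
    all_patches <- unlist(patch_sets, recursive = FALSE)
    X_all <- embedder_featurize(all_patches, config)
    std <- if (config$standardize) fit_standardizer(X_all) else NULL
    X_all <- apply_standardizer(X_all, std)
    center <- compute_center(embedder_forward(params, X_all)$phi)

    state <- rapply(params, function(p) p * 0, how = "replace")
    losses <- numeric(config$steps)
    n_vid <- length(patch_sets)
    steps_per_epoch <- max(1L, n_vid %/% config$batch_size)

    for (step in seq_len(config$steps)) {
      vids <- sample.int(n_vid, config$batch_size)
      views <- list()
      shifted <- logical(0)
      for (vi in vids) {
        pk <- patch_sets[[vi]]
        patch <- pk[[sample.int(length(pk), 1)]]
        pair <- positive_pair_augment(patch, config$crop_scale)
        views <- c(views, pair)
        shifted <- c(shifted, FALSE, FALSE)
        if (use_shift) {
          z <- apply_shift(patch, shift)
          zpair <- positive_pair_augment(z, config$crop_scale)
          views <- c(views, zpair)
          shifted <- c(shifted, TRUE, TRUE)
        }
      }
      m <- length(views)
      pairs <- as.integer(seq_len(m) + c(1L, -1L))  # (1,2),(3,4),...
      X <- apply_standardizer(embedder_featurize(views, config), std)
      fw <- embedder_forward(params, X)
      lg <- loss_grad_objective(fw$phi, pairs, shifted, center,
                                config$tau, config$margin, config$objective)
      losses[step] <- lg$value
      grads <- embedder_backprop(params, X, fw, lg$grad)
      gnorm <- sqrt(sum(unlist(grads)^2))
      if (is.finite(config$clip_norm) && gnorm > config$clip_norm) {
        grads <- rapply(grads, function(g) g * config$clip_norm / gnorm,
                        how = "replace")
      }
      lr_t <- config$lr *
        min(1, step / max(1L, config$warmup_steps))
      for (part in names(params)) {
        upd <- sgd_step(params[[part]], grads[[part]], state[[part]],
                        lr_t, config$momentum, config$weight_decay)
        params[[part]] <- upd$params
        state[[part]] <- upd$state
      }
      if (config$center_recompute_per_epoch && step %% steps_per_epoch == 0L) {
        center <- compute_center(embedder_forward(params, X_all)$phi)
      }
    }
    structure(list(params = params, center = center, config = config,
                   shift = shift, standardizer = std, loss_history = losses),
              class = "scad_embedder")
  })
}
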