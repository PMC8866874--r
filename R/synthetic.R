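# Synthetic otoscopy-like video generator. Frames show a shaded elliptical
# "eardrum" on a darker textured canal background; abnormal videos recolor the
# whole membrane or a sector of it. The generator stands in for restricted
# clinical footage and reproduces its statistical structure: normal-only
# training split, skewed class balance, per-frame boxes annotated only when
# the membrane spans at least 20% of the frame in both width and height.

#' Scene specification for the synthetic otoscopy generator
#'
#' Describes how individual frames are rendered: frame geometry, eardrum size
#' and appearance, anomaly model, and nuisance parameters (center drift and
#' pixel noise).
#'
#' @param frame_size integer `c(H, W)` in pixels.
#' @param eardrum_axes_range range of the ellipse diameter per axis, as a
#'   fraction of the corresponding frame dimension. Both axes are drawn
#'   independently and uniformly from this range.
#' @param eardrum_presence_prob probability that a frame shows the eardrum.
#' @param normal_color list with `mean` (RGB in \[0,1\]) and `sd` (per-channel
#'   standard deviation of the per-video membrane base color).
#' @param anomaly_magnitude strength of the abnormal color shift in \[0,1\];
#'   0 renders abnormal frames identical to normal ones.
#' @param anomaly_extent list with `kind` (subset of `"whole"`, `"partial"`;
#'   sampled uniformly per video) and `partial_fraction_range`, the fraction of
#'   the membrane area covered by a partial (sector) lesion.
#' @param frames_per_video_range integer range of frames per video.
#' @param jitter_px per-frame drift of the eardrum center, in pixels.
#' @param noise_std standard deviation of additive Gaussian pixel noise.
#' @return an object of class `scad_scene`.
#' @examples
#' sc <- scene_spec(frame_size = c(64, 64))
#' fr <- generate_frame(sc, seed = 1)
#' str(fr$box)
#' @export
scene_spec <- function(frame_size = c(64L, 64L),
                       eardrum_axes_range = c(0.35, 0.65),
                       eardrum_presence_prob = 0.85,
                       normal_color = list(mean = c(0.80, 0.62, 0.50),
                                           sd = c(0.05, 0.05, 0.05)),
                       anomaly_magnitude = 0.35,
                       anomaly_extent = list(kind = c("whole", "partial"),
                                             partial_fraction_range = c(0.2, 0.6)),
                       frames_per_video_range = c(5L, 15L),
                       jitter_px = 2,
                       noise_std = 0.02) {
  spec <- list(
    frame_size = as.integer(frame_size),
    eardrum_axes_range = as.numeric(eardrum_axes_range),
    eardrum_presence_prob = eardrum_presence_prob,
    normal_color = normal_color,
    anomaly_magnitude = anomaly_magnitude,
    anomaly_extent = anomaly_extent,
    frames_per_video_range = as.integer(frames_per_video_range),
    jitter_px = jitter_px,
    noise_std = noise_std
  )
  class(spec) <- "scad_scene"
  validate_scene(spec)
}

validate_scene <- function(scene) {
  if (!inherits(scene, "scad_scene")) stop_spec("not a scene_spec object")
  fs <- scene$frame_size
  if (length(fs) != 2L || any(fs < 8L)) stop_spec("frame_size must be two integers >= 8")
  ar <- scene$eardrum_axes_range
  if (length(ar) != 2L || ar[1] > ar[2] || ar[1] <= 0 || ar[2] >= 1) {
    stop_spec("eardrum_axes_range must lie within (0, 1) with lower <= upper")
  }
  p <- scene$eardrum_presence_prob
  if (!is.numeric(p) || p < 0 || p > 1) stop_spec("eardrum_presence_prob must be in [0, 1]")
  if (scene$anomaly_magnitude < 0 || scene$anomaly_magnitude > 1) {
    stop_spec("anomaly_magnitude must be in [0, 1]")
  }
  kinds <- scene$anomaly_extent$kind
  if (!length(kinds) || !all(kinds %in% c("whole", "partial"))) {
    stop_spec("anomaly_extent$kind must be a subset of {'whole', 'partial'}")
  }
  pfr <- scene$anomaly_extent$partial_fraction_range
  if (length(pfr) != 2L || pfr[1] > pfr[2] || pfr[1] <= 0 || pfr[2] > 1) {
    stop_spec("partial_fraction_range must lie within (0, 1]")
  }
  fr <- scene$frames_per_video_range
  if (length(fr) != 2L || any(fr < 1L) || fr[1] > fr[2]) {
    stop_spec("frames_per_video_range must be a positive non-empty integer range")
  }
  if (scene$jitter_px < 0) stop_spec("jitter_px must be >= 0")
  if (scene$noise_std < 0) stop_spec("noise_std must be >= 0")
  nc <- scene$normal_color
  if (length(nc$mean) != 3L || length(nc$sd) != 3L || any(nc$sd < 0)) {
    stop_spec("normal_color must supply 3 channel means and non-negative sds")
  }
  scene
}

#' Dataset specification: split/class counts and the global seed
#'
#' The training split holds normal videos only; validation and test splits mix
#' normal and abnormal videos. Defaults reproduce the skewed clinical balance
#' of 60 training normals, 10 + 10 validation and test normals, and 10 + 10
#' validation and test abnormals.
#'
#' @param n_train_normal,n_val_normal,n_val_abnormal,n_test_normal,n_test_abnormal
#'   non-negative video counts per split and class.
#' @param seed integer seed driving independent per-video substreams.
#' @return an object of class `scad_dataset_spec`.
#' @export
dataset_spec <- function(n_train_normal = 60L, n_val_normal = 10L,
                         n_val_abnormal = 10L, n_test_normal = 10L,
                         n_test_abnormal = 10L, seed = 1L) {
  counts <- c(n_train_normal, n_val_normal, n_val_abnormal,
              n_test_normal, n_test_abnormal)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_spec("all split counts must be non-negative integers")
  }
  spec <- list(n_train_normal = as.integer(n_train_normal),
               n_val_normal = as.integer(n_val_normal),
               n_val_abnormal = as.integer(n_val_abnormal),
               n_test_normal = as.integer(n_test_normal),
               n_test_abnormal = as.integer(n_test_abnormal),
               seed = as.integer(seed))
  class(spec) <- "scad_dataset_spec"
  spec
}

# Minimum box extent (fraction of frame dimension) for a frame to carry an
# eardrum annotation, matching the clinical annotation rule.
ANNOTATION_MIN_EXTENT <- 0.2

# Direction of the abnormal color shift: erythema-like reddening.
ANOMALY_COLOR_DIRECTION <- c(0.60, -0.25, -0.25)

new_frame_record <- function(image, has_eardrum, box) {
  structure(list(image = image, has_eardrum = has_eardrum, box = box),
            class = "scad_frame")
}

# Draw the per-video (or standalone per-frame) appearance parameters:
# membrane size and base color are stable within a video, as is the lesion.
# Always consumes the same RNG draws regardless of the video label so that
# normal/abnormal twins generated from one seed differ only by the shift.
draw_appearance <- function(scene) {
  axes <- stats::runif(2, scene$eardrum_axes_range[1], scene$eardrum_axes_range[2])
  base_color <- clip01(stats::rnorm(3, scene$normal_color$mean, scene$normal_color$sd))
  kind <- scene$anomaly_extent$kind[
    1L + floor(stats::runif(1) * length(scene$anomaly_extent$kind))]
  pfr <- scene$anomaly_extent$partial_fraction_range
  frac <- stats::runif(1, pfr[1], pfr[2])
  angle0 <- stats::runif(1, 0, 2 * pi)
  list(axes = axes, base_color = base_color,
       anomaly = list(kind = kind, fraction = frac, angle0 = angle0))
}

# Render one frame. RNG draw order is fixed and independent of is_abnormal:
# presence, texture field, pixel noise.
render_frame <- function(scene, is_abnormal, center, appearance) {
  H <- scene$frame_size[1]
  W <- scene$frame_size[2]
  present <- stats::runif(1) < scene$eardrum_presence_prob
  axes <- appearance$axes
  texture <- gaussian_blur(matrix(stats::rnorm(H * W), H, W), sigma = W / 12)
  texture <- texture / max(1e-8, stats::sd(as.vector(texture))) * 0.04
  noise <- array(stats::rnorm(H * W * 3, sd = scene$noise_std), c(H, W, 3))

  bg <- c(0.20, 0.13, 0.10)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch] * (1 + texture)

  box <- NULL
  has <- FALSE
  if (present) {
    sax <- axes[1] / 2  # semi-axis, fraction of width (x) ...
    say <- axes[2] / 2  # ... and of height (y)
    xs <- (seq_len(W) - 0.5) / W
    ys <- (seq_len(H) - 0.5) / H
    u <- outer(rep(1, H), (xs - center[1]) / sax)
    v <- outer((ys - center[2]) / say, rep(1, W))
    r2 <- u^2 + v^2
    inside <- r2 <= 1
    if (any(inside)) {
      shading <- 1 - 0.35 * r2
      col <- appearance$base_color
      region <- inside
      if (is_abnormal && scene$anomaly_magnitude > 0) {
        an <- appearance$anomaly
        if (an$kind == "partial") {
          ang <- (atan2(v, u) - an$angle0) %% (2 * pi)
          region <- inside & ang <= an$fraction * 2 * pi
        }
        delta <- scene$anomaly_magnitude * ANOMALY_COLOR_DIRECTION
      } else {
        delta <- c(0, 0, 0)
        region <- inside & FALSE
      }
      for (ch in 1:3) {
        layer <- img[, , ch]
        layer[inside] <- col[ch] * shading[inside]
        layer[region] <- layer[region] + delta[ch]
        img[, , ch] <- layer
      }
    }
    # Tight analytic box of the ellipse, clipped to the frame.
    bx <- c(max(0, center[1] - sax), min(1, center[1] + sax))
    by <- c(max(0, center[2] - say), min(1, center[2] + say))
    extent_ok <- (bx[2] - bx[1]) >= ANNOTATION_MIN_EXTENT &&
      (by[2] - by[1]) >= ANNOTATION_MIN_EXTENT
    if (extent_ok && bx[2] > bx[1] && by[2] > by[1]) {
      has <- TRUE
      box <- bounding_box(bx[1], by[1], bx[2], by[2])
    }
  }
  img <- clip01(img + noise)
  img <- round(img * 255) / 255  # 8-bit levels: lossless PNG round-trip
  new_frame_record(img, has, box)
}

#' Generate a single synthetic frame
#'
#' Draws the eardrum presence, size, appearance and noise from the current (or
#' supplied) RNG stream and renders the frame. The annotation rule follows the
#' clinical protocol: the frame is labeled eardrum-present, with a tight
#' bounding box, only when the membrane's extent reaches at least 20% of the
#' frame in both width and height.
#'
#' @param scene a [scene_spec()].
#' @param is_abnormal apply the abnormal color shift inside the membrane.
#' @param seed optional integer seed (restores the caller's RNG afterwards).
#' @return a frame record: `image` (H x W x 3 array in \[0,1\]),
#'   `has_eardrum` flag, and `box` (a [bounding_box()] or `NULL`).
#' @export
generate_frame <- function(scene, is_abnormal = FALSE, seed = NULL) {
  validate_scene(scene)
  with_seed(seed, {
    center <- stats::runif(2, 0.35, 0.65)
    appearance <- draw_appearance(scene)
    render_frame(scene, is_abnormal, center, appearance)
  })
}

new_video_record <- function(video_id, frames, label, split) {
  structure(list(video_id = video_id, frames = frames,
                 label = label, split = split),
            class = "scad_video")
}

#' Generate one synthetic video
#'
#' Frame count is drawn from `frames_per_video_range`; the eardrum center
#' performs a bounded random walk of `jitter_px` pixels per frame; abnormal
#' videos apply one fixed lesion (whole membrane or a sector) to every frame in
#' which the membrane is drawn. Every video is guaranteed at least one
#' annotated eardrum frame, mirroring the clinical inclusion rule that a video
#' with no usable membrane view would not enter the dataset.
#'
#' @param scene a [scene_spec()].
#' @param label `"normal"` or `"abnormal"`.
#' @param seed optional integer seed.
#' @param video_id identifier string.
#' @param split split tag (`"train"`, `"val"` or `"test"`).
#' @return a video record (class `scad_video`).
#' @export
generate_video <- function(scene, label = c("normal", "abnormal"), seed = NULL,
                           video_id = "video_000", split = "test") {
  validate_scene(scene)
  label <- match.arg(label)
  if (split == "train" && label != "normal") {
    stop_spec("the training split contains normal videos only")
  }
  with_seed(seed, {
    fr <- scene$frames_per_video_range
    n_frames <- if (fr[1] == fr[2]) fr[1] else sample(fr[1]:fr[2], 1)
    appearance <- draw_appearance(scene)
    is_abn <- label == "abnormal"
    for (attempt in 1:20) {
      center <- stats::runif(2, 0.35, 0.65)
      frames <- vector("list", n_frames)
      for (t in seq_len(n_frames)) {
        if (t > 1) {
          drift <- stats::runif(2, -scene$jitter_px, scene$jitter_px) /
            rev(scene$frame_size)  # px -> fraction of (W, H)
          center <- pmin(pmax(center + drift, 0.2), 0.8)
        }
        frames[[t]] <- render_frame(scene, is_abn, center, appearance)
      }
      if (any(vapply(frames, function(f) f$has_eardrum, logical(1)))) break
    }
    if (!any(vapply(frames, function(f) f$has_eardrum, logical(1)))) {
      # Force a full-size membrane in the first frame (vanishingly rare).
      forced <- scene
      forced$eardrum_presence_prob <- 1
      app_forced <- appearance
      app_forced$axes <- rep(scene$eardrum_axes_range[2], 2)
      frames[[1]] <- render_frame(forced, is_abn, c(0.5, 0.5), app_forced)
    }
    new_video_record(video_id, frames, label, split)
  })
}

#' Generate a split-keyed synthetic dataset
#'
#' Each video is rendered from an independent substream derived from
#' `dspec$seed`, so the dataset is bit-reproducible and individual videos can
#' be regenerated in isolation.
#'
#' @param dspec a [dataset_spec()].
#' @param scene a [scene_spec()].
#' @return a list with elements `train`, `val`, `test`, each a list of video
#'   records; class `scad_dataset`.
#' @examples
#' ds <- generate_dataset(dataset_spec(n_train_normal = 2, n_val_normal = 1,
#'                                     n_val_abnormal = 1, n_test_normal = 1,
#'                                     n_test_abnormal = 1, seed = 7),
#'                        scene_spec())
#' lengths(ds)
#' @export
generate_dataset <- function(dspec, scene) {
  if (!inherits(dspec, "scad_dataset_spec")) stop_spec("`dspec` must be a dataset_spec()")
  validate_scene(scene)
  plan <- list(
    list(split = "train", label = "normal",   n = dspec$n_train_normal),
    list(split = "val",   label = "normal",   n = dspec$n_val_normal),
    list(split = "val",   label = "abnormal", n = dspec$n_val_abnormal),
    list(split = "test",  label = "normal",   n = dspec$n_test_normal),
    list(split = "test",  label = "abnormal", n = dspec$n_test_abnormal)
  )
  out <- list(train = list(), val = list(), test = list())
  counter <- 0L
  for (grp in plan) {
    for (i in seq_len(grp$n)) {
      counter <- counter + 1L
      vid <- sprintf("%s_%s_%03d", grp$split, grp$label, i)
      v <- generate_video(scene, grp$label, seed = derive_seed(dspec$seed, counter),
                          video_id = vid, split = grp$split)
      out[[grp$split]][[length(out[[grp$split]]) + 1L]] <- v
    }
  }
  structure(out, class = "scad_dataset", dataset_spec = dspec, scene_spec = scene)
}

#' @export
print.scad_dataset <- function(x, ...) {
  n <- vapply(x, length, integer(1))
  cat(sprintf("synthetic otoscopy dataset: %d train / %d val / %d test videos\n",
              n[["train"]], n[["val"]], n[["test"]]))
  invisible(x)
}

# Flat list of all videos in a dataset.
all_videos <- function(dataset) {
  c(dataset$train, dataset$val, dataset$test)
}
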