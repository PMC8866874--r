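# Augmentations. Two families: (i) the benign positive-pair augmentation
# (random resized crop + horizontal flip) used to build contrastive views,
# which deliberately leaves color untouched because color is the diagnostic
# cue; (ii) the three distributional shift transformations that color-jitter
# the whole patch (cj-wf), a random rectangle (cj-rc), or smoothly-weighted
# random regions (cj-rr) to manufacture off-distribution negatives.

#' Shift transformation specification
#'
#' @param kind `"cj-wf"` (whole frame), `"cj-rc"` (random rectangle) or
#'   `"cj-rr"` (random region).
#' @param jitter_params list of half-ranges for `brightness`, `contrast`,
#'   `saturation` (multiplicative factors drawn from `1 +/- range`) and `hue`
#'   (additive shift of the hue angle, in turns). Defaults are
#'   chroma-weighted: hue and saturation carry the bulk of the perturbation
#'   while brightness and contrast stay mild, so shifted samples emulate the
#'   pathology-like chromatic deviations of an inflamed membrane rather than
#'   benign illumination changes (which an anomaly detector must tolerate,
#'   not flag).
#' @param rc_area_range rectangle area as a fraction of the patch (cj-rc).
#' @param rc_aspect_range rectangle aspect ratio range (cj-rc).
#' @param rr_n_points_range integer range of seed points (cj-rr).
#' @param rr_sigma_frac Gaussian smoothing sigma as a fraction of the patch
#'   side (cj-rr).
#' @return an object of class `scad_shift_spec`.
#' @export
shift_spec <- function(kind = c("cj-wf", "cj-rc", "cj-rr"),
                       jitter_params = list(brightness = 0.1, contrast = 0.1,
                                            saturation = 0.4, hue = 0.15),
                       rc_area_range = c(0.1, 0.5),
                       rc_aspect_range = c(1 / 3, 3),
                       rr_n_points_range = c(1L, 5L),
                       rr_sigma_frac = 0.1) {
  kind <- match.arg(kind)
  jp <- jitter_params
  for (f in c("brightness", "contrast", "saturation", "hue")) {
    if (is.null(jp[[f]]) || jp[[f]] < 0) stop_spec(sprintf("jitter '%s' must be >= 0", f))
  }
  if (rc_area_range[1] <= 0 || rc_area_range[2] > 1 || rc_area_range[1] > rc_area_range[2]) {
    stop_spec("rc_area_range must lie within (0, 1]")
  }
  if (any(rr_n_points_range < 1L) || rr_n_points_range[1] > rr_n_points_range[2]) {
    stop_spec("rr_n_points_range must be a positive integer range")
  }
  if (rr_sigma_frac <= 0) stop_spec("rr_sigma_frac must be > 0")
  structure(list(kind = kind, jitter_params = jp,
                 rc_area_range = as.numeric(rc_area_range),
                 rc_aspect_range = as.numeric(rc_aspect_range),
                 rr_n_points_range = as.integer(rr_n_points_range),
                 rr_sigma_frac = rr_sigma_frac),
            class = "scad_shift_spec")
}

#' Color jitter
#'
#' Perturbs brightness, contrast, saturation and hue, each by a factor (or
#' hue shift) drawn uniformly from the configured range, applied in random
#' order with clipping to \[0,1\] after each step. Contrast and saturation
#' blend toward the mean luma and the per-pixel luma respectively; hue rotates
#' in HSV space with wraparound.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param jitter_params see [shift_spec()]; half-ranges per component.
#' @param seed optional integer seed.
#' @return jittered image, same shape, values in \[0,1\].
#' @export
color_jitter <- function(image, jitter_params = shift_spec()$jitter_params,
                         seed = NULL) {
  check_image(image)
  with_seed(seed, {
    jp <- jitter_params
    b <- stats::runif(1, max(0, 1 - jp$brightness), 1 + jp$brightness)
    co <- stats::runif(1, max(0, 1 - jp$contrast), 1 + jp$contrast)
    sa <- stats::runif(1, max(0, 1 - jp$saturation), 1 + jp$saturation)
    hu <- stats::runif(1, -jp$hue, jp$hue)
    order4 <- sample.int(4)
    for (op in order4) {
      image <- switch(op,
        clip01(image * b),
        { g <- mean(luminance(image)); clip01((image - g) * co + g) },
        { L <- luminance(image)
          out <- image
          for (ch in 1:3) out[, , ch] <- L + (image[, , ch] - L) * sa
          clip01(out) },
        if (hu != 0) {
          hsv <- rgb_to_hsv_image(image)
          hsv[, , 1] <- (hsv[, , 1] + hu) %% 1
          clip01(hsv_to_rgb_image(hsv))
        } else image
      )
    }
    image
  })
}

#' Build the per-pixel weight mask for a shift transformation
#'
#' `cj-wf` yields an all-ones mask; `cj-rc` a binary mask that is one inside a
#' single random rectangle (area and aspect ratio drawn from the spec);
#' `cj-rr` starts from a zero map, sets a random number of random pixels to
#' one, smooths with a Gaussian filter and rescales so the maximum is one.
#'
#' @param kind transformation kind (`"cj-wf"`, `"cj-rc"`, `"cj-rr"`).
#' @param shape integer `c(H, W)`.
#' @param spec a [shift_spec()].
#' @param seed optional integer seed.
#' @return H x W matrix of weights in \[0,1\].
#' @export
make_mask <- function(kind, shape, spec = shift_spec(kind), seed = NULL) {
  if (!kind %in% c("cj-wf", "cj-rc", "cj-rr")) {
    stop_spec(sprintf("unknown shift kind '%s'", kind))
  }
  H <- shape[1]
  W <- shape[2]
  with_seed(seed, switch(kind,
    "cj-wf" = matrix(1, H, W),
    "cj-rc" = {
      area <- stats::runif(1, spec$rc_area_range[1], spec$rc_area_range[2])
      aspect <- exp(stats::runif(1, log(spec$rc_aspect_range[1]),
                                 log(spec$rc_aspect_range[2])))
      # target pixel extents: w/h = aspect, w*h = area * H * W
      w <- sqrt(area * H * W * aspect)
      h <- sqrt(area * H * W / aspect)
      w <- max(1L, min(W, as.integer(round(w))))
      h <- max(1L, min(H, as.integer(round(h))))
      y0 <- sample.int(H - h + 1L, 1)
      x0 <- sample.int(W - w + 1L, 1)
      m <- matrix(0, H, W)
      m[y0:(y0 + h - 1L), x0:(x0 + w - 1L)] <- 1
      m
    },
    "cj-rr" = {
      npr <- spec$rr_n_points_range
      n_pts <- if (npr[1] == npr[2]) npr[1] else sample(npr[1]:npr[2], 1)
      m <- matrix(0, H, W)
      ys <- sample.int(H, n_pts, replace = TRUE)
      xs <- sample.int(W, n_pts, replace = TRUE)
      m[cbind(ys, xs)] <- 1
      sm <- gaussian_blur(m, sigma = spec$rr_sigma_frac * min(H, W))
      clip01(sm / max(sm))
    }
  ))
}

#' Apply a shift transformation
#'
#' Interpolates the color-jittered image with the original using the
#' transformation's pixel-wise weight mask:
#' `out = mask * jittered + (1 - mask) * original`.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param spec a [shift_spec()].
#' @param seed optional integer seed.
#' @return shifted image, same shape, values in \[0,1\].
#' @export
apply_shift <- function(image, spec = shift_spec(), seed = NULL) {
  check_image(image)
  with_seed(seed, {
    mask <- make_mask(spec$kind, dim(image)[1:2], spec)
    jit <- color_jitter(image, spec$jitter_params)
    out <- image
    for (ch in 1:3) {
      out[, , ch] <- mask * jit[, , ch] + (1 - mask) * image[, , ch]
    }
    clip01(out)
  })
}

#' Two augmented views of one patch (positive pair)
#'
#' Each view is an independent random resized crop (retaining
#' `crop_scale` to 100% of the patch per axis) followed by a random
#' horizontal flip. Color is never altered here.
#'
#' @param image H x W x 3 array.
#' @param crop_scale minimum retained fraction of each axis (default 0.7).
#' @param augment set `FALSE` to return two identical copies.
#' @param seed optional integer seed.
#' @return list of two images with the input shape.
#' @export
positive_pair_augment <- function(image, crop_scale = 0.7, augment = TRUE,
                                  seed = NULL) {
  check_image(image)
  if (!augment) return(list(image, image))
  with_seed(seed, list(random_view(image, crop_scale),
                       random_view(image, crop_scale)))
}

random_view <- function(image, crop_scale = 0.7) {
  d <- dim(image)
  sy <- stats::runif(1, crop_scale, 1)
  sx <- stats::runif(1, crop_scale, 1)
  y0 <- stats::runif(1, 0, 1 - sy)
  x0 <- stats::runif(1, 0, 1 - sx)
  out <- resize_bilinear(image, d[1], d[2],
                         y0 = y0, y1 = y0 + sy, x0 = x0, x1 = x0 + sx)
  if (stats::runif(1) < 0.5) out <- out[, rev(seq_len(d[2])), , drop = FALSE]
  out
}
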