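# Image primitives used across the pipeline. Images are plain H x W x 3
# arrays with channel values in [0, 1], row = y (down), column = x (right).

# Bilinear resampling matrix mapping n_in input pixel centers onto n_out
# output sample positions spread over the normalized window [lo, hi].
# Sample j sits at lo + (j - 0.5) * (hi - lo) / n_out; positions are clamped
# to the input support so integer-aligned windows reproduce pixels exactly.
resample_matrix <- function(n_in, n_out, lo = 0, hi = 1) {
  pos <- lo + (seq_len(n_out) - 0.5) * (hi - lo) / n_out
  t <- pos * n_in - 0.5
  t <- pmin(pmax(t, 0), n_in - 1)
  i0 <- floor(t)
  w <- t - i0
  M <- matrix(0, n_out, n_in)
  idx0 <- cbind(seq_len(n_out), i0 + 1)
  idx1 <- cbind(seq_len(n_out), pmin(i0 + 2, n_in))
  M[idx0] <- M[idx0] + (1 - w)
  M[idx1] <- M[idx1] + w
  M
}

# Bilinear crop-and-resize of the normalized window [x0,x1] x [y0,y1].
resize_bilinear <- function(img, out_h, out_w, y0 = 0, y1 = 1, x0 = 0, x1 = 1) {
  d <- dim(img)
  Ry <- resample_matrix(d[1], out_h, y0, y1)
  Rx <- resample_matrix(d[2], out_w, x0, x1)
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Ry %*% img[, , ch] %*% t(Rx)
  out
}

# Non-overlapping f x f block means; used to featurize frames/patches for the
# fully-connected backbones (averaging avoids the aliasing a strided bilinear
# downsample would introduce).
mean_pool <- function(img, f) {
  d <- dim(img)
  if (d[1] %% f != 0 || d[2] %% f != 0) {
    stop_spec("mean_pool: image dimensions must be divisible by the pooling factor")
  }
  h2 <- d[1] %/% f
  w2 <- d[2] %/% f
  out <- array(0, c(h2, w2, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    m <- colMeans(array(m, c(f, h2 * d[2])))      # pool rows
    m <- matrix(m, h2, d[2])
    m <- colMeans(array(t(m), c(f, w2 * h2)))     # pool columns
    out[, , ch] <- t(matrix(m, w2, h2))
  }
  out
}

# 1D Gaussian convolution operator with zero padding (no edge renormalization).
gauss_conv_matrix <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    ij <- cbind(i[ok], j[ok])
    M[ij] <- M[ij] + k[o + r + 1]
  }
  M
}

# Separable Gaussian smoothing of a matrix (zero padding at the borders).
gaussian_blur <- function(m, sigma) {
  if (!is.matrix(m)) stop_spec("gaussian_blur expects a matrix")
  if (!is.numeric(sigma) || sigma <= 0) stop_spec("`sigma` must be positive")
  Gy <- gauss_conv_matrix(nrow(m), sigma)
  Gx <- gauss_conv_matrix(ncol(m), sigma)
  Gy %*% m %*% t(Gx)
}

# RGB <-> HSV, vectorized over whole images. Hue in [0, 1).
rgb_to_hsv_image <- function(img) {
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  out <- array(0, d)
  out[, , 1] <- hsv[1, ]
  out[, , 2] <- hsv[2, ]
  out[, , 3] <- hsv[3, ]
  out
}

hsv_to_rgb_image <- function(img) {
  d <- dim(img)
  n <- d[1] * d[2]
  h <- as.vector(img[, , 1]) %% 1
  s <- as.vector(img[, , 2])
  v <- as.vector(img[, , 3])
  h6 <- h * 6
  i <- as.integer(h6) %% 6L          # sextant index 0..5
  f <- h6 - floor(h6)
  comp <- cbind(v, v * (1 - s), v * (1 - f * s), v * (1 - (1 - f) * s))
  # per-sextant column choices into (v, p, q, t)
  rsel <- c(1L, 3L, 2L, 2L, 4L, 1L)[i + 1L]
  gsel <- c(4L, 1L, 1L, 3L, 2L, 2L)[i + 1L]
  bsel <- c(2L, 2L, 4L, 1L, 1L, 3L)[i + 1L]
  rows <- seq_len(n)
  out <- array(0, d)
  out[, , 1] <- comp[cbind(rows, rsel)]
  out[, , 2] <- comp[cbind(rows, gsel)]
  out[, , 3] <- comp[cbind(rows, bsel)]
  out
}

# Rec. 601 luma, used by contrast/saturation jitter and in tests.
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

flatten_features <- function(img, pool = 1L) {
  if (pool > 1L) img <- mean_pool(img, pool)
  as.vector(img)
}
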