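# Independent brute-force oracles. Deliberately naive (loops, rasterization,
# exhaustive enumeration); they never share code with the implementations
# they check.

# Contrastive loss for one anchor by explicit double loop.
oracle_contrastive <- function(embeds, anchor, positive, tau) {
  num <- exp(sum(embeds[anchor, ] * embeds[positive, ]) / tau)
  den <- 0
  for (m in seq_len(nrow(embeds))) {
    if (m != anchor) den <- den + exp(sum(embeds[anchor, ] * embeds[m, ]) / tau)
  }
  -log(num / den)
}

# Batch-mean mean-shifted contrastive loss via per-vector loops.
oracle_msc <- function(embeds, pairs, center, tau) {
  theta <- t(apply(embeds, 1, function(v) {
    u <- v - center
    u / sqrt(sum(u^2))
  }))
  mean(vapply(seq_len(nrow(embeds)), function(i) {
    oracle_contrastive(theta, i, pairs[i], tau)
  }, numeric(1)))
}

oracle_angular <- function(embeds, center) {
  -mean(apply(embeds, 1, function(v) sum(v * center)))
}

oracle_shift_angular <- function(x_embeds, z_embeds, center, margin = 1) {
  ax <- mean(apply(x_embeds, 1, function(v) -sum(v * center)))
  az <- mean(apply(z_embeds, 1, function(v) max(0, margin + sum(v * center))))
  ax + az
}

# IoU by counting pixels on an n x n raster of the unit square.
oracle_iou_raster <- function(a, b, n = 1000L) {
  xs <- (seq_len(n) - 0.5) / n
  ys <- (seq_len(n) - 0.5) / n
  in_box <- function(box) {
    outer(ys >= box[2] & ys <= box[4], xs >= box[1] & xs <= box[3], "&")
  }
  ia <- in_box(as.numeric(a))
  ib <- in_box(as.numeric(b))
  sum(ia & ib) / sum(ia | ib)
}

# kNN anomaly score by full sort of cosine similarities.
oracle_knn_score <- function(feat, bank_mat, k) {
  sims <- apply(bank_mat, 1, function(r) sum(r * feat))
  sims <- sort(sims, decreasing = TRUE)
  sum(1 - sims[seq_len(k)])
}

# AUROC by exhaustive pair counting with ties worth one half.
oracle_auroc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  100 * tot / (length(pos) * length(neg))
}

# Dense 2D Gaussian convolution with zero padding, direct quadruple loop
# (kept tiny by its callers).
oracle_gauss_blur <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k1 <- dnorm(seq(-r, r), sd = sigma)
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di
      jj <- j + dj
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m)) {
        acc <- acc + m[ii, jj] * k2[di + r + 1, dj + r + 1]
      }
    }
    out[i, j] <- acc
  }
  out
}

# Random unit row vectors.
runit <- function(n, d) {
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}
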