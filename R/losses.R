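# Training objective for the shift-contrastive embedder: contrastive loss on
# the unit sphere, its mean-shifted variant, the angular center loss, and the
# distributional-shift angular loss, together with the analytic gradients used
# by the trainer. Embeddings are row vectors of unit Euclidean norm.

NORM_EPS <- 1e-8

#' Scale a vector to the unit sphere
#'
#' @param v finite numeric vector.
#' @return `v / ||v||_2`.
#' @export
l2_normalize <- function(v) {
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
    stop_numeric("`v` must be finite numeric")
  }
  n <- sqrt(sum(v^2))
  if (n < NORM_EPS) stop_degenerate("cannot normalize a (near-)zero vector")
  v / n
}

# Row-wise l2 normalization of a matrix.
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n < NORM_EPS)) stop_degenerate("matrix contains (near-)zero rows")
  m / n
}

check_unit_rows <- function(m, what = "embeddings", tol = 1e-5) {
  n <- sqrt(rowSums(m^2))
  if (any(abs(n - 1) > tol)) {
    stop_spec(sprintf("`%s` must have unit-norm rows", what))
  }
  invisible(m)
}

#' Bundle embeddings with their positive-pair structure
#'
#' A contrastive batch holds the embedding matrix of all augmented views, the
#' pairing that maps each view to its positive partner (a fixed-point-free
#' involution), and a flag marking views of shift-transformed instances.
#'
#' @param embeddings M x d matrix of unit-norm rows.
#' @param pairs integer vector of length M; `pairs[i]` is the index of view
#'   `i`'s positive partner.
#' @param shifted logical vector of length M (default all `FALSE`).
#' @return an object of class `scad_batch`.
#' @export
contrastive_batch <- function(embeddings, pairs, shifted = NULL) {
  if (!is.matrix(embeddings)) stop_spec("`embeddings` must be a matrix")
  check_unit_rows(embeddings)
  m <- nrow(embeddings)
  pairs <- as.integer(pairs)
  if (length(pairs) != m || any(pairs < 1L) || any(pairs > m)) {
    stop_spec("`pairs` must index rows of `embeddings`")
  }
  if (any(pairs == seq_len(m)) || any(pairs[pairs] != seq_len(m))) {
    stop_spec("`pairs` must be an involution with no fixed points")
  }
  if (is.null(shifted)) shifted <- rep(FALSE, m)
  if (length(shifted) != m) stop_spec("`shifted` must have one flag per row")
  if (any(shifted != shifted[pairs])) {
    stop_spec("shifted flags must agree within positive pairs")
  }
  structure(list(embeddings = embeddings, pairs = pairs, shifted = shifted),
            class = "scad_batch")
}

batch_embeddings <- function(batch) {
  if (inherits(batch, "scad_batch")) batch$embeddings else batch
}

#' Contrastive loss for one positive pair
#'
#' `-log( exp(e_a . e_p / tau) / sum_{m != a} exp(e_a . e_m / tau) )`: the
#' anchor's similarity to its positive partner against its similarity to every
#' other view in the batch; the denominator excludes only the anchor itself.
#'
#' @param batch a [contrastive_batch()] or unit-row embedding matrix.
#' @param anchor,positive row indices of the anchor view and its partner.
#' @param tau positive temperature.
#' @return non-negative scalar.
#' @examples
#' e <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, -1))
#' contrastive_loss(e, 1, 2, tau = 0.25)
#' @export
contrastive_loss <- function(batch, anchor, positive, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop_spec("`tau` must be a positive scalar")
  }
  e <- batch_embeddings(batch)
  check_unit_rows(e)
  if (anchor == positive) stop_spec("anchor and positive must differ")
  sims <- as.numeric(e %*% e[anchor, ]) / tau
  others <- setdiff(seq_len(nrow(e)), anchor)
  # log-sum-exp for stability
  s <- sims[others]
  m <- max(s)
  (m + log(sum(exp(s - m)))) - sims[positive]
}

#' Mean-shifted embedding
#'
#' Re-centers a unit embedding by the training-set center and projects back to
#' the unit sphere: `(phi - c) / ||phi - c||`.
#'
#' @param x_embed unit-norm embedding vector.
#' @param c unit-norm center vector.
#' @return unit-norm vector.
#' @export
mean_shift <- function(x_embed, c) {
  v <- x_embed - c
  n <- sqrt(sum(v^2))
  if (n < NORM_EPS) stop_degenerate("embedding coincides with the center")
  v / n
}

mean_shift_rows <- function(embeds, c) {
  v <- sweep(embeds, 2, c)
  normalize_rows(v)
}

#' Mean-shifted contrastive loss over a batch
#'
#' Applies the contrastive loss in the mean-shifted embedding space, averaged
#' over all views as anchors. Shift-transformed views, when present in the
#' batch, participate as ordinary instances: they have their own positive
#' pairs and act as negatives to every other view.
#'
#' @param batch a [contrastive_batch()].
#' @param c unit-norm center of the training set.
#' @param tau positive temperature.
#' @return scalar loss.
#' @export
msc_loss <- function(batch, c, tau) {
  if (!inherits(batch, "scad_batch")) stop_spec("`batch` must be a contrastive_batch()")
  theta <- mean_shift_rows(batch$embeddings, c)
  msc_core(theta, batch$pairs, tau)$value
}

# Loss and gradient of the batch-mean contrastive objective on already
# mean-shifted (unit) embeddings theta. Vectorized softmax over the similarity
# matrix; the naive double-loop oracle for this lives in the test suite.
msc_core <- function(theta, pairs, tau, want_grad = FALSE) {
  m <- nrow(theta)
  S <- theta %*% t(theta) / tau
  diag(S) <- -Inf                      # anchor excluded from its denominator
  mx <- apply(S, 1, max)
  lse <- mx + log(rowSums(exp(S - mx)))
  pos <- S[cbind(seq_len(m), pairs)]
  value <- mean(lse - pos)
  if (!want_grad) return(list(value = value))
  P <- exp(S - lse)                    # row-softmax, zero on the diagonal
  G <- P
  G[cbind(seq_len(m), pairs)] <- G[cbind(seq_len(m), pairs)] - 1
  G <- G / m
  grad_theta <- (G + t(G)) %*% theta / tau
  list(value = value, grad_theta = grad_theta)
}

# Chain a gradient w.r.t. theta back to the unit embeddings phi.
backprop_mean_shift <- function(grad_theta, phi, c) {
  v <- sweep(phi, 2, c)
  r <- sqrt(rowSums(v^2))
  theta <- v / r
  (grad_theta - rowSums(grad_theta * theta) * theta) / r
}

#' Angular center loss
#'
#' Batch mean of `-phi(x) . c`: attracts normal embeddings toward the
#' training-set center direction. Bounded in \[-1, 1\].
#'
#' @param x_embeds matrix of unit-norm embeddings (rows), or a single vector.
#' @param c unit-norm center.
#' @return scalar in \[-1, 1\].
#' @export
angular_loss <- function(x_embeds, c) {
  if (!is.matrix(x_embeds)) x_embeds <- matrix(x_embeds, nrow = 1)
  check_unit_rows(x_embeds)
  -mean(x_embeds %*% c)
}

#' Distributional-shift angular loss
#'
#' Attracts normal embeddings toward the center and repels embeddings of
#' shift-transformed samples from it through a hinge on their cosine to the
#' center: batch mean of `-phi(x) . c + max(0, margin + phi(z) . c)`. The
#' hinge is zero only once a shifted sample reaches the center's antipode (at
#' `margin = 1`), so shifted views feel a constant outward pull until they
#' saturate. Bounded in \[-1, 3\] for `margin = 1`.
#'
#' @param x_embeds matrix of unit-norm embeddings of normal views.
#' @param z_embeds matrix of unit-norm embeddings of shift-transformed views.
#' @param c unit-norm center.
#' @param margin hinge margin (default 1).
#' @return scalar.
#' @export
shift_angular_loss <- function(x_embeds, z_embeds, c, margin = 1) {
  if (!is.matrix(x_embeds)) x_embeds <- matrix(x_embeds, nrow = 1)
  if (!is.matrix(z_embeds)) z_embeds <- matrix(z_embeds, nrow = 1)
  check_unit_rows(x_embeds, "x_embeds")
  check_unit_rows(z_embeds, "z_embeds")
  -mean(x_embeds %*% c) + mean(pmax(0, margin + z_embeds %*% c))
}

#' Full training objective: mean-shifted contrastive + shift angular
#'
#' The batch must carry shifted flags; the contrastive term runs over all
#' views (shifted views as additional instances), the angular terms split the
#' batch into normal and shifted views.
#'
#' @param batch a [contrastive_batch()] with at least one shifted and one
#'   normal view.
#' @param c unit-norm center.
#' @param tau positive temperature.
#' @param margin hinge margin of the shift angular term.
#' @return scalar loss.
#' @export
final_loss <- function(batch, c, tau, margin = 1) {
  if (!inherits(batch, "scad_batch")) stop_spec("`batch` must be a contrastive_batch()")
  if (!any(batch$shifted) || all(batch$shifted)) {
    stop_spec("final loss needs both normal and shifted views in the batch")
  }
  msc_loss(batch, c, tau) +
    shift_angular_loss(batch$embeddings[!batch$shifted, , drop = FALSE],
                       batch$embeddings[batch$shifted, , drop = FALSE],
                       c, margin)
}

#' Normalized center of a set of embeddings
#'
#' @param train_embeds matrix of unit-norm embeddings (rows).
#' @return unit-norm center vector.
#' @export
compute_center <- function(train_embeds) {
  if (!is.matrix(train_embeds)) train_embeds <- matrix(train_embeds, nrow = 1)
  if (nrow(train_embeds) == 0L) stop_spec("cannot compute the center of an empty set")
  check_unit_rows(train_embeds)
  mu <- colMeans(train_embeds)
  if (sqrt(sum(mu^2)) < NORM_EPS) {
    stop_degenerate("embedding mean is (near-)zero; center undefined")
  }
  l2_normalize(mu)
}

# ---------------------------------------------------------------------------
# Embedding-space loss values + gradients for the trainer. All return
# list(value, grad) with grad w.r.t. the unit embeddings phi (M x d). The
# trainer then chains through the normalization and network layers.

loss_grad_msc <- function(phi, pairs, c, tau) {
  theta <- mean_shift_rows(phi, c)
  core <- msc_core(theta, pairs, tau, want_grad = TRUE)
  list(value = core$value,
       grad = backprop_mean_shift(core$grad_theta, phi, c))
}

loss_grad_angular <- function(phi, c) {
  m <- nrow(phi)
  list(value = -mean(phi %*% c),
       grad = matrix(-c, m, length(c), byrow = TRUE) / m)
}

loss_grad_shift_angular <- function(phi, shifted, c, margin = 1) {
  x <- phi[!shifted, , drop = FALSE]
  z <- phi[shifted, , drop = FALSE]
  zc <- as.numeric(z %*% c)
  value <- -mean(x %*% c) + mean(pmax(0, margin + zc))
  grad <- matrix(0, nrow(phi), ncol(phi))
  grad[!shifted, ] <- matrix(-c, nrow(x), length(c), byrow = TRUE) / nrow(x)
  active <- (margin + zc) > 0
  gz <- matrix(0, nrow(z), ncol(phi))
  gz[active, ] <- matrix(c, sum(active), length(c), byrow = TRUE) / nrow(z)
  grad[shifted, ] <- gz
  list(value = value, grad = grad)
}

# Objective dispatch for the four ablation modes.
loss_grad_objective <- function(phi, pairs, shifted, c, tau, margin, mode) {
  switch(mode,
    final = {
      a <- loss_grad_msc(phi, pairs, c, tau)
      b <- loss_grad_shift_angular(phi, shifted, c, margin)
      list(value = a$value + b$value, grad = a$grad + b$grad)
    },
    msc = {
      a <- loss_grad_msc(phi, pairs, c, tau)
      b <- loss_grad_angular(phi, c)
      list(value = a$value + b$value, grad = a$grad + b$grad)
    },
    angular = loss_grad_angular(phi, c),
    shift_angular = loss_grad_shift_angular(phi, shifted, c, margin),
    stop_spec(sprintf("unknown training objective '%s'", mode))
  )
}
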