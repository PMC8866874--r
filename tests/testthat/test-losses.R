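# Training objective: closed forms, oracle agreement, bounds, gradients and
# the embedder training contracts.

test_that("l2_normalize, mean_shift and compute_center algebra", {
  expect_equal(l2_normalize(c(3, 4)), c(0.6, 0.8))
  u <- l2_normalize(rnorm(5))
  expect_equal(l2_normalize(u), u)
  expect_error(l2_normalize(c(0, 0)), class = "scad_degenerate_error")

  expect_equal(mean_shift(c(1, 0), c(0, 1)), c(1, -1) / sqrt(2))
  expect_error(mean_shift(c(0, 1), c(0, 1)), class = "scad_degenerate_error")
  set.seed(11)
  for (i in 1:20) {
    th <- mean_shift(runit(1, 6)[1, ], runit(1, 6)[1, ])
    expect_equal(sqrt(sum(th^2)), 1)
  }

  u <- l2_normalize(rnorm(4))
  expect_equal(compute_center(rbind(u, u, u)), u)
  expect_equal(compute_center(rbind(c(1, 0), c(0, 1))), c(1, 1) / sqrt(2))
  expect_error(compute_center(rbind(c(1, 0), c(-1, 0))),
               class = "scad_degenerate_error")
})

test_that("contrastive loss closed forms", {
  # single positive pair: denominator holds only the positive -> 0
  e <- runit(2, 8)
  e[2, ] <- e[1, ]
  expect_equal(contrastive_loss(e, 1, 2, tau = 0.25), 0)
  expect_equal(contrastive_loss(e, 1, 2, tau = 3), 0)

  # all-identical batch of M = 4 instances -> log(M - 1), any tau
  u <- l2_normalize(rnorm(6))
  e4 <- rbind(u, u, u, u)
  for (tau in c(0.1, 0.25, 1)) {
    expect_equal(contrastive_loss(e4, 1, 2, tau), log(3))
  }

  # positive at similarity 1, two orthogonal negatives, tau = 0.25
  e <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(contrastive_loss(e, 1, 2, 0.25), log(1 + 2 * exp(-4)),
               tolerance = 1e-10)
  expect_equal(contrastive_loss(e, 1, 2, 0.25), 0.03598, tolerance = 5e-4)

  expect_error(contrastive_loss(e, 1, 2, tau = 0), class = "scad_spec_error")
})

test_that("vectorized losses agree with the double-loop oracles on random
           batches", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(2:5, 1)
    d <- sample(c(4, 8, 16), 1)
    e <- runit(2 * n, d)
    pairs <- as.integer(seq_len(2 * n) + c(1L, -1L))
    c0 <- runit(1, d)[1, ]
    tau <- runif(1, 0.1, 1)
    b <- contrastive_batch(e, pairs)
    expect_equal(msc_loss(b, c0, tau), oracle_msc(e, pairs, c0, tau),
                 tolerance = 1e-6)
    expect_equal(angular_loss(e, c0), oracle_angular(e, c0), tolerance = 1e-6)
    z <- runit(n, d)
    expect_equal(shift_angular_loss(e, z, c0),
                 oracle_shift_angular(e, z, c0), tolerance = 1e-6)
    i <- sample(2 * n, 1)
    expect_equal(contrastive_loss(e, i, pairs[i], tau),
                 oracle_contrastive(e, i, pairs[i], tau), tolerance = 1e-6)
  }
})

test_that("mean-shifted loss with an orthogonal center equals the plain
           contrastive loss at doubled temperature", {
  # with c orthogonal to every embedding, theta_i . theta_j =
  # (phi_i . phi_j + 1) / 2: a constant shift (cancels) and a 1/2 scale
  # (absorbed by tau -> 2 tau)
  set.seed(22)
  for (rep in 1:10) {
    n <- 3
    e_low <- runit(2 * n, 6)
    e <- cbind(e_low, 0)
    c0 <- c(rep(0, 6), 1)
    pairs <- as.integer(seq_len(2 * n) + c(1L, -1L))
    tau <- runif(1, 0.2, 0.8)
    lhs <- msc_loss(contrastive_batch(e, pairs), c0, tau)
    rhs <- mean(vapply(seq_len(2 * n), function(i) {
      contrastive_loss(e, i, pairs[i], 2 * tau)
    }, numeric(1)))
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("msc loss on engineered identical mean-shifted embeddings gives
           log(M - 1)", {
  # all phi equal -> all theta equal
  u <- l2_normalize(c(1, 2, -1, 0.5))
  m <- 6
  e <- matrix(rep(u, each = m), m)
  pairs <- as.integer(seq_len(m) + c(1L, -1L))
  c0 <- l2_normalize(c(1, 0, 0, 0))
  expect_equal(msc_loss(contrastive_batch(e, pairs), c0, 0.25), log(m - 1))
})

test_that("angular and shift-angular losses hit their anchor values and
           bounds", {
  d <- 8
  c0 <- runit(1, d)[1, ]
  expect_equal(angular_loss(rbind(c0, c0), c0), -1)
  v <- runit(1, d)[1, ]
  perp <- l2_normalize(v - sum(v * c0) * c0)  # orthogonal to c0
  expect_equal(angular_loss(matrix(perp, 1), c0), 0, tolerance = 1e-10)
  expect_equal(angular_loss(rbind(c0, perp), c0), -0.5, tolerance = 1e-10)

  # repulsion hinge: zero only at the antipode, saturated at the center
  expect_equal(shift_angular_loss(matrix(c0, 1), matrix(-c0, 1), c0), -1)
  expect_equal(shift_angular_loss(matrix(c0, 1), matrix(perp, 1), c0), 0,
               tolerance = 1e-10)
  expect_equal(shift_angular_loss(matrix(c0, 1), matrix(c0, 1), c0), 1)

  set.seed(23)
  for (rep in 1:50) {
    x <- runit(4, d); z <- runit(4, d); cc <- runit(1, d)[1, ]
    a <- angular_loss(x, cc)
    expect_gte(a, -1); expect_lte(a, 1)
    s <- shift_angular_loss(x, z, cc)
    expect_gte(s, -1); expect_lte(s, 3)
  }
})

test_that("final loss is the sum of its components and supports the
           ablation reduction", {
  set.seed(24)
  n <- 3; d <- 8
  e <- runit(4 * n, d)
  pairs <- as.integer(seq_len(4 * n) + c(1L, -1L))
  shifted <- rep(c(FALSE, FALSE, TRUE, TRUE), n)
  b <- contrastive_batch(e, pairs, shifted)
  c0 <- runit(1, d)[1, ]
  expect_equal(final_loss(b, c0, 0.25),
               msc_loss(b, c0, 0.25) +
                 shift_angular_loss(e[!shifted, ], e[shifted, ], c0))
  # without shifted views the final loss is undefined; the msc ablation
  # (contrastive + plain angular) is the fallback objective
  b2 <- contrastive_batch(e, pairs)
  expect_error(final_loss(b2, c0, 0.25), class = "scad_spec_error")
  abl <- otoscad:::loss_grad_objective(e, pairs, rep(FALSE, 4 * n), c0,
                                       0.25, 1, "msc")
  expect_equal(abl$value, msc_loss(b2, c0, 0.25) + angular_loss(e, c0))
})

test_that("analytic gradients of every objective match central finite
           differences", {
  set.seed(25)
  n <- 2; d <- 6
  phi <- runit(4 * n, d)
  pairs <- as.integer(seq_len(4 * n) + c(1L, -1L))
  shifted <- rep(c(FALSE, FALSE, TRUE, TRUE), n)
  c0 <- runit(1, d)[1, ]
  h <- 1e-6
  for (mode in c("final", "msc", "angular", "shift_angular")) {
    lg <- otoscad:::loss_grad_objective(phi, pairs, shifted, c0, 0.25, 1, mode)
    fd <- matrix(0, nrow(phi), d)
    for (i in seq_len(nrow(phi))) for (j in seq_len(d)) {
      up <- phi; up[i, j] <- up[i, j] + h
      dn <- phi; dn[i, j] <- dn[i, j] - h
      fd[i, j] <- (otoscad:::loss_grad_objective(up, pairs, shifted, c0,
                                                 0.25, 1, mode)$value -
                   otoscad:::loss_grad_objective(dn, pairs, shifted, c0,
                                                 0.25, 1, mode)$value) / (2 * h)
    }
    expect_equal(lg$grad, fd, tolerance = 1e-4)
    # the final objective's gradient is the sum of its components' gradients
    if (mode == "final") {
      g1 <- otoscad:::loss_grad_msc(phi, pairs, c0, 0.25)$grad
      g2 <- otoscad:::loss_grad_shift_angular(phi, shifted, c0, 1)$grad
      expect_equal(lg$grad, g1 + g2, tolerance = 1e-12)
    }
  }
})

test_that("network backprop matches finite differences through the encoder", {
  set.seed(26)
  cfg <- embedder_config(patch_size = 8L, pool = 2L, hidden = 5L, dim = 4L,
                         steps = 1L, batch_size = 2L, seed = 1L)
  params <- otoscad:::embedder_init(cfg)
  X <- matrix(rnorm(8 * otoscad:::embedder_feature_dim(cfg)), 8)
  pairs <- as.integer(seq_len(8) + c(1L, -1L))
  shifted <- rep(c(FALSE, FALSE, TRUE, TRUE), 2)
  c0 <- runit(1, 4)[1, ]
  loss_of <- function(p) {
    fw <- otoscad:::embedder_forward(p, X)
    otoscad:::loss_grad_objective(fw$phi, pairs, shifted, c0, 0.25, 1,
                                  "final")$value
  }
  fw <- otoscad:::embedder_forward(params, X)
  lg <- otoscad:::loss_grad_objective(fw$phi, pairs, shifted, c0, 0.25, 1,
                                      "final")
  grads <- otoscad:::embedder_backprop(params, X, fw, lg$grad)
  h <- 1e-6
  for (layer in c("enc1", "enc2")) {
    W <- params[[layer]]$W
    for (idx in sample(length(W), 12)) {
      up <- params; up[[layer]]$W[idx] <- up[[layer]]$W[idx] + h
      dn <- params; dn[[layer]]$W[idx] <- dn[[layer]]$W[idx] - h
      fd <- (loss_of(up) - loss_of(dn)) / (2 * h)
      expect_equal(grads[[layer]]$W[idx], fd, tolerance = 1e-4)
    }
  }
})

test_that("embedder training reduces the loss, separates shifted patches from
           the center, and is seed-reproducible", {
  emb <- tiny_embedder("final")
  ds0 <- tiny_dataset()
  # same seed, zero steps: the untouched initial encoder and center
  emb0 <- train_embedder(ds0$train,
                         embedder_config(objective = "final", steps = 0L,
                                         batch_size = 6L, lr = 0.01,
                                         seed = 5L),
                         shift_spec("cj-wf"))
  expect_identical(emb0$center, emb$center)
  # the objective on a fixed held-out batch drops from initialization
  psets <- otoscad:::training_patches(ds0$train, 32L)
  views <- list()
  shifted <- logical(0)
  set.seed(99)
  for (p in lapply(psets, `[[`, 1)) {
    pr <- positive_pair_augment(p)
    zp <- positive_pair_augment(apply_shift(p, shift_spec("cj-wf")))
    views <- c(views, pr, zp)
    shifted <- c(shifted, FALSE, FALSE, TRUE, TRUE)
  }
  pairs <- as.integer(seq_along(views) + c(1L, -1L))
  loss_under <- function(e) {
    final_loss(contrastive_batch(embed_patches(e, views), pairs, shifted),
               e$center, tau = 0.25)
  }
  expect_lt(loss_under(emb), loss_under(emb0))

  # after training, normal patches sit closer to the center than their
  # shift-transformed versions: the objective's stated goal
  ds <- tiny_dataset()
  patches <- unlist(otoscad:::training_patches(ds$train, 32L),
                    recursive = FALSE)
  set.seed(31)
  shifted <- lapply(patches, apply_shift, spec = shift_spec("cj-wf"))
  cos_n <- mean(embed_patches(emb, patches) %*% emb$center)
  cos_z <- mean(embed_patches(emb, shifted) %*% emb$center)
  expect_gt(cos_n, cos_z)

  emb2 <- train_embedder(ds$train,
                         embedder_config(objective = "final", steps = 400L,
                                         batch_size = 6L, lr = 0.01,
                                         seed = 5L),
                         shift_spec("cj-wf"))
  expect_identical(emb$params, emb2$params)
  expect_error(train_embedder(ds$train[1], embedder_config()),
               class = "scad_spec_error")
  expect_warning(
    train_embedder(ds$train[1:2],
                   embedder_config(batch_size = 60L, steps = 2L, seed = 1L)),
    "clamping")
})
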