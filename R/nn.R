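# Minimal fully-connected network machinery shared by the detector and the
# embedder: He-initialised dense layers, ReLU, softmax cross entropy, and SGD
# with classical momentum. Written in base R matrix ops; gradients are
# analytic and checked against finite differences in the test suite.

nn_dense_init <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out),
       b = numeric(n_out))
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One SGD + momentum step over a flat named list of parameter matrices.
sgd_step <- function(params, grads, state, lr, momentum = 0.9, weight_decay = 0) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    v <- momentum * state[[nm]] - lr * g
    state[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
  list(params = params, state = state)
}

zero_like <- function(params) lapply(params, function(p) p * 0)
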