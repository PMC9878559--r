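# Minimal neural-network primitives (dense layers, Adam, activations,
# inverted dropout) shared by the GAN and the stage-2 classifiers. All
# randomness flows through R's RNG so seeded training is reproducible;
# matrices are small (~50-dim tabular rows), so vectorized base R with
# BLAS-backed matrix products is sufficient.

sigmoid_ <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))
relu_ <- function(z) pmax(z, 0)
lrelu_ <- function(z, a = 0.2) ifelse(z > 0, z, a * z)

# He-scaled dense-layer initialization
dense_init <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out),
       b = rep(0, n_out))
}

dense_fwd <- function(x, layer) sweep(x %*% layer$W, 2, layer$b, `+`)

# inverted dropout; returns scaled mask (1/keep on kept units)
dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  matrix(stats::rbinom(nr * nc, 1L, keep) / keep, nr, nc)
}

# Adam over a flat list of parameter arrays (matrices/vectors)
adam_init <- function(params) {
  zero <- lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# column-standardization helpers (scalers are fit on training data and
# stored in each handle so predict() sees the same transformation)
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mean = mu, sd = sd)
}
apply_scaler <- function(x, sc) sweep(sweep(x, 2, sc$mean), 2, sc$sd, `/`)
invert_scaler <- function(z, sc) sweep(sweep(z, 2, sc$sd, `*`), 2, sc$mean, `+`)

# deterministic minibatch index blocks over a pre-shuffled permutation
minibatches <- function(n, batch_size) {
  split(sample.int(n), ceiling(seq_len(n) / batch_size))
}
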