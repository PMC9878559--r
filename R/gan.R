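# Generative adversarial oversampling of the minority (binding) class.
# Generator and discriminator are two-hidden-layer fully connected
# networks — the rows are ~50-dim descriptor vectors, so no convolutional
# structure is warranted. Training follows the standard two-player
# objective: the discriminator maximizes its ability to tell real
# minority rows from generated ones, the generator minimizes it (the
# non-saturating form of the generator loss is used, the standard remedy
# for vanishing early-training gradients). Data are standardized
# internally; generated rows are mapped back to original descriptor
# units.

#' GAN configuration for minority oversampling
#'
#' @param latent_dim Dimension of the generator's noise input (default 32).
#' @param generator_layers,discriminator_layers Widths of the two hidden
#'   layers (default `c(64, 64)` each).
#' @param epochs Training epochs over the minority rows (default 200).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Adam step size for both players (default 2e-4;
#'   Adam momentum 0.5/0.999, the usual GAN setting).
#' @param seed Integer seed.
#' @return Object of class `gan_config`.
#' @export
gan_config <- function(latent_dim = 32L, generator_layers = c(64L, 64L),
                       discriminator_layers = c(64L, 64L), epochs = 200L,
                       batch_size = 64L, learning_rate = 2e-4, seed = 1L) {
  stopifnot(length(generator_layers) == 2L, length(discriminator_layers) == 2L)
  structure(list(latent_dim = check_count(latent_dim, "latent_dim"),
                 generator_layers = vapply(generator_layers, check_count,
                                           integer(1), name = "generator_layers"),
                 discriminator_layers = vapply(discriminator_layers, check_count,
                                               integer(1), name = "discriminator_layers"),
                 epochs = check_count(epochs, "epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 learning_rate = as.numeric(learning_rate),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "gan_config")
}

gen_forward <- function(gp, z) {
  h1 <- relu_(dense_fwd(z, gp[[1]]))
  h2 <- relu_(dense_fwd(h1, gp[[2]]))
  out <- dense_fwd(h2, gp[[3]])   # linear output in standardized units
  list(h1 = h1, h2 = h2, out = out)
}

disc_forward <- function(dp, x) {
  h1 <- lrelu_(dense_fwd(x, dp[[1]]))
  h2 <- lrelu_(dense_fwd(h1, dp[[2]]))
  logit <- dense_fwd(h2, dp[[3]])
  list(h1 = h1, h2 = h2, logit = logit, p = sigmoid_(logit))
}

# gradient of the discriminator BCE w.r.t. its parameters, plus the
# gradient w.r.t. the input rows (needed to backprop into the generator)
disc_backward <- function(dp, x, cache, dlogit, want_dx = FALSE) {
  g <- vector("list", 6)
  g[[5]] <- t(cache$h2) %*% dlogit; g[[6]] <- colSums(dlogit)
  dh2 <- dlogit %*% t(dp[[3]]$W)
  dh2 <- dh2 * ifelse(cache$h2 > 0, 1, 0.2)
  g[[3]] <- t(cache$h1) %*% dh2; g[[4]] <- colSums(dh2)
  dh1 <- dh2 %*% t(dp[[2]]$W)
  dh1 <- dh1 * ifelse(cache$h1 > 0, 1, 0.2)
  g[[1]] <- t(x) %*% dh1; g[[2]] <- colSums(dh1)
  dx <- if (want_dx) dh1 %*% t(dp[[1]]$W) else NULL
  list(grads = g, dx = dx)
}

gen_backward <- function(gp, z, cache, dout) {
  g <- vector("list", 6)
  g[[5]] <- t(cache$h2) %*% dout; g[[6]] <- colSums(dout)
  dh2 <- dout %*% t(gp[[3]]$W)
  dh2[cache$h2 <= 0] <- 0
  g[[3]] <- t(cache$h1) %*% dh2; g[[4]] <- colSums(dh2)
  dh1 <- dh2 %*% t(gp[[2]]$W)
  dh1[cache$h1 <= 0] <- 0
  g[[1]] <- t(z) %*% dh1; g[[2]] <- colSums(dh1)
  g
}

flatten_layers <- function(layers) {
  out <- list()
  for (l in layers) { out <- c(out, list(l$W), list(l$b)) }
  out
}
unflatten_layers <- function(flat) {
  lapply(seq_len(length(flat) / 2), function(i)
    list(W = flat[[2 * i - 1]], b = flat[[2 * i]]))
}

#' Train a GAN on the minority (binding) rows
#'
#' Fits the two-player generator/discriminator game on the minority rows
#' of a training split so that new, plausible binding conformations can
#' be synthesized by [sample_minority()]. Rows are standardized
#' internally (scaler fit on the minority rows); the returned handle
#' carries the scaler and generator weights and is an ordinary R list,
#' serializable with `saveRDS()`.
#'
#' @param minority_rows Numeric matrix of minority-class rows (>= 10
#'   rows, all finite).
#' @param cfg A [gan_config()].
#' @return Object of class `gan_generator`.
#' @export
fit_gan <- function(minority_rows, cfg = gan_config()) {
  stopifnot(inherits(cfg, "gan_config"))
  if (is.data.frame(minority_rows)) minority_rows <- as.matrix(minority_rows)
  if (!is.matrix(minority_rows) || !is.numeric(minority_rows))
    stop_("`minority_rows` must be a numeric matrix")
  if (nrow(minority_rows) < 10L)
    stop_("need at least 10 minority rows to train a GAN (got %d)",
          nrow(minority_rows))
  if (anyNA(minority_rows) || any(!is.finite(minority_rows)))
    stop_("`minority_rows` contains missing or non-finite values")
  d <- ncol(minority_rows)
  sc <- fit_scaler(minority_rows)
  xr <- apply_scaler(minority_rows, sc)
  n <- nrow(xr)
  with_seed(cfg$seed, {
    gl <- cfg$generator_layers; dl <- cfg$discriminator_layers
    gp <- list(dense_init(cfg$latent_dim, gl[1]), dense_init(gl[1], gl[2]),
               dense_init(gl[2], d, scale = sqrt(1 / gl[2])))
    dp <- list(dense_init(d, dl[1]), dense_init(dl[1], dl[2]),
               dense_init(dl[2], 1L, scale = sqrt(1 / dl[2])))
    g_state <- adam_init(flatten_layers(gp))
    d_state <- adam_init(flatten_layers(dp))
    # exponential moving average of generator weights; the averaged
    # generator is what gets sampled, damping the oscillation of the
    # two-player game around its equilibrium
    g_ema <- flatten_layers(gp)
    ema_decay <- 0.995
    lr <- cfg$learning_rate
    for (epoch in seq_len(cfg$epochs)) {
      for (idx in minibatches(n, cfg$batch_size)) {
        b <- length(idx)
        real <- xr[idx, , drop = FALSE]
        z <- matrix(stats::rnorm(b * cfg$latent_dim), b, cfg$latent_dim)
        fake <- gen_forward(gp, z)$out
        # --- discriminator update: maximize log D(real) + log(1 - D(fake))
        cr <- disc_forward(dp, real)
        cf <- disc_forward(dp, fake)
        gr <- disc_backward(dp, real, cr, (cr$p - 1) / b)$grads
        gf <- disc_backward(dp, fake, cf, (cf$p - 0) / b)$grads
        gsum <- Map(`+`, gr, gf)
        st <- adam_step(flatten_layers(dp), gsum, d_state, lr, beta1 = 0.5)
        dp <- unflatten_layers(st$params); d_state <- st$state
        # --- generator update: minimize -log D(fake) (non-saturating)
        z <- matrix(stats::rnorm(b * cfg$latent_dim), b, cfg$latent_dim)
        gc_ <- gen_forward(gp, z)
        cf2 <- disc_forward(dp, gc_$out)
        dfake <- disc_backward(dp, gc_$out, cf2, (cf2$p - 1) / b, want_dx = TRUE)$dx
        gg <- gen_backward(gp, z, gc_, dfake)
        st <- adam_step(flatten_layers(gp), gg, g_state, lr, beta1 = 0.5)
        gp <- unflatten_layers(st$params); g_state <- st$state
        g_ema <- Map(function(e, p) ema_decay * e + (1 - ema_decay) * p,
                     g_ema, st$params)
      }
    }
    structure(list(generator = unflatten_layers(g_ema), scaler = sc,
                   latent_dim = cfg$latent_dim,
                   d = d, colnames = colnames(minority_rows), cfg = cfg),
              class = "gan_generator")
  })
}

#' @export
print.gan_generator <- function(x, ...) {
  cat(sprintf("<gan_generator> %d-dim descriptors, latent %d, hidden %s, %d epochs\n",
              x$d, x$latent_dim, paste(x$cfg$generator_layers, collapse = "x"),
              x$cfg$epochs))
  invisible(x)
}

#' Sample synthetic minority rows from a trained GAN
#'
#' Draws `k` rows from the generator and maps them back to original
#' descriptor units. Sampling is seeded (default: derived from the
#' training seed) so the same request is reproducible.
#'
#' @param handle A `gan_generator` from [fit_gan()].
#' @param k Number of rows to generate (>= 1).
#' @param seed Integer seed for the noise draw.
#' @return Numeric `k x d` matrix, all finite, column names preserved.
#' @export
sample_minority <- function(handle, k, seed = NULL) {
  if (!inherits(handle, "gan_generator"))
    stop_("`handle` must be a trained gan_generator (see fit_gan)")
  k <- check_count(k, "k")
  if (is.null(seed)) seed <- derive_seed(handle$cfg$seed, "sample_minority")
  z <- with_seed(seed,
                 matrix(stats::rnorm(k * handle$latent_dim), k, handle$latent_dim))
  out <- invert_scaler(gen_forward(handle$generator, z)$out, handle$scaler)
  colnames(out) <- handle$colnames
  out
}
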