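# 1-D convolutional classifier over the ordered descriptor vector:
# convolution (ReLU) -> dropout -> max pooling -> dense (ReLU) -> sigmoid
# output, binary cross-entropy loss, Adam. The descriptor order is the
# dataset's column order — arbitrary but fixed, so adjacent-column motifs
# the convolution picks up are reproducible across fits.

cnn_geometry <- function(d, cfg) {
  L <- d - cfg$kernel + 1L
  if (L < 1L) stop_("need at least `kernel` = %d features (got %d)", cfg$kernel, d)
  P <- L %/% cfg$pool
  pooled <- P >= 1L
  if (!pooled) P <- L       # too few conv positions to pool: identity pool
  list(L = L, P = P, pooled = pooled)
}

# rows of the im2col matrix are (sample b, position l) pairs indexed
# b + (l-1)*B, so column-major reshapes stay aligned throughout
cnn_im2col <- function(x, L, k) {
  B <- nrow(x)
  xc <- matrix(0, B * L, k)
  for (j in seq_len(k)) xc[, j] <- as.vector(x[, j:(j + L - 1), drop = FALSE])
  xc
}

cnn_forward <- function(par, x, cfg, geo, training = FALSE) {
  B <- nrow(x)
  xc <- cnn_im2col(x, geo$L, cfg$kernel)
  zc <- sweep(xc %*% par$Wc, 2, par$bc, `+`)
  ac <- relu_(zc)
  mask <- if (training) dropout_mask(nrow(ac), ncol(ac), cfg$dropout) else NULL
  if (!is.null(mask)) ac <- ac * mask
  if (geo$pooled) {
    rows <- function(l) as.vector(outer(seq_len(B), (l - 1L) * B, `+`))
    win <- lapply(seq_len(cfg$pool), function(w)
      ac[rows(seq(w, by = cfg$pool, length.out = geo$P)), , drop = FALSE])
    pooled <- Reduce(pmax, win)
    argmax <- Reduce(function(a, w) ifelse(win[[w]] == pooled & a == 0L, w, a),
                     seq_len(cfg$pool), accumulate = FALSE,
                     init = matrix(0L, nrow(pooled), ncol(pooled)))
  } else {
    pooled <- ac
    win <- NULL; argmax <- NULL
  }
  flat <- matrix(as.vector(pooled), nrow = B)
  h <- relu_(sweep(flat %*% par$W2, 2, par$b2, `+`))
  p <- sigmoid_(sweep(h %*% par$W3, 2, par$b3, `+`))
  list(xc = xc, ac = ac, mask = mask, pooled = pooled, argmax = argmax,
       flat = flat, h = h, p = as.vector(p))
}

cnn_backward <- function(par, cache, y, cfg, geo) {
  B <- length(y)
  dz3 <- matrix((cache$p - y) / B, B, 1)
  gW3 <- t(cache$h) %*% dz3; gb3 <- colSums(dz3)
  dh <- dz3 %*% t(par$W3)
  dh[cache$h <= 0] <- 0
  gW2 <- t(cache$flat) %*% dh; gb2 <- colSums(dh)
  dflat <- dh %*% t(par$W2)
  dpooled <- matrix(as.vector(dflat), nrow = B * geo$P)
  dac <- matrix(0, nrow(cache$ac), ncol(cache$ac))
  if (geo$pooled) {
    rows <- function(l) as.vector(outer(seq_len(B), (l - 1L) * B, `+`))
    for (w in seq_len(cfg$pool)) {
      rw <- rows(seq(w, by = cfg$pool, length.out = geo$P))
      sel <- cache$argmax == w
      tmp <- matrix(0, geo$P * B, ncol(dac))
      tmp[sel] <- dpooled[sel]
      dac[rw, ] <- dac[rw, ] + tmp
    }
  } else {
    dac <- dpooled
  }
  if (!is.null(cache$mask)) dac <- dac * cache$mask
  dac[cache$ac <= 0] <- 0
  gWc <- t(cache$xc) %*% dac; gbc <- colSums(dac)
  list(Wc = gWc, bc = gbc, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Train the 1-D convolutional stage-2 classifier
#'
#' Fits the CNN described in [net_config()] on a (typically rebalanced)
#' training split. Columns are standardized internally (scaler fit on the
#' training rows and stored in the handle). Training is single-threaded
#' and fully seeded, so a given seed reproduces the fit exactly.
#'
#' @param train A [conformation_dataset()] with both classes and at least
#'   `kernel` features.
#' @param cfg A [net_config()].
#' @return Object of class `cnn_classifier`.
#' @export
train_cnn <- function(train, cfg = net_config()) {
  stopifnot(inherits(train, "conformation_dataset"), inherits(cfg, "net_config"))
  check_two_classes(train, "CNN training")
  d <- ncol(train$features)
  geo <- cnn_geometry(d, cfg)
  sc <- fit_scaler(train$features)
  xs <- apply_scaler(train$features, sc)
  y <- train$labels
  with_seed(cfg$seed, {
    par <- list()
    ci <- dense_init(cfg$kernel, cfg$conv_filters)
    par$Wc <- ci$W; par$bc <- ci$b
    di <- dense_init(geo$P * cfg$conv_filters, cfg$dense)
    par$W2 <- di$W; par$b2 <- di$b
    oi <- dense_init(cfg$dense, 1L, scale = sqrt(1 / cfg$dense))
    par$W3 <- oi$W; par$b3 <- oi$b
    state <- adam_init(par)
    for (epoch in seq_len(cfg$epochs)) {
      for (idx in minibatches(nrow(xs), cfg$batch_size)) {
        cache <- cnn_forward(par, xs[idx, , drop = FALSE], cfg, geo,
                             training = TRUE)
        grads <- cnn_backward(par, cache, y[idx], cfg, geo)
        st <- adam_step(par, grads[names(par)], state, cfg$learning_rate)
        par <- st$params; state <- st$state
      }
    }
    structure(list(par = par, scaler = sc, cfg = cfg, geo = geo,
                   feature_names = train$feature_names),
              class = "cnn_classifier")
  })
}

#' @export
print.cnn_classifier <- function(x, ...) {
  cat(sprintf("<cnn_classifier> %d features -> conv(%d filters, kernel %d) -> pool(%d) -> dense(%d) -> sigmoid\n",
              length(x$feature_names), x$cfg$conv_filters, x$cfg$kernel,
              x$cfg$pool, x$cfg$dense))
  invisible(x)
}

#' @rdname train_cnn
#' @param object A `cnn_classifier`.
#' @param ds Dataset to score; features must match training.
#' @param threshold Hard-label threshold; default the config's.
#' @param ... Unused.
#' @export
predict.cnn_classifier <- function(object, ds, threshold = NULL, ...) {
  stopifnot(inherits(ds, "conformation_dataset"))
  check_feature_match(object$feature_names, ds)
  if (is.null(threshold)) threshold <- object$cfg$threshold
  xs <- apply_scaler(ds$features, object$scaler)
  p <- cnn_forward(object$par, xs, object$cfg, object$geo, training = FALSE)$p
  prediction_set(ds$labels, p, threshold = threshold)
}
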