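# Recurrent stage-2 classifier: the descriptor vector is consumed as a
# length-d sequence (one descriptor per timestep) by two stacked LSTM
# layers with dropout, then a dense ReLU layer with dropout and a sigmoid
# output. Per the architecture contract, the cell's candidate and hidden
# activations are rectified-linear; the three gates stay sigmoidal.
# Binary cross-entropy loss, Adam, full backpropagation through time.

lstm_init <- function(n_in, H) {
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias starts open
  list(Wx = matrix(stats::rnorm(n_in * 4 * H, sd = sqrt(1 / n_in)), n_in, 4 * H),
       Wh = matrix(stats::rnorm(H * 4 * H, sd = sqrt(1 / H)), H, 4 * H),
       b = b)
}

# x: list over t of (B x n_in) inputs. Returns per-step caches and the
# full hidden-state sequence.
lstm_forward <- function(layer, x) {
  T_ <- length(x)
  B <- nrow(x[[1]])
  H <- nrow(layer$Wh)   # Wh is H x 4H
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  caches <- vector("list", T_)
  hs <- vector("list", T_)
  ii <- seq_len(H); fi <- H + ii; oi <- 2 * H + ii; gi <- 3 * H + ii
  for (t in seq_len(T_)) {
    a <- sweep(x[[t]] %*% layer$Wx + h %*% layer$Wh, 2, layer$b, `+`)
    i <- sigmoid_(a[, ii, drop = FALSE])
    f <- sigmoid_(a[, fi, drop = FALSE])
    o <- sigmoid_(a[, oi, drop = FALSE])
    g <- relu_(a[, gi, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    hc <- relu_(cc)
    h_prev <- h
    h <- o * hc
    caches[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = c_prev, c = cc,
                        hc = hc, h_prev = h_prev, x = x[[t]])
    hs[[t]] <- h
  }
  list(caches = caches, hs = hs)
}

# dhs: list over t of gradients w.r.t. h_t (zero matrices where unused).
# Returns parameter gradients and per-step input gradients.
lstm_backward <- function(layer, fwd, dhs) {
  T_ <- length(fwd$caches)
  H <- nrow(layer$Wh)
  B <- nrow(dhs[[T_]])
  gWx <- layer$Wx * 0; gWh <- layer$Wh * 0; gb <- layer$b * 0
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  dxs <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    cc <- fwd$caches[[t]]
    dh <- dhs[[t]] + dh_next
    do_ <- dh * cc$hc
    da_o <- do_ * cc$o * (1 - cc$o)
    dc <- dc_next + dh * cc$o * (cc$c > 0)
    df <- dc * cc$c_prev
    da_f <- df * cc$f * (1 - cc$f)
    di <- dc * cc$g
    da_i <- di * cc$i * (1 - cc$i)
    dg <- dc * cc$i
    da_g <- dg * (cc$g > 0)
    da <- cbind(da_i, da_f, da_o, da_g)
    gWx <- gWx + t(cc$x) %*% da
    gWh <- gWh + t(cc$h_prev) %*% da
    gb <- gb + colSums(da)
    dxs[[t]] <- da %*% t(layer$Wx)
    dh_next <- da %*% t(layer$Wh)
    dc_next <- dc * cc$f
  }
  list(Wx = gWx, Wh = gWh, b = gb, dxs = dxs)
}

rnn_forward <- function(par, x, cfg, training = FALSE) {
  B <- nrow(x); T_ <- ncol(x)
  x1 <- lapply(seq_len(T_), function(t) x[, t, drop = FALSE])
  f1 <- lstm_forward(par$l1, x1)
  m1 <- if (training) lapply(seq_len(T_), function(t)
    dropout_mask(B, ncol(f1$hs[[t]]), cfg$dropout)) else NULL
  h1 <- if (is.null(m1) || is.null(m1[[1]])) f1$hs
        else Map(`*`, f1$hs, m1)
  f2 <- lstm_forward(par$l2, h1)
  hT <- f2$hs[[T_]]
  m2 <- if (training) dropout_mask(B, ncol(hT), cfg$dropout) else NULL
  hTd <- if (is.null(m2)) hT else hT * m2
  hd <- relu_(sweep(hTd %*% par$Wd, 2, par$bd, `+`))
  m3 <- if (training) dropout_mask(B, ncol(hd), cfg$dropout) else NULL
  hdd <- if (is.null(m3)) hd else hd * m3
  p <- sigmoid_(sweep(hdd %*% par$Wo, 2, par$bo, `+`))
  list(f1 = f1, f2 = f2, m1 = m1, m2 = m2, m3 = m3, h1 = h1, hT = hT,
       hTd = hTd, hd = hd, hdd = hdd, p = as.vector(p), T_ = T_, B = B)
}

rnn_backward <- function(par, cache, y, cfg) {
  B <- cache$B; T_ <- cache$T_
  dz <- matrix((cache$p - y) / B, B, 1)
  gWo <- t(cache$hdd) %*% dz; gbo <- colSums(dz)
  dhdd <- dz %*% t(par$Wo)
  if (!is.null(cache$m3)) dhdd <- dhdd * cache$m3
  dhd <- dhdd
  dhd[cache$hd <= 0] <- 0
  gWd <- t(cache$hTd) %*% dhd; gbd <- colSums(dhd)
  dhT <- dhd %*% t(par$Wd)
  if (!is.null(cache$m2)) dhT <- dhT * cache$m2
  H2 <- nrow(par$l2$Wh)
  dhs2 <- c(rep(list(matrix(0, B, H2)), T_ - 1L), list(dhT))
  b2 <- lstm_backward(par$l2, cache$f2, dhs2)
  dh1 <- b2$dxs
  if (!is.null(cache$m1) && !is.null(cache$m1[[1]]))
    dh1 <- Map(`*`, dh1, cache$m1)
  b1 <- lstm_backward(par$l1, cache$f1, dh1)
  list(l1.Wx = b1$Wx, l1.Wh = b1$Wh, l1.b = b1$b,
       l2.Wx = b2$Wx, l2.Wh = b2$Wh, l2.b = b2$b,
       Wd = gWd, bd = gbd, Wo = gWo, bo = gbo)
}

rnn_flatten <- function(par) list(par$l1$Wx, par$l1$Wh, par$l1$b,
                                  par$l2$Wx, par$l2$Wh, par$l2$b,
                                  par$Wd, par$bd, par$Wo, par$bo)
rnn_unflatten <- function(flat) {
  list(l1 = list(Wx = flat[[1]], Wh = flat[[2]], b = flat[[3]]),
       l2 = list(Wx = flat[[4]], Wh = flat[[5]], b = flat[[6]]),
       Wd = flat[[7]], bd = flat[[8]], Wo = flat[[9]], bo = flat[[10]])
}

#' Train the recurrent stage-2 classifier
#'
#' Fits the two-layer LSTM described in [net_config()] on a (typically
#' rebalanced) training split, reading each row's descriptors as a
#' sequence in column order. Columns are standardized internally; the fit
#' is single-threaded and fully seeded. Because the descriptors form the
#' sequence, permuting feature columns changes the model — the order is
#' arbitrary but must be held fixed, which the feature-match check in
#' `predict()` enforces.
#'
#' @param train A [conformation_dataset()] with both classes.
#' @param cfg A [net_config()].
#' @return Object of class `rnn_classifier`.
#' @export
train_rnn <- function(train, cfg = net_config()) {
  stopifnot(inherits(train, "conformation_dataset"), inherits(cfg, "net_config"))
  check_two_classes(train, "RNN training")
  sc <- fit_scaler(train$features)
  xs <- apply_scaler(train$features, sc)
  y <- train$labels
  with_seed(cfg$seed, {
    par <- list(l1 = lstm_init(1L, cfg$rnn_units[1]),
                l2 = lstm_init(cfg$rnn_units[1], cfg$rnn_units[2]))
    di <- dense_init(cfg$rnn_units[2], cfg$rnn_dense)
    par$Wd <- di$W; par$bd <- di$b
    oi <- dense_init(cfg$rnn_dense, 1L, scale = sqrt(1 / cfg$rnn_dense))
    par$Wo <- oi$W; par$bo <- oi$b
    flat <- rnn_flatten(par)
    state <- adam_init(flat)
    grad_order <- c("l1.Wx", "l1.Wh", "l1.b", "l2.Wx", "l2.Wh", "l2.b",
                    "Wd", "bd", "Wo", "bo")
    for (epoch in seq_len(cfg$epochs)) {
      for (idx in minibatches(nrow(xs), cfg$batch_size)) {
        cache <- rnn_forward(par, xs[idx, , drop = FALSE], cfg, training = TRUE)
        grads <- rnn_backward(par, cache, y[idx], cfg)
        st <- adam_step(rnn_flatten(par), grads[grad_order], state,
                        cfg$learning_rate)
        par <- rnn_unflatten(st$params); state <- st$state
      }
    }
    structure(list(par = par, scaler = sc, cfg = cfg,
                   feature_names = train$feature_names),
              class = "rnn_classifier")
  })
}

#' @export
print.rnn_classifier <- function(x, ...) {
  cat(sprintf("<rnn_classifier> %d-step sequence -> LSTM(%d) -> LSTM(%d) -> dense(%d) -> sigmoid\n",
              length(x$feature_names), x$cfg$rnn_units[1], x$cfg$rnn_units[2],
              x$cfg$rnn_dense))
  invisible(x)
}

#' @rdname train_rnn
#' @param object An `rnn_classifier`.
#' @param ds Dataset to score; features must match training (same order).
#' @param threshold Hard-label threshold; default the config's.
#' @param ... Unused.
#' @export
predict.rnn_classifier <- function(object, ds, threshold = NULL, ...) {
  stopifnot(inherits(ds, "conformation_dataset"))
  check_feature_match(object$feature_names, ds)
  if (is.null(threshold)) threshold <- object$cfg$threshold
  xs <- apply_scaler(ds$features, object$scaler)
  p <- rnn_forward(object$par, xs, object$cfg, training = FALSE)$p
  prediction_set(ds$labels, p, threshold = threshold)
}
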