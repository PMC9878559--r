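# Independent brute-force oracles and small fixture builders. These
# deliberately use different code paths (nested loops, full-matrix
# enumeration, stats::aov) than the package internals they check.

# small labeled dataset from explicit vectors
tiny_ds <- function(..., labels, name = "tiny") {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  conformation_dataset(m, labels, name = name)
}

random_ds <- function(n, d, seed, discrete = FALSE) {
  set.seed(seed)
  m <- if (discrete) matrix(sample(1:6, n * d, replace = TRUE), n, d)
       else matrix(rnorm(n, sd = 2) + rnorm(n * d), n, d)
  colnames(m) <- sprintf("f%02d", seq_len(d))
  labels <- integer(n)
  labels[sample.int(n, max(2L, n %/% 3L))] <- 1L
  if (sum(labels) < 2L || sum(labels == 0L) < 2L) labels[1:2] <- c(0L, 1L)
  conformation_dataset(m, labels)
}

# exhaustive per-element confusion tally
oracle_confusion <- function(truth, pred) {
  out <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(truth)) {
    key <- if (truth[i] == 1L && pred[i] == 1L) "tp"
           else if (truth[i] == 0L && pred[i] == 0L) "tn"
           else if (truth[i] == 0L && pred[i] == 1L) "fp"
           else "fn"
    out[key] <- out[key] + 1L
  }
  out
}

# one-way F via R's own ANOVA machinery
oracle_anova_f <- function(x, y) {
  fit <- summary(stats::aov(x ~ factor(y)))
  fit[[1]][["F value"]][1]
}

# plug-in mutual information (nats) by nested loops over the joint table;
# assumes the feature is discrete-valued (few unique values)
oracle_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (u in unique(x)) {
    for (v in unique(y)) {
      puv <- sum(x == u & y == v) / n
      if (puv == 0) next
      pu <- sum(x == u) / n
      pv <- sum(y == v) / n
      total <- total + puv * log(puv / (pu * pv))
    }
  }
  total
}

# Pearson correlation of average ranks, with both ranks and the product
# moments computed by explicit sums
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  a <- avg_rank(x); b <- avg_rank(y)
  am <- sum(a) / length(a); bm <- sum(b) / length(b)
  sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# full-matrix recurrence enumeration: z-score, optional embedding,
# build the M x M logical matrix, then run-length-encode each diagonal
oracle_rqa_census <- function(series, cfg) {
  s <- stats::sd(series)
  if (cfg$normalize) {
    if (s == 0) stop("oracle does not handle constant series")
    series <- (series - mean(series)) / s
    eps <- cfg$radius
  } else {
    eps <- cfg$radius * s
  }
  if (cfg$embedding_dim > 1L) {
    M <- length(series) - (cfg$embedding_dim - 1L) * cfg$delay
    x <- sapply(seq_len(cfg$embedding_dim),
                function(c) series[seq_len(M) + (c - 1L) * cfg$delay])
  } else {
    x <- matrix(series, ncol = 1L)
  }
  M <- nrow(x)
  R <- matrix(FALSE, M, M)
  for (i in seq_len(M))
    for (k in seq_len(M))
      R[i, k] <- sqrt(sum((x[i, ] - x[k, ])^2)) <= eps
  counts <- stats::setNames(integer(0), character(0))
  for (off in seq_len(M - 1L)) {
    diag_cells <- R[cbind(seq_len(M - off), seq_len(M - off) + off)]
    r <- rle(diag_cells)
    for (len in r$lengths[r$values]) {
      nm <- as.character(len)
      counts[nm] <- if (nm %in% names(counts)) counts[nm] + 1L else 1L
    }
  }
  counts <- counts[as.integer(names(counts)) >= cfg$jmin]
  counts[order(as.integer(names(counts)))]
}

oracle_entr <- function(census) {
  if (length(census) == 0) return(0)
  p <- census / sum(census)
  -sum(p * log(p))
}

# separable two-feature fixture: classes split cleanly on feature 1
separable_ds <- function(n = 200, d = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  m <- matrix(rnorm(n * d), n, d)
  m[, 1] <- m[, 1] + ifelse(y == 1L, 6, -6)
  colnames(m) <- sprintf("f%02d", seq_len(d))
  conformation_dataset(m, y, name = "separable")
}
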