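# Two-stage rebalancing of a training split under the equal-size
# contract: every real binding row is kept, the GAN fills the minority up
# to the planned share, and the majority is cluster-undersampled down to
# the remainder, so the rebuilt training set has exactly the size of the
# original one.

#' Resampling plan for rebuilding a training split
#'
#' @param target_total Size of the rebuilt training set. `NULL` (default)
#'   means the size of the training split passed to [rebalance()] — the
#'   equal-size contract; any other value is rejected there.
#' @param minority_target Minority (binding) count after oversampling.
#'   `NULL` (default) means `floor(target_total / 2)`, i.e. a 1:1 rebuilt
#'   balance.
#' @param kmeans_clusters Number of K-Means clusters used to undersample
#'   the majority (default 10).
#' @param seed Integer seed for clustering and generator sampling.
#' @return Object of class `resampling_plan`.
#' @export
resampling_plan <- function(target_total = NULL, minority_target = NULL,
                            kmeans_clusters = 10L, seed = 1L) {
  structure(list(
    target_total = if (is.null(target_total)) NULL
                   else check_count(target_total, "target_total"),
    minority_target = if (is.null(minority_target)) NULL
                      else check_count(minority_target, "minority_target"),
    kmeans_clusters = check_count(kmeans_clusters, "kmeans_clusters"),
    seed = check_count(seed, "seed", min = 0L)), class = "resampling_plan")
}

#' Cluster-based undersampling of the majority class
#'
#' Clusters the majority rows with K-Means (minimum intra-cluster,
#' maximum inter-cluster distance objective) on internally standardized
#' columns, allocates the requested count across clusters proportionally
#' to cluster size (largest remainder), and keeps, within each cluster,
#' the rows nearest its centroid — a deterministic choice of cluster
#' representatives.
#'
#' @param majority_rows Numeric matrix of majority-class rows.
#' @param target Number of rows to keep (0 <= `target` <= `nrow`).
#' @param k_clusters Number of clusters (default 10; capped at the number
#'   of rows).
#' @param seed Integer seed for the K-Means starts.
#' @return Sorted integer vector of exactly `target` distinct row indices
#'   into `majority_rows`.
#' @export
kmeans_undersample <- function(majority_rows, target, k_clusters = 10L,
                               seed = 1L) {
  if (is.data.frame(majority_rows)) majority_rows <- as.matrix(majority_rows)
  stopifnot(is.matrix(majority_rows), is.numeric(majority_rows))
  n <- nrow(majority_rows)
  target <- check_count(target, "target", min = 0L)
  if (target > n)
    stop_("target (%d) exceeds the number of majority rows (%d)", target, n)
  if (target == 0L) return(integer(0))
  if (target == n) return(seq_len(n))
  k_clusters <- check_count(k_clusters, "k_clusters")
  k <- min(k_clusters, n, nrow(unique(majority_rows)))
  xs <- apply_scaler(majority_rows, fit_scaler(majority_rows))
  km <- with_seed(seed,
                  stats::kmeans(xs, centers = k, nstart = 5L, iter.max = 50L))
  sizes <- as.numeric(table(factor(km$cluster, levels = seq_len(k))))
  alloc <- largest_remainder(sizes, target)
  picked <- integer(0)
  for (c in seq_len(k)) {
    if (alloc[c] == 0L) next
    members <- which(km$cluster == c)
    dist2 <- rowSums(sweep(xs[members, , drop = FALSE], 2, km$centers[c, ])^2)
    picked <- c(picked, members[order(dist2, members)[seq_len(alloc[c])]])
  }
  sort(picked)
}

#' Rebuild a training split with GAN oversampling and K-Means undersampling
#'
#' Implements the equal-size rebalancing contract: the output has exactly
#' as many rows as `train`; all real minority (binding) rows are
#' retained and the GAN generates the rest of the planned minority share;
#' the majority side is filled by [kmeans_undersample()]. When a
#' `majority_pool` is given (typically the rows the stage-1 classifier
#' classified correctly as non-binding), undersampling draws from that
#' pool, falling back to all majority rows if the pool is too small.
#'
#' @param train A [conformation_dataset()] training split with both
#'   classes.
#' @param plan A [resampling_plan()].
#' @param gan_cfg A [gan_config()] for the minority generator.
#' @param majority_pool Optional integer vector of row indices (into
#'   `train`) restricting which majority rows may be kept.
#' @return A [conformation_dataset()] whose extra element `provenance`
#'   labels each row `"real"` or `"generated"`. Rows are ordered: real
#'   minority, generated minority, undersampled majority.
#' @export
rebalance <- function(train, plan = resampling_plan(), gan_cfg = gan_config(),
                      majority_pool = NULL) {
  stopifnot(inherits(train, "conformation_dataset"),
            inherits(plan, "resampling_plan"))
  check_two_classes(train, "rebalancing")
  n <- nrow(train$features)
  target_total <- if (is.null(plan$target_total)) n else plan$target_total
  if (target_total != n)
    stop_("equal-size contract: target_total (%d) must equal the training size (%d)",
          target_total, n)
  min_idx <- which(train$labels == 1L)
  maj_idx <- which(train$labels == 0L)
  m <- length(min_idx)
  minority_target <- if (is.null(plan$minority_target))
    max(m, floor(target_total / 2)) else plan$minority_target
  if (minority_target < m)
    stop_("minority_target (%d) is below the real minority count (%d); real binding rows are never dropped",
          minority_target, m)
  if (minority_target > target_total)
    stop_("minority_target (%d) exceeds target_total (%d)", minority_target,
          target_total)
  majority_target <- target_total - minority_target
  if (majority_target > length(maj_idx))
    stop_("majority share (%d) exceeds the available majority rows (%d); lower minority_target",
          majority_target, length(maj_idx))
  n_gen <- minority_target - m
  gen_rows <- NULL
  if (n_gen > 0L) {
    handle <- fit_gan(train$features[min_idx, , drop = FALSE], gan_cfg)
    gen_rows <- sample_minority(handle, n_gen,
                                seed = derive_seed(plan$seed, "oversample"))
  }
  pool <- majority_pool
  if (!is.null(pool)) {
    pool <- intersect(as.integer(pool), maj_idx)
    if (length(pool) < majority_target) pool <- NULL  # fallback: all majority
  }
  if (is.null(pool)) pool <- maj_idx
  keep_rel <- kmeans_undersample(train$features[pool, , drop = FALSE],
                                 majority_target,
                                 k_clusters = plan$kmeans_clusters,
                                 seed = derive_seed(plan$seed, "undersample"))
  keep_maj <- pool[keep_rel]
  feats <- rbind(train$features[min_idx, , drop = FALSE], gen_rows,
                 train$features[keep_maj, , drop = FALSE])
  labels <- c(rep(1L, minority_target), rep(0L, majority_target))
  out <- conformation_dataset(feats, labels, name = paste0(train$name, "_rebalanced"),
                              feature_names = train$feature_names)
  out$provenance <- c(rep("real", m), rep("generated", n_gen),
                      rep("real", majority_target))
  out
}
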