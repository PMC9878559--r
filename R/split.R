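#' Train/test split specification
#'
#' Captures the evaluation protocol: a 30%/70% train/test partition,
#' stratified by class so the severe binding/non-binding imbalance is
#' preserved on both sides.
#'
#' @param train_fraction Proportion of rows assigned to training, in (0,1).
#'   Default 0.30.
#' @param stratified Stratify by class? Default `TRUE`. When `FALSE` rows
#'   are sampled without regard to label.
#' @param seed Integer seed making the partition reproducible.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.30, stratified = TRUE, seed = 1L) {
  structure(list(train_fraction = check_fraction(train_fraction, "train_fraction"),
                 stratified = isTRUE(stratified),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "split_spec")
}

# largest-remainder allocation of `total` across groups with weights `w`
largest_remainder <- function(w, total) {
  exact <- w / sum(w) * total
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Stratified train/test split
#'
#' Partitions a dataset into disjoint, exhaustive train and test subsets.
#' The train size is `round(train_fraction * n)`; under stratification the
#' train rows are allocated across classes by largest remainder, so each
#' class's train count deviates from `train_fraction * class count` by less
#' than one row. Row order within each side preserves the original frame
#' order; the selected row indices are attached so a run can be replayed.
#'
#' @param ds A [conformation_dataset()].
#' @param spec A [split_spec()].
#' @return List with elements `train` and `test` (both
#'   [conformation_dataset()]s) plus `train_idx` and `test_idx`, the row
#'   indices of each side in the original dataset.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n = 100, d = 4, minority_count = 20,
#'                                       seed = 1))
#' sp <- stratified_split(ds, split_spec(0.30, seed = 7))
#' sum(sp$train$labels)  # 6 = round(0.30 * 20)
#' @export
stratified_split <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "conformation_dataset"), inherits(spec, "split_spec"))
  n <- nrow(ds$features)
  tab <- table(factor(ds$labels, levels = c(0, 1)))
  if (any(tab < 2L))
    stop_("each class needs at least 2 rows to split (binding: %d, non-binding: %d)",
          tab[["1"]], tab[["0"]])
  n_train <- as.integer(round(spec$train_fraction * n))
  if (n_train < 1L || n_train >= n)
    stop_("train fraction %.3f leaves an empty train or test side for n = %d",
          spec$train_fraction, n)
  idx_train <- with_seed(spec$seed, {
    if (spec$stratified) {
      counts <- largest_remainder(as.numeric(tab), n_train)
      take0 <- sample(which(ds$labels == 0L), counts[1])
      take1 <- sample(which(ds$labels == 1L), counts[2])
      sort(c(take0, take1))
    } else {
      sort(sample.int(n, n_train))
    }
  })
  idx_test <- setdiff(seq_len(n), idx_train)
  sub <- function(idx) conformation_dataset(
    ds$features[idx, , drop = FALSE], ds$labels[idx],
    name = ds$name, feature_names = ds$feature_names)
  list(train = sub(idx_train), test = sub(idx_test),
       train_idx = idx_train, test_idx = idx_test)
}
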