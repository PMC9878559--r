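# Four univariate feature scorers and the consensus vote that intersects
# their top-x lists. Each scorer returns a `feature_ranking`; the
# consensus keeps the descriptors selected by at least `threshold` of the
# four methods.

new_feature_ranking <- function(method, scores, top_x) {
  top_x <- check_count(top_x, "top_x")
  # stable ordering: score descending, ties by original column order
  ord <- order(-scores, seq_along(scores))
  k <- min(top_x, length(scores))
  structure(list(method = method, scores = scores, top_x = top_x,
                 selected = names(scores)[ord[seq_len(k)]]),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> method = %s, %d features, top_x = %d\n",
              x$method, length(x$scores), x$top_x))
  top <- x$scores[x$selected]
  cat("  selected:", paste(sprintf("%s (%.4g)", names(top), top),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_ranking <- function(x, ...) {
  ord <- order(-x$scores, seq_along(x$scores))
  data.frame(feature = names(x$scores)[ord], method = x$method,
             score = unname(x$scores)[ord], rank = seq_along(x$scores),
             selected = names(x$scores)[ord] %in% x$selected,
             row.names = NULL)
}

#' One-way ANOVA F feature scores
#'
#' Scores each descriptor by the one-way F statistic between the binding
#' and non-binding groups: between-group mean square over within-group
#' mean square. A descriptor identical in distribution across classes
#' scores near 0; a descriptor whose class means separate cleanly scores
#' high. A degenerate descriptor with zero within-group variance scores
#' `Inf` when the class means differ and 0 when they do not.
#'
#' @param ds A [conformation_dataset()] with both classes present.
#' @param top_x Number of features to retain (default 15; the published
#'   protocol leaves this to the user).
#' @return Object of class `feature_ranking`: fields `method`, `scores`
#'   (named, in column order), `top_x`, and `selected` (top features by
#'   score, ties broken by column order).
#' @examples
#' # groups {1,2,3} vs {2,3,4}: F = 1.5
#' ds <- conformation_dataset(matrix(c(1, 2, 3, 2, 3, 4), ncol = 1,
#'                                   dimnames = list(NULL, "f")),
#'                            labels = c(0, 0, 0, 1, 1, 1))
#' anova_f_scores(ds)$scores
#' @export
anova_f_scores <- function(ds, top_x = 15L) {
  stopifnot(inherits(ds, "conformation_dataset"))
  check_two_classes(ds, "ANOVA F scoring")
  y <- ds$labels
  x <- ds$features
  n <- nrow(x)
  i0 <- y == 0L; i1 <- y == 1L
  n0 <- sum(i0); n1 <- sum(i1)
  m0 <- colMeans(x[i0, , drop = FALSE])
  m1 <- colMeans(x[i1, , drop = FALSE])
  gm <- colMeans(x)
  ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
  ssw <- colSums(sweep(x[i0, , drop = FALSE], 2, m0)^2) +
         colSums(sweep(x[i1, , drop = FALSE], 2, m1)^2)
  msb <- ssb / 1
  msw <- ssw / (n - 2)
  f <- ifelse(msw == 0, ifelse(msb == 0, 0, Inf), msb / msw)
  new_feature_ranking("anova", stats::setNames(f, ds$feature_names), top_x)
}

# quantile binning with degenerate-tie handling; features with at most
# `bins` distinct values are binned by value so that, e.g., a binary
# descriptor keeps both levels rather than collapsing into one interval
discretize_feature <- function(x, bins) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Mutual-information feature scores
#'
#' Estimates `I(feature; label)` in nats for each descriptor by
#' equal-frequency (quantile) binning of the descriptor and the plug-in
#' double sum `I = sum_u sum_v p(u,v) log(p(u,v) / (p(u) p(v)))` against
#' the discrete 0/1 label. Mutual information is non-negative by
#' definition and is 0 when descriptor and label are independent. A
#' constant descriptor occupies a single bin and scores 0.
#'
#' @param ds A [conformation_dataset()].
#' @param bins Number of quantile bins for the descriptor (default 10).
#' @param top_x Number of features to retain (default 15).
#' @return A `feature_ranking` (see [anova_f_scores()]).
#' @export
mutual_information_scores <- function(ds, bins = 10L, top_x = 15L) {
  stopifnot(inherits(ds, "conformation_dataset"))
  check_two_classes(ds, "mutual-information scoring")
  bins <- check_count(bins, "bins", min = 2L)
  n <- nrow(ds$features)
  if (n < bins) stop_("need at least `bins` = %d rows (got %d)", bins, n)
  y <- ds$labels
  scores <- vapply(seq_len(ncol(ds$features)), function(j) {
    u <- discretize_feature(ds$features[, j], bins)
    joint <- table(u, y) / n
    pu <- rowSums(joint); pv <- colSums(joint)
    pos <- joint > 0
    sum(joint[pos] * log(joint[pos] / outer(pu, pv)[pos]))
  }, numeric(1))
  new_feature_ranking("mi", stats::setNames(scores, ds$feature_names), top_x)
}

#' Spearman-correlation feature scores
#'
#' Scores each descriptor by the absolute Spearman rank correlation with
#' the binding label: the Pearson correlation of the rank-transformed
#' descriptor with the rank-transformed label (average ranks on ties),
#' which captures the strength of any monotone relationship. Features are
#' ranked by `|rho|`; a constant descriptor has undefined correlation and
#' scores 0 with a warning.
#'
#' @param ds A [conformation_dataset()] with both classes and `n >= 3`.
#' @param top_x Number of features to retain (default 15).
#' @return A `feature_ranking` whose scores are `|rho|`; the signed
#'   correlations are kept in attribute `"rho"`.
#' @export
spearman_scores <- function(ds, top_x = 15L) {
  stopifnot(inherits(ds, "conformation_dataset"))
  check_two_classes(ds, "Spearman scoring")
  if (nrow(ds$features) < 3L) stop_("need at least 3 rows")
  y <- rank(ds$labels)
  rho <- vapply(seq_len(ncol(ds$features)), function(j) {
    x <- ds$features[, j]
    if (stats::sd(x) == 0) {
      warning(sprintf("constant feature '%s': Spearman correlation undefined, scored 0",
                      ds$feature_names[j]), call. = FALSE)
      return(0)
    }
    stats::cor(rank(x), y)
  }, numeric(1))
  scores <- stats::setNames(abs(rho), ds$feature_names)
  out <- new_feature_ranking("spearman", scores, top_x)
  attr(out, "rho") <- stats::setNames(rho, ds$feature_names)
  out
}

#' Consensus vote over the four feature rankings
#'
#' Each feature receives one vote per ranking whose `selected` list
#' contains it (0–4); features with at least `threshold` votes form the
#' consensus set, in original column order. The strict intersection
#' (`threshold = 4`) is the default; `threshold = 3` is the documented
#' relaxation for datasets where the strict intersection is too small.
#' An empty consensus is returned as-is — callers decide the fallback.
#'
#' @param rankings List of `feature_ranking`s over the same feature set
#'   (typically ANOVA, MI, RQA entropy, Spearman).
#' @param threshold Minimum votes for selection, between 1 and
#'   `length(rankings)`. Default 4.
#' @return Object of class `consensus_score`: fields `votes` (named
#'   integer vector in column order), `threshold`, `selected`.
#' @export
consensus_select <- function(rankings, threshold = 4L) {
  if (inherits(rankings, "feature_ranking")) rankings <- list(rankings)
  stopifnot(all(vapply(rankings, inherits, logical(1), "feature_ranking")))
  threshold <- check_count(threshold, "threshold")
  if (threshold > length(rankings))
    stop_("threshold (%d) exceeds the number of rankings (%d)",
          threshold, length(rankings))
  feats <- names(rankings[[1]]$scores)
  for (r in rankings[-1])
    if (!setequal(names(r$scores), feats))
      stop_("rankings cover different feature sets ('%s' vs '%s')",
            rankings[[1]]$method, r$method)
  votes <- stats::setNames(integer(length(feats)), feats)
  for (r in rankings) votes[r$selected] <- votes[r$selected] + 1L
  structure(list(votes = votes, threshold = threshold,
                 selected = feats[votes >= threshold],
                 methods = vapply(rankings, `[[`, character(1), "method")),
            class = "consensus_score")
}

#' @export
print.consensus_score <- function(x, ...) {
  cat(sprintf("<consensus_score> threshold %d of %d methods (%s)\n",
              x$threshold, length(x$methods), paste(x$methods, collapse = ", ")))
  if (length(x$selected))
    cat(sprintf("  %d features selected: %s\n", length(x$selected),
                paste(x$selected, collapse = ", ")))
  else cat("  no feature reached the threshold\n")
  invisible(x)
}

#' @export
as.data.frame.consensus_score <- function(x, ...) {
  data.frame(feature = names(x$votes), votes = unname(x$votes),
             selected = names(x$votes) %in% x$selected, row.names = NULL)
}

#' Run all four scorers on a dataset
#'
#' Convenience wrapper producing the ANOVA, mutual-information,
#' recurrence-entropy and Spearman rankings with shared `top_x`.
#'
#' @param ds A [conformation_dataset()].
#' @param top_x Features retained per method (default 15).
#' @param mi_bins Quantile bins for mutual information (default 10).
#' @param rqa_cfg An [rqa_config()].
#' @return Named list of four `feature_ranking`s.
#' @export
score_features <- function(ds, top_x = 15L, mi_bins = 10L,
                           rqa_cfg = rqa_config()) {
  list(anova = anova_f_scores(ds, top_x = top_x),
       mi = mutual_information_scores(ds, bins = mi_bins, top_x = top_x),
       rqa = rqa_entropy_scores(ds, cfg = rqa_cfg, top_x = top_x),
       spearman = spearman_scores(ds, top_x = top_x))
}
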