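# Enrichment-ratio evaluation: how much better the cascade's predicted
# binding conformations are than random selection, measured on ranked
# subsets of the truly binding (TP + FN) conformations.

#' Base enrichment ratio
#'
#' Fraction of binding conformations in an evaluation set — the hit rate
#' random selection would achieve.
#'
#' @param labels 0/1 label vector with at least one binding (1) label.
#' @return Proportion in (0, 1\].
#' @export
base_enrichment_ratio <- function(labels) {
  labels <- check_binary_vector(labels, "labels")
  if (length(labels) == 0L) stop_("`labels` is empty")
  if (sum(labels) == 0L)
    stop_("no binding conformations: base enrichment ratio is undefined")
  sum(labels) / length(labels)
}

#' ML enrichment ratio
#'
#' Correctly identified binding conformations over all binding
#' conformations considered: `tp / (tp + fn)`.
#'
#' @param tp,fn Non-negative TP and FN counts, `tp + fn > 0`.
#' @return Proportion in \[0, 1\].
#' @export
ml_enrichment_ratio <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop_("counts must be non-negative")
  if (tp + fn == 0) stop_("tp + fn must be positive")
  tp / (tp + fn)
}

#' Final enrichment ratio
#'
#' Fold-improvement of the classifier's hit rate over random selection:
#' `ml / base`. Equals 1 when the classifier does no better than random
#' and is capped at `1 / base` (a perfect classifier).
#'
#' @param ml ML enrichment ratio in \[0, 1\].
#' @param base Base enrichment ratio in (0, 1\].
#' @return Non-negative ratio.
#' @export
final_enrichment_ratio <- function(ml, base) {
  if (base <= 0) stop_("base enrichment ratio must be positive")
  ml / base
}

#' Data-selection filter for the enrichment framework
#'
#' A filter orders the truly binding conformations (the TP and FN
#' predictions) by a score and keeps a top percentage. The four named
#' defaults in [default_filters()] are this package's reconstruction of
#' the published filter labels A–D, which were defined in earlier work and
#' are configurable here: A ranks by the stage-2 probability best-first,
#' B by the stage-1 probability best-first, C by the mean of both
#' best-first, and D by the stage-2 probability worst-first (a
#' pessimistic control). Any numeric column of the prediction set (e.g.
#' an external docking score attached by the caller) can serve as
#' `ranking_key`.
#'
#' @param id Filter label (e.g. `"A"`).
#' @param ranking_key Column of the prediction set to rank on, or
#'   `"mean"` for the mean of `prob` and `stage1_prob`.
#' @param direction `"desc"` (best-first, default) or `"asc"`.
#' @param percent Percentage of the ranked set kept, in (0, 100\].
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(id, ranking_key = "prob", direction = c("desc", "asc"),
                        percent = 1.0) {
  direction <- match.arg(direction)
  if (!is.numeric(percent) || percent <= 0 || percent > 100)
    stop_("percent must be in (0, 100]")
  structure(list(id = as.character(id), ranking_key = ranking_key,
                 direction = direction, percent = as.numeric(percent)),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
default_filters <- function() {
  list(filter_spec("A", "prob", "desc"),
       filter_spec("B", "stage1_prob", "desc"),
       filter_spec("C", "mean", "desc"),
       filter_spec("D", "prob", "asc"))
}

filter_key_values <- function(preds, key) {
  if (identical(key, "mean")) {
    if (!"stage1_prob" %in% names(preds))
      stop_("ranking_key 'mean' needs a `stage1_prob` column in the prediction set")
    return(rowMeans(cbind(preds$prob, preds$stage1_prob)))
  }
  if (!key %in% names(preds))
    stop_("ranking_key '%s' is not a column of the prediction set", key)
  as.numeric(preds[[key]])
}

#' Apply a data-selection filter to a prediction set
#'
#' Restricts the prediction set to the truly binding conformations
#' (TP and FN), orders them by the filter's ranking key, keeps the top
#' `ceiling(percent/100 * n)` rows (at least one; ties broken by stable
#' row order), and tallies TP and FN within the kept subset.
#'
#' @param preds A [prediction_set()] containing at least one
#'   truth-positive row.
#' @param f A [filter_spec()].
#' @return Named list with `tp`, `fn`, and `kept` (subset size).
#' @export
apply_filter <- function(preds, f) {
  stopifnot(inherits(preds, "prediction_set"), inherits(f, "filter_spec"))
  pos <- preds[preds$truth == 1L, , drop = FALSE]
  if (nrow(pos) == 0L)
    stop_("no truly binding conformations in the prediction set")
  key <- filter_key_values(pos, f$ranking_key)
  ord <- if (f$direction == "desc") order(-key, seq_along(key))
         else order(key, seq_along(key))
  k <- max(1L, as.integer(ceiling(f$percent / 100 * nrow(pos))))
  kept <- pos[ord[seq_len(k)], , drop = FALSE]
  list(tp = sum(kept$hard == 1L), fn = sum(kept$hard == 0L), kept = k)
}

#' Enrichment report over a filter/percentage grid
#'
#' Evaluates every (filter, percentage) cell: the filter selects a ranked
#' subset of the truly binding conformations, and the cell records the
#' TP/FN tally, the ML enrichment ratio, the base enrichment ratio of the
#' evaluation set, and their quotient (the final enrichment ratio). The
#' report also identifies the maxima and minima over all cells, mirroring
#' the customary summary layout.
#'
#' @param preds A [prediction_set()].
#' @param base_labels 0/1 labels of the evaluation set defining the base
#'   enrichment ratio (typically `preds$truth`).
#' @param filters List of [filter_spec()]s (default [default_filters()]).
#' @param percents Percentages evaluated per filter (default
#'   `c(0.5, 1, 5, 10)`).
#' @param classifier Text tag stored with the report.
#' @return Object of class `enrichment_report`: a list with `cells`
#'   (data frame, one row per filter x percentage), `base_ratio`,
#'   `maxima`, `minima`, `classifier`.
#' @export
enrichment_report <- function(preds, base_labels = preds$truth,
                              filters = default_filters(),
                              percents = c(0.5, 1, 5, 10),
                              classifier = "classifier") {
  stopifnot(inherits(preds, "prediction_set"))
  base <- base_enrichment_ratio(base_labels)
  rows <- list()
  for (f in filters) {
    for (pct in percents) {
      fp <- f; fp$percent <- pct
      res <- apply_filter(preds, fp)
      ml <- ml_enrichment_ratio(res$tp, res$fn)
      rows[[length(rows) + 1L]] <- data.frame(
        filter = f$id, ranking_key = f$ranking_key, direction = f$direction,
        percent = pct, kept = res$kept, tp = res$tp, fn = res$fn,
        ml_ratio = ml, base_ratio = base,
        final_ratio = final_enrichment_ratio(ml, base))
    }
  }
  cells <- do.call(rbind, rows)
  imax <- which.max(cells$final_ratio)
  imin <- which.min(cells$final_ratio)
  pick <- function(i) list(final_ratio = cells$final_ratio[i],
                           filter = cells$filter[i], percent = cells$percent[i])
  structure(list(cells = cells, base_ratio = base, maxima = pick(imax),
                 minima = pick(imin), classifier = classifier),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report> %s | base ratio %.4f | %d cells\n",
              x$classifier, x$base_ratio, nrow(x$cells)))
  cat(sprintf("  maxima %.1f (filter %s, %.1f%% of data)   minima %.1f (filter %s, %.1f%% of data)\n",
              x$maxima$final_ratio, x$maxima$filter, x$maxima$percent,
              x$minima$final_ratio, x$minima$filter, x$minima$percent))
  invisible(x)
}

#' @export
as.data.frame.enrichment_report <- function(x, ...) {
  cbind(classifier = x$classifier, x$cells)
}
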