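# Recurrence quantification of frame-ordered descriptor series. Each
# descriptor column is read as a univariate series over MD frame order;
# its recurrence matrix R(i,k) = 1 iff states i and k fall within a
# radius of each other, and the Shannon entropy of the distribution of
# diagonal line lengths (ENTR) quantifies how deterministic the series'
# recurrences are.

#' Recurrence-analysis configuration
#'
#' @param radius Recurrence threshold as a fraction of the series'
#'   standard deviation (default 0.2).
#' @param jmin Minimum diagonal line length counted (default 2).
#' @param embedding_dim Time-delay embedding dimension (default 1 = no
#'   embedding; state distance is then Euclidean over the embedded
#'   coordinates).
#' @param delay Embedding delay in frames (default 1).
#' @param normalize Z-score the series before thresholding (default
#'   `TRUE`), making the analysis scale-invariant.
#' @return Object of class `rqa_config`.
#' @export
rqa_config <- function(radius = 0.2, jmin = 2L, embedding_dim = 1L,
                       delay = 1L, normalize = TRUE) {
  if (!is.numeric(radius) || radius <= 0) stop_("radius must be > 0")
  structure(list(radius = as.numeric(radius),
                 jmin = check_count(jmin, "jmin", min = 2L),
                 embedding_dim = check_count(embedding_dim, "embedding_dim"),
                 delay = check_count(delay, "delay"),
                 normalize = isTRUE(normalize)),
            class = "rqa_config")
}

# time-delay embedding: rows are states (x_i, x_{i+tau}, ..., x_{i+(m-1)tau})
embed_series <- function(x, m, tau) {
  M <- length(x) - (m - 1L) * tau
  if (M < 1L) stop_("series too short for embedding dimension %d, delay %d", m, tau)
  sapply(seq_len(m), function(c) x[seq_len(M) + (c - 1L) * tau])
}

#' Diagonal-line census of a recurrence matrix
#'
#' Builds the recurrence structure of a frame-ordered series and counts
#' maximal diagonal line segments of each length, excluding the main
#' diagonal (Theiler window 1; the symmetric lower triangle mirrors the
#' upper one, so only offsets >= 1 are counted). Two states recur when
#' their (Euclidean, if embedded) distance is at most
#' `radius * sd(series)` — after z-scoring when `normalize` is on.
#'
#' A constant series under `normalize = TRUE` has no scale to z-score
#' against and is treated as all-recurrent: every diagonal is one maximal
#' line spanning its full length.
#'
#' @param series Numeric vector, frame-ordered.
#' @param cfg An [rqa_config()].
#' @return Named integer vector mapping diagonal length (as name) to the
#'   number of maximal segments of that length, restricted to lengths
#'   `>= jmin`; empty when no such line exists.
#' @export
recurrence_diagonals <- function(series, cfg = rqa_config()) {
  stopifnot(inherits(cfg, "rqa_config"))
  series <- as.numeric(series)
  if (anyNA(series)) stop_("series contains missing values")
  if (length(series) < cfg$jmin)
    stop_("series length %d is below jmin = %d", length(series), cfg$jmin)
  s <- stats::sd(series)
  if (cfg$normalize) {
    if (s == 0) {
      # constant series: all-recurrent matrix; one maximal line per diagonal
      M <- length(series) - (cfg$embedding_dim - 1L) * cfg$delay
      lens <- seq(M - 1L, 1L)
      lens <- lens[lens >= cfg$jmin]
      return(stats::setNames(rep(1L, length(lens)), lens))
    }
    series <- (series - mean(series)) / s
    eps <- cfg$radius
  } else {
    eps <- cfg$radius * s
  }
  x <- if (cfg$embedding_dim > 1L)
    embed_series(series, cfg$embedding_dim, cfg$delay)
  else matrix(series, ncol = 1L)
  counts <- rqa_census_cpp(x, eps, cfg$jmin)
  lens <- which(counts > 0L)
  lens <- lens[lens >= cfg$jmin]
  stats::setNames(counts[lens], lens)
}

# ENTR of a diagonal census: Shannon entropy (nats) of p(j)
diag_entropy <- function(census) {
  if (length(census) == 0L || sum(census) == 0L) return(0)
  p <- census / sum(census)
  -sum(p * log(p))
}

#' Recurrence-entropy feature scores
#'
#' Scores every descriptor by the Shannon entropy (in nats) of its
#' diagonal-line-length distribution, `ENTR = -sum_j p(j) log p(j)` with
#' `p(j)` the proportion of maximal diagonal lines of length `j >= jmin`
#' in the descriptor's recurrence matrix over frame order. Descriptors
#' whose frame-to-frame dynamics revisit states in structured ways (the
#' signature of slow conformational modes) score high; a descriptor with
#' no qualifying diagonal line scores 0. This is the only scorer that
#' uses frame order rather than the class labels.
#'
#' @param ds A [conformation_dataset()] (row order = frame order).
#' @param cfg An [rqa_config()].
#' @param top_x Number of features to retain (default 15).
#' @return A `feature_ranking` (see [anova_f_scores()]).
#' @export
rqa_entropy_scores <- function(ds, cfg = rqa_config(), top_x = 15L) {
  stopifnot(inherits(ds, "conformation_dataset"))
  scores <- vapply(seq_len(ncol(ds$features)), function(j)
    diag_entropy(recurrence_diagonals(ds$features[, j], cfg)), numeric(1))
  new_feature_ranking("rqa", stats::setNames(scores, ds$feature_names), top_x)
}
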