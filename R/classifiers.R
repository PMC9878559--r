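# Stage-1 gradient-boosted trees (xgboost) and the shared prediction-set
# representation used by both stages and by the enrichment framework.

#' Build a prediction set
#'
#' A prediction set pairs each evaluated conformation with its true
#' label, predicted binding probability, hard label at a threshold
#' (`>= threshold` maps to class 1), and confusion category (TP/TN/FP/FN).
#' Additional score columns (e.g. the stage-1 probability alongside the
#' stage-2 one) may be attached for the enrichment filters to rank on.
#'
#' @param truth 0/1 vector of true labels.
#' @param prob Predicted probabilities in \[0, 1\], same length.
#' @param threshold Hard-label threshold (default 0.5).
#' @param row Optional row identifiers (default sequence).
#' @param ... Further numeric score columns of the same length.
#' @return A data frame of class `prediction_set` with columns `row`,
#'   `truth`, `prob`, `hard`, `category`, and any extra score columns;
#'   the threshold is kept as attribute `"threshold"`.
#' @export
prediction_set <- function(truth, prob, threshold = 0.5, row = NULL, ...) {
  truth <- check_binary_vector(truth, "truth")
  prob <- as.numeric(prob)
  if (length(prob) != length(truth))
    stop_("`prob` and `truth` differ in length")
  if (anyNA(prob) || any(prob < 0 | prob > 1))
    stop_("`prob` must lie in [0, 1] with no missing values")
  if (is.null(row)) row <- seq_along(truth)
  hard <- as.integer(prob >= threshold)
  category <- ifelse(truth == 1L, ifelse(hard == 1L, "TP", "FN"),
                     ifelse(hard == 1L, "FP", "TN"))
  out <- data.frame(row = row, truth = truth, prob = prob, hard = hard,
                    category = category, ...)
  attr(out, "threshold") <- threshold
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' @export
print.prediction_set <- function(x, ...) {
  cc <- confusion_counts(x$truth, x$hard)
  cat(sprintf("<prediction_set> %d conformations, threshold %.2f\n",
              nrow(x), attr(x, "threshold")))
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d | accuracy %.3f",
              cc$tp, cc$tn, cc$fp, cc$fn, accuracy(cc)))
  if (cc$tp + cc$fn > 0) cat(sprintf(", sensitivity %.3f", sensitivity(cc)))
  cat("\n")
  invisible(x)
}

# confusion counts straight off a prediction set
pred_confusion <- function(preds) confusion_counts(preds$truth, preds$hard)

check_feature_match <- function(model_names, ds) {
  if (!identical(model_names, ds$feature_names)) {
    missing <- setdiff(model_names, ds$feature_names)
    extra <- setdiff(ds$feature_names, model_names)
    msg <- "dataset features do not match the classifier's training features"
    if (length(missing)) msg <- paste0(msg, "; missing: ",
                                       paste(missing, collapse = ", "))
    if (length(extra)) msg <- paste0(msg, "; unexpected: ",
                                     paste(extra, collapse = ", "))
    if (!length(missing) && !length(extra))
      msg <- paste0(msg, "; same names in a different order")
    stop_("%s", msg)
  }
}

#' Train the stage-1 gradient-boosted tree classifier
#'
#' Fits a gradient-boosted tree ensemble (additive CART models trained
#' against a regularized logistic objective, via the xgboost library) on
#' the raw, imbalanced training split. Its role in the cascade is to flag
#' which majority rows it handles correctly (TN) — those form the pool the
#' K-Means undersampler draws from — and to supply the stage-1 probability
#' used by enrichment filter rankings.
#'
#' @param train A [conformation_dataset()] with both classes.
#' @param params Named list of xgboost parameters overriding the defaults
#'   (`eta = 0.3`, `max_depth = 6`, `nthread = 1`).
#' @param nrounds Boosting rounds (default 100).
#' @param seed Integer seed.
#' @return Object of class `stage1_classifier`.
#' @export
train_stage1 <- function(train, params = list(), nrounds = 100L, seed = 1L) {
  stopifnot(inherits(train, "conformation_dataset"))
  check_two_classes(train, "stage-1 training")
  defaults <- list(objective = "binary:logistic", eta = 0.3, max_depth = 6L,
                   nthread = 1L, eval_metric = "logloss")
  p <- utils::modifyList(defaults, params)
  booster <- with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(train$features, label = train$labels)
    xgboost::xgb.train(params = p, data = dtrain,
                       nrounds = check_count(nrounds, "nrounds"), verbose = 0)
  })
  structure(list(booster = booster, feature_names = train$feature_names,
                 params = p, nrounds = nrounds, seed = seed),
            class = "stage1_classifier")
}

#' @export
print.stage1_classifier <- function(x, ...) {
  cat(sprintf("<stage1_classifier> gradient-boosted trees: %d rounds, depth %d, %d features\n",
              x$nrounds, x$params$max_depth, length(x$feature_names)))
  invisible(x)
}

#' @rdname train_stage1
#' @param object A `stage1_classifier`.
#' @param ds Dataset to score; feature names and order must match training.
#' @param threshold Hard-label threshold (default 0.5; `prob >= threshold`
#'   is class 1).
#' @param ... Unused.
#' @export
predict.stage1_classifier <- function(object, ds, threshold = 0.5, ...) {
  stopifnot(inherits(ds, "conformation_dataset"))
  check_feature_match(object$feature_names, ds)
  prob <- predict(object$booster, xgboost::xgb.DMatrix(ds$features))
  prediction_set(ds$labels, prob, threshold = threshold)
}

#' Stage-1 classification result with TN/TP row records
#'
#' Scores a dataset with the stage-1 classifier and records which rows it
#' classified correctly in each class: the TN rows feed the majority
#' undersampler, the TP rows document the correctly detected binding
#' conformations.
#'
#' @param handle A `stage1_classifier`.
#' @param ds Dataset to score.
#' @param threshold Hard-label threshold (default 0.5).
#' @return List with `predictions` (a [prediction_set()]), `tn_rows`, and
#'   `tp_rows` (integer row indices into `ds`).
#' @export
stage_one_result <- function(handle, ds, threshold = 0.5) {
  preds <- predict(handle, ds, threshold = threshold)
  list(predictions = preds,
       tn_rows = which(preds$category == "TN"),
       tp_rows = which(preds$category == "TP"))
}

#' Stage-2 network configuration
#'
#' Hyperparameters of the two stage-2 deep classifiers. The CNN is a 1-D
#' convolution over the ordered descriptor vector (ReLU), dropout, max
#' pooling, a dense ReLU layer and a sigmoid output; the RNN consumes the
#' descriptor vector as a length-d sequence through two LSTM layers with
#' dropout (ReLU cell activations), a dense ReLU layer with dropout and a
#' sigmoid output. Both train with binary cross-entropy and Adam.
#'
#' @param conv_filters CNN convolution filters (default 32).
#' @param kernel CNN kernel length (default 3).
#' @param pool CNN max-pooling length (default 2).
#' @param dense CNN dense-layer width (default 64).
#' @param rnn_units Widths of the two LSTM layers (default `c(64, 64)`).
#' @param rnn_dense RNN dense-layer width (default 32).
#' @param dropout Dropout rate for both networks (default 0.2).
#' @param epochs Training epochs (default 100).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param threshold Hard-label threshold (default 0.5).
#' @param seed Integer seed.
#' @return Object of class `net_config`.
#' @export
net_config <- function(conv_filters = 32L, kernel = 3L, pool = 2L,
                       dense = 64L, rnn_units = c(64L, 64L), rnn_dense = 32L,
                       dropout = 0.2, epochs = 100L, batch_size = 32L,
                       learning_rate = 1e-3, threshold = 0.5, seed = 1L) {
  if (dropout < 0 || dropout >= 1) stop_("dropout must be in [0, 1)")
  stopifnot(length(rnn_units) == 2L)
  structure(list(conv_filters = check_count(conv_filters, "conv_filters"),
                 kernel = check_count(kernel, "kernel"),
                 pool = check_count(pool, "pool"),
                 dense = check_count(dense, "dense"),
                 rnn_units = vapply(rnn_units, check_count, integer(1),
                                    name = "rnn_units"),
                 rnn_dense = check_count(rnn_dense, "rnn_dense"),
                 dropout = as.numeric(dropout),
                 epochs = check_count(epochs, "epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 learning_rate = as.numeric(learning_rate),
                 threshold = as.numeric(threshold),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "net_config")
}
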