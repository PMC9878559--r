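#' Fit the two-stage imbalance-aware classification cascade
#'
#' The cascade is the package's central model. Stage 1 fits
#' gradient-boosted trees ([train_stage1()]) on the raw, imbalanced
#' training split and records which majority rows it classifies
#' correctly (TN). The training split is then rebuilt under the
#' equal-size contract ([rebalance()]): every real binding row is kept,
#' a GAN trained on the binding rows generates the rest of the planned
#' minority share, and the majority share is K-Means-undersampled from
#' the stage-1 TN pool. Stage 2 fits the requested deep classifiers
#' (1-D CNN and/or LSTM) on the rebuilt, balanced set.
#'
#' @param train A [conformation_dataset()] training split with both
#'   classes (already feature-selected, if selection is in use).
#' @param stage2 Which stage-2 tracks to fit: `"cnn"`, `"rnn"`, or
#'   `"both"` (default).
#' @param plan A [resampling_plan()].
#' @param gan_cfg A [gan_config()].
#' @param net_cfg A [net_config()] shared by both tracks.
#' @param xgb_params,nrounds Stage-1 boosting parameters (see
#'   [train_stage1()]).
#' @param gate_majority Restrict undersampling to the stage-1 TN pool
#'   (default `TRUE`; `FALSE` draws from all majority rows).
#' @param seed Master seed; stage seeds are derived from it
#'   deterministically, overriding the seeds inside `plan`, `gan_cfg`
#'   and `net_cfg`.
#' @return Object of class `cascade_fit` with elements `stage1`,
#'   `stage1_result`, `rebuilt` (the rebalanced training set), `models`
#'   (named list of stage-2 classifiers), and the configurations used.
#' @seealso [predict.cascade_fit()], [run_pipeline()]
#' @examples
#' \donttest{
#' ds <- generate_dataset(preset_spec("PLANTED", effect_size = 2))
#' sp <- stratified_split(ds, split_spec(0.30, seed = 1))
#' fit <- cascade_fit(sp$train, stage2 = "cnn",
#'                    net_cfg = net_config(epochs = 20), seed = 1)
#' preds <- predict(fit, sp$test, track = "cnn")
#' }
#' @export
cascade_fit <- function(train, stage2 = c("both", "cnn", "rnn"),
                        plan = resampling_plan(), gan_cfg = gan_config(),
                        net_cfg = net_config(), xgb_params = list(),
                        nrounds = 100L, gate_majority = TRUE, seed = 1L) {
  stopifnot(inherits(train, "conformation_dataset"))
  stage2 <- match.arg(stage2)
  tracks <- if (stage2 == "both") c("cnn", "rnn") else stage2
  plan$seed <- derive_seed(seed, "plan")
  gan_cfg$seed <- derive_seed(seed, "gan")
  stage1 <- train_stage1(train, params = xgb_params, nrounds = nrounds,
                         seed = derive_seed(seed, "stage1"))
  s1 <- stage_one_result(stage1, train, threshold = net_cfg$threshold)
  rebuilt <- rebalance(train, plan, gan_cfg,
                       majority_pool = if (gate_majority) s1$tn_rows)
  models <- list()
  for (tr in tracks) {
    cfg <- net_cfg
    cfg$seed <- derive_seed(seed, paste0("net_", tr))
    models[[tr]] <- if (tr == "cnn") train_cnn(rebuilt, cfg)
                    else train_rnn(rebuilt, cfg)
  }
  structure(list(stage1 = stage1, stage1_result = s1, rebuilt = rebuilt,
                 models = models, plan = plan, gan_cfg = gan_cfg,
                 net_cfg = net_cfg, gate_majority = gate_majority,
                 seed = seed, feature_names = train$feature_names,
                 n_train = nrow(train$features)),
            class = "cascade_fit")
}

#' Predict with a fitted cascade
#'
#' Scores a dataset with one stage-2 track and attaches the stage-1
#' probability as an extra column (`stage1_prob`), which the enrichment
#' filters can rank on.
#'
#' @param object A [cascade_fit()].
#' @param ds Dataset to score (same features as training).
#' @param track `"cnn"` or `"rnn"`; default the first fitted track.
#' @param threshold Hard-label threshold; default the network config's.
#' @param ... Unused.
#' @return A [prediction_set()] with extra column `stage1_prob`.
#' @export
predict.cascade_fit <- function(object, ds, track = NULL, threshold = NULL,
                                ...) {
  if (is.null(track)) track <- names(object$models)[1]
  if (!track %in% names(object$models))
    stop_("track '%s' was not fitted (available: %s)", track,
          paste(names(object$models), collapse = ", "))
  if (is.null(threshold)) threshold <- object$net_cfg$threshold
  p2 <- predict(object$models[[track]], ds, threshold = threshold)
  p1 <- predict(object$stage1, ds, threshold = threshold)
  prediction_set(p2$truth, p2$prob, threshold = threshold, row = p2$row,
                 stage1_prob = p1$prob)
}

#' @export
print.cascade_fit <- function(x, ...) {
  cat(sprintf("<cascade_fit> trained on %d rows x %d descriptors (seed %d)\n",
              x$n_train, length(x$feature_names), x$seed))
  prov <- table(x$rebuilt$provenance, x$rebuilt$labels)
  cat(sprintf("  rebuilt training set: %d rows (%d binding: %d real + %d generated; %d non-binding)\n",
              nrow(x$rebuilt$features), sum(x$rebuilt$labels == 1L),
              sum(x$rebuilt$provenance == "real" & x$rebuilt$labels == 1L),
              sum(x$rebuilt$provenance == "generated"),
              sum(x$rebuilt$labels == 0L)))
  cat(sprintf("  stage-2 tracks: %s\n", paste(names(x$models), collapse = ", ")))
  invisible(x)
}

#' @export
summary.cascade_fit <- function(object, ds = NULL, ...) {
  print(object)
  s1cc <- pred_confusion(object$stage1_result$predictions)
  cat(sprintf("  stage-1 on its training split: accuracy %.3f, sensitivity %.3f\n",
              accuracy(s1cc), sensitivity(s1cc)))
  if (!is.null(ds)) {
    for (tr in names(object$models)) {
      cc <- pred_confusion(predict(object, ds, track = tr))
      cat(sprintf("  %s track on supplied data: accuracy %.3f, sensitivity %.3f\n",
                  tr, accuracy(cc), sensitivity(cc)))
    }
  }
  invisible(object)
}
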