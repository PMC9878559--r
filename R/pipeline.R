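# End-to-end orchestration: load or generate a descriptor table, score
# and consensus-select features, split 30/70, fit the two-stage cascade,
# score the held-out 70%, and evaluate enrichment per stage-2 track.

#' Pipeline configuration
#'
#' Bundles every knob of an end-to-end run. All stochastic stages derive
#' their seeds deterministically from `seed`, so one master seed fixes
#' the whole run.
#'
#' @param input Path to a CSV dataset, or `NULL` to generate `preset`.
#' @param preset Synthetic preset name (see [preset_spec()]) used when
#'   `input` is `NULL`. Default `"PLANTED"`.
#' @param effect_size Planted effect size when generating a preset.
#' @param label_column Label column name for CSV input.
#' @param train_fraction,stratified Split protocol (default 0.30,
#'   stratified).
#' @param feature_selection Run the four scorers and consensus projection
#'   (default `TRUE`); `FALSE` trains on the full descriptor table.
#' @param top_x Features retained per scorer (default 15).
#' @param mi_bins Mutual-information quantile bins (default 10).
#' @param rqa An [rqa_config()].
#' @param consensus_threshold Votes required for consensus (default 4;
#'   3 is the documented relaxation).
#' @param plan A [resampling_plan()].
#' @param gan A [gan_config()].
#' @param net A [net_config()].
#' @param stage2 Stage-2 tracks: `"both"`, `"cnn"`, or `"rnn"`.
#' @param filters Enrichment filters (default [default_filters()]).
#' @param percents Enrichment percentages (default `c(0.5, 1, 5, 10)`).
#' @param gate_majority Undersample from the stage-1 TN pool (default
#'   `TRUE`).
#' @param out_dir Output directory for artifacts, or `NULL` for none.
#' @param seed Master seed.
#' @param deterministic Strip wall-clock timings from the run record so
#'   identical configurations reproduce it bit-identically (default
#'   `TRUE`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, preset = "PLANTED", effect_size = 1,
                            label_column = "label", train_fraction = 0.30,
                            stratified = TRUE, feature_selection = TRUE,
                            top_x = 15L, mi_bins = 10L, rqa = rqa_config(),
                            consensus_threshold = 4L,
                            plan = resampling_plan(), gan = gan_config(),
                            net = net_config(), stage2 = "both",
                            filters = default_filters(),
                            percents = c(0.5, 1, 5, 10),
                            gate_majority = TRUE, out_dir = NULL, seed = 1L) {
  structure(list(input = input, preset = preset,
                 effect_size = as.numeric(effect_size),
                 label_column = label_column,
                 train_fraction = check_fraction(train_fraction, "train_fraction"),
                 stratified = isTRUE(stratified),
                 feature_selection = isTRUE(feature_selection),
                 top_x = check_count(top_x, "top_x"),
                 mi_bins = check_count(mi_bins, "mi_bins", min = 2L),
                 rqa = rqa, consensus_threshold = check_count(consensus_threshold,
                                                              "consensus_threshold"),
                 plan = plan, gan = gan, net = net, stage2 = stage2,
                 filters = filters, percents = as.numeric(percents),
                 gate_majority = isTRUE(gate_majority), out_dir = out_dir,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full conformation-selection pipeline
#'
#' Executes, in order: load or generate the dataset; the four feature
#' scorers and the consensus vote (unless feature selection is off);
#' projection onto the consensus set; a stratified 30/70 split; the
#' two-stage cascade ([cascade_fit()]); prediction on the held-out test
#' split per stage-2 track; and an enrichment report per track. Every
#' stage seed is derived from the master seed. When `out_dir` is set,
#' rankings, the consensus set, predictions, enrichment tables, the
#' configuration and a run log are written there.
#'
#' An empty consensus at the configured threshold aborts the run with an
#' explicit message (the threshold is a configuration choice, never a
#' silent fallback).
#'
#' @param cfg A [pipeline_config()].
#' @param deterministic Strip timings from the run record (default
#'   `TRUE`) so identical config + seed reproduce it bit-identically.
#' @return Object of class `run_record`: configuration, per-stage
#'   artifacts (rankings, consensus, split indices, stage-1 result,
#'   rebuilt-set provenance, prediction sets, enrichment reports),
#'   per-track test metrics, and package version.
#' @export
run_pipeline <- function(cfg = pipeline_config(), deterministic = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name, t_start) {
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t_start, 3)
  }

  ts <- proc.time()[["elapsed"]]
  ds <- pipeline_stage("load", {
    if (!is.null(cfg$input)) read_dataset(cfg$input, cfg$label_column)
    else {
      spec <- preset_spec(cfg$preset, seed = derive_seed(cfg$seed, "data"),
                          effect_size = cfg$effect_size)
      generate_dataset(spec)
    }
  })
  tick("load", ts)

  rankings <- NULL; consensus <- NULL
  active <- ds
  if (cfg$feature_selection) {
    ts <- proc.time()[["elapsed"]]
    rankings <- pipeline_stage("feature_scoring",
      score_features(ds, top_x = cfg$top_x, mi_bins = cfg$mi_bins,
                     rqa_cfg = cfg$rqa))
    consensus <- pipeline_stage("consensus",
      consensus_select(rankings, threshold = cfg$consensus_threshold))
    if (length(consensus$selected) == 0L)
      stop_("pipeline stage 'consensus' failed: no feature was selected by %d of 4 methods; consider --consensus-threshold 3",
            cfg$consensus_threshold)
    active <- pipeline_stage("projection",
                             project_features(ds, consensus$selected))
    tick("feature_selection", ts)
  }

  ts <- proc.time()[["elapsed"]]
  sp <- pipeline_stage("split",
    stratified_split(active, split_spec(cfg$train_fraction, cfg$stratified,
                                        seed = derive_seed(cfg$seed, "split"))))
  tick("split", ts)

  ts <- proc.time()[["elapsed"]]
  fit <- pipeline_stage("cascade",
    cascade_fit(sp$train, stage2 = cfg$stage2, plan = cfg$plan,
                gan_cfg = cfg$gan, net_cfg = cfg$net,
                gate_majority = cfg$gate_majority,
                seed = derive_seed(cfg$seed, "cascade")))
  tick("cascade", ts)

  ts <- proc.time()[["elapsed"]]
  predictions <- list(); reports <- list(); metrics <- list()
  for (tr in names(fit$models)) {
    preds <- pipeline_stage(paste0("predict_", tr),
                            predict(fit, sp$test, track = tr))
    rep <- pipeline_stage(paste0("enrichment_", tr),
      enrichment_report(preds, base_labels = sp$test$labels,
                        filters = cfg$filters, percents = cfg$percents,
                        classifier = paste0("boost+gan-", toupper(tr))))
    cc <- pred_confusion(preds)
    predictions[[tr]] <- preds
    reports[[tr]] <- rep
    metrics[[tr]] <- list(accuracy = accuracy(cc), sensitivity = sensitivity(cc),
                          tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn)
  }
  s1_test <- pipeline_stage("stage1_test", predict(fit$stage1, sp$test))
  s1cc <- pred_confusion(s1_test)
  metrics$stage1 <- list(accuracy = accuracy(s1cc),
                         sensitivity = sensitivity(s1cc),
                         tp = s1cc$tp, tn = s1cc$tn, fp = s1cc$fp, fn = s1cc$fn)
  tick("evaluate", ts)
  timings$total <- round(proc.time()[["elapsed"]] - t0, 3)

  record <- structure(list(
    config = cfg,
    dataset = list(name = ds$name, n = nrow(ds$features),
                   d = ncol(ds$features), minority = sum(ds$labels == 1L)),
    rankings = rankings, consensus = consensus,
    active_features = active$feature_names,
    train_idx = sp$train_idx, test_idx = sp$test_idx,
    stage1_train = fit$stage1_result$predictions,
    stage1_tn_rows = fit$stage1_result$tn_rows,
    stage1_tp_rows = fit$stage1_result$tp_rows,
    rebuilt_provenance = table(fit$rebuilt$provenance, fit$rebuilt$labels),
    predictions = predictions, stage1_test = s1_test, reports = reports,
    metrics = metrics,
    version = as.character(utils::packageVersion("confcascade")),
    timings = if (deterministic) NULL else timings
  ), class = "run_record")
  # the fitted cascade carries external pointers (xgboost) and is kept out
  # of the record so two deterministic runs compare identical()
  if (!is.null(cfg$out_dir)) write_run_artifacts(record, fit, cfg$out_dir)
  record
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> %s: %d x %d (%d binding), seed %d\n",
              x$dataset$name, x$dataset$n, x$dataset$d, x$dataset$minority,
              x$config$seed))
  if (!is.null(x$consensus))
    cat(sprintf("  consensus (threshold %d): %s\n", x$consensus$threshold,
                paste(x$consensus$selected, collapse = ", ")))
  else cat("  feature selection: off (full descriptor table)\n")
  for (tr in names(x$reports)) {
    m <- x$metrics[[tr]]
    cat(sprintf("  %s track: accuracy %.3f, sensitivity %.3f; max final enrichment %.1f (filter %s, %.1f%%)\n",
                tr, m$accuracy, m$sensitivity,
                x$reports[[tr]]$maxima$final_ratio, x$reports[[tr]]$maxima$filter,
                x$reports[[tr]]$maxima$percent))
  }
  cat(sprintf("  stage-1 on test: accuracy %.3f, sensitivity %.3f\n",
              x$metrics$stage1$accuracy, x$metrics$stage1$sensitivity))
  invisible(x)
}

# Flatten the run into CSV/JSON artifacts plus a plain-text log naming
# every default, so no hidden configuration exists.
write_run_artifacts <- function(record, fit, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_("cannot create output directory: %s", out_dir)
  p <- function(...) file.path(out_dir, ...)
  if (!is.null(record$rankings)) {
    rk <- do.call(rbind, lapply(record$rankings, as.data.frame))
    utils::write.csv(rk, p("feature_rankings.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(record$consensus), p("consensus.csv"),
                     row.names = FALSE)
    writeLines(record$consensus$selected, p("selected_features.txt"))
  }
  for (tr in names(record$predictions)) {
    utils::write.csv(as.data.frame(record$predictions[[tr]]),
                     p(sprintf("predictions_%s.csv", tr)), row.names = FALSE)
    utils::write.csv(as.data.frame(record$reports[[tr]]),
                     p(sprintf("enrichment_%s.csv", tr)), row.names = FALSE)
  }
  rebuilt_df <- as.data.frame(fit$rebuilt$features, check.names = FALSE)
  rebuilt_df$label <- fit$rebuilt$labels
  rebuilt_df$provenance <- fit$rebuilt$provenance
  utils::write.csv(rebuilt_df, p("rebuilt_training_set.csv"), row.names = FALSE)
  jsonlite::write_json(record$metrics, p("metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  cfg <- record$config
  yaml::write_yaml(list(
    input = cfg$input, preset = cfg$preset, effect_size = cfg$effect_size,
    train_fraction = cfg$train_fraction, stratified = cfg$stratified,
    feature_selection = cfg$feature_selection, top_x = cfg$top_x,
    mi_bins = cfg$mi_bins,
    rqa = unclass(cfg$rqa), consensus_threshold = cfg$consensus_threshold,
    plan = unclass(cfg$plan), gan = unclass(cfg$gan), net = unclass(cfg$net),
    stage2 = cfg$stage2, percents = cfg$percents,
    gate_majority = cfg$gate_majority, seed = cfg$seed), p("config.yaml"))
  log <- c(
    sprintf("confcascade %s run, master seed %d", record$version, cfg$seed),
    sprintf("dataset: %s (%d x %d, %d binding)", record$dataset$name,
            record$dataset$n, record$dataset$d, record$dataset$minority),
    sprintf("feature selection: %s (top_x=%d, mi_bins=%d, rqa radius=%.2f jmin=%d dim=%d delay=%d, consensus threshold=%d)",
            ifelse(cfg$feature_selection, "on", "off"), cfg$top_x, cfg$mi_bins,
            cfg$rqa$radius, cfg$rqa$jmin, cfg$rqa$embedding_dim, cfg$rqa$delay,
            cfg$consensus_threshold),
    sprintf("split: %.2f train, stratified=%s", cfg$train_fraction, cfg$stratified),
    sprintf("resampling: kmeans_clusters=%d, gate_majority=%s; gan latent=%d hidden=%s epochs=%d batch=%d lr=%g",
            cfg$plan$kmeans_clusters, cfg$gate_majority, cfg$gan$latent_dim,
            paste(cfg$gan$generator_layers, collapse = "x"), cfg$gan$epochs,
            cfg$gan$batch_size, cfg$gan$learning_rate),
    sprintf("networks: conv %dx kernel %d pool %d dense %d; lstm %s dense %d; dropout %.2f epochs %d batch %d lr %g threshold %.2f",
            cfg$net$conv_filters, cfg$net$kernel, cfg$net$pool, cfg$net$dense,
            paste(cfg$net$rnn_units, collapse = "x"), cfg$net$rnn_dense,
            cfg$net$dropout, cfg$net$epochs, cfg$net$batch_size,
            cfg$net$learning_rate, cfg$net$threshold),
    sprintf("filters: %s; percents: %s",
            paste(vapply(cfg$filters, function(f)
              sprintf("%s=%s/%s", f$id, f$ranking_key, f$direction),
              character(1)), collapse = ", "),
            paste(cfg$percents, collapse = ", ")))
  writeLines(log, p("run.log"))
  invisible(out_dir)
}
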