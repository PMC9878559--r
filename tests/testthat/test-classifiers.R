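test_that("prediction sets enforce the threshold convention and partition", {
  p <- prediction_set(c(1, 0, 1, 0), c(0.5, 0.5, 0.2, 0.7), threshold = 0.5)
  expect_equal(p$hard, c(1L, 1L, 0L, 1L))      # prob == threshold maps to 1
  expect_equal(p$category, c("TP", "FP", "FN", "FP"))
  p2 <- prediction_set(c(1, 0), c(1, 1), threshold = 1.01)
  expect_equal(p2$hard, c(0L, 0L))
  set.seed(4)
  truth <- rbinom(300, 1, 0.3); prob <- runif(300)
  ps <- prediction_set(truth, prob, threshold = 0.4)
  cc <- confcascade:::pred_confusion(ps)
  expect_equal(c(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn),
               oracle_confusion(truth, as.integer(prob >= 0.4)))
  expect_equal(sort(unique(ps$category)), sort(unique(c("TP", "TN", "FP", "FN"))))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 300L)
  expect_error(prediction_set(c(1, 0), c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("stage-1 boosting separates separable data and is deterministic", {
  ds <- separable_ds(200)
  m <- train_stage1(ds, seed = 1)
  preds <- predict(m, ds)
  expect_equal(accuracy(confcascade:::pred_confusion(preds)), 1.0)
  m2 <- train_stage1(ds, seed = 1)
  expect_identical(predict(m2, ds)$prob, preds$prob)
  s1 <- stage_one_result(m, ds)
  expect_equal(sort(c(s1$tn_rows, s1$tp_rows)), seq_len(200))  # all correct
})

test_that("stage-1 on label-permuted data sits at the majority-class rate", {
  accs <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 400
    x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, sprintf("f%d", 1:5)))
    y <- sample(rep(c(0L, 1L), c(300, 100)))
    ds <- conformation_dataset(x, y)
    sp <- stratified_split(ds, split_spec(0.5, seed = seed))
    m <- train_stage1(sp$train, seed = seed, nrounds = 20,
                      params = list(max_depth = 2L, eta = 0.1))
    accuracy(confcascade:::pred_confusion(predict(m, sp$test)))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.75), 0.05)
})

test_that("classifiers reject mismatched features with a named message", {
  ds <- separable_ds(60)
  m <- train_stage1(ds, seed = 2)
  other <- random_ds(30, 3, seed = 1)
  expect_error(predict(m, other), "unexpected: f03")
  perm <- conformation_dataset(ds$features[, c(2, 1)], ds$labels,
                               feature_names = c("f02", "f01"))
  expect_error(predict(m, perm), "different order")
})

test_that("the CNN memorizes a tiny separable fixture and stays in [0,1]", {
  ds <- separable_ds(20, d = 6, seed = 3)
  cfg <- net_config(epochs = 500, batch_size = 10, seed = 4)
  m <- train_cnn(ds, cfg)
  p <- predict(m, ds)
  expect_true(all(p$prob >= 0 & p$prob <= 1))
  expect_equal(accuracy(confcascade:::pred_confusion(p)), 1.0)
  m2 <- train_cnn(ds, cfg)
  expect_identical(predict(m2, ds)$prob, p$prob)
  expect_error(train_cnn(project_features(ds, "f01"), net_config(kernel = 3)),
               "at least `kernel`")
  single <- conformation_dataset(ds$features, rep(0L, 20))
  expect_error(train_cnn(single, cfg), "both classes")
})

test_that("the LSTM memorizes a tiny fixture, is seed-deterministic and order-sensitive", {
  ds <- separable_ds(20, d = 6, seed = 5)
  cfg <- net_config(epochs = 400, batch_size = 10, seed = 6)
  m <- train_rnn(ds, cfg)
  p <- predict(m, ds)
  expect_true(all(p$prob >= 0 & p$prob <= 1))
  expect_equal(accuracy(confcascade:::pred_confusion(p)), 1.0)
  m2 <- train_rnn(ds, cfg)
  expect_identical(predict(m2, ds)$prob, p$prob)
  # feeding the descriptors in a different order is a different model
  perm_feats <- ds$features[, c(3, 1, 2, 6, 5, 4)]
  colnames(perm_feats) <- ds$feature_names
  dsp <- conformation_dataset(perm_feats, ds$labels,
                              feature_names = ds$feature_names)
  expect_false(identical(predict(m, dsp)$prob, p$prob))
  single <- conformation_dataset(ds$features, rep(1L, 20))
  expect_error(train_rnn(single, cfg), "both classes")
})

test_that("both networks detect a planted signal on held-out data", {
  ds <- generate_dataset(synthetic_spec(n = 600, d = 10, minority_count = 300,
                                        informative = 1:3, effect_size = 2,
                                        seed = 11))
  sp <- stratified_split(ds, split_spec(0.5, seed = 1))
  cfg <- net_config(epochs = 40, seed = 2)
  for (train_fun in list(train_cnn, train_rnn)) {
    m <- train_fun(sp$train, cfg)
    cc <- confcascade:::pred_confusion(predict(m, sp$test))
    expect_gt(sensitivity(cc), 0.6)
  }
})
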