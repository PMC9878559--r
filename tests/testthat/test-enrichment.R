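test_that("the three enrichment ratios follow their definitions", {
  expect_equal(base_enrichment_ratio(c(1, 0, 0, 0)), 0.25)
  expect_equal(base_enrichment_ratio(rep(1, 7)), 1.0)
  expect_equal(base_enrichment_ratio(c(rep(1, 851), rep(0, 2147))), 851 / 2998)
  expect_error(base_enrichment_ratio(c(0, 0)), "no binding")

  expect_equal(ml_enrichment_ratio(9, 3), 0.75)
  expect_equal(ml_enrichment_ratio(4, 0), 1.0)
  expect_equal(ml_enrichment_ratio(0, 5), 0.0)
  expect_error(ml_enrichment_ratio(0, 0), "positive")

  expect_equal(final_enrichment_ratio(0.75, 0.25), 3.0)
  expect_equal(final_enrichment_ratio(0.4, 0.4), 1.0)
  expect_equal(final_enrichment_ratio(0.75, 851 / 2998), 0.75 * 2998 / 851)
  expect_equal(final_enrichment_ratio(0.75, 851 / 2998), 2.6422,
               tolerance = 1e-4)
  expect_error(final_enrichment_ratio(0.5, 0), "positive")
})

test_that("filters keep the right ranked subset of truth-positive rows", {
  # 200 positives at 1 percent: ceiling keeps 2 rows
  p <- prediction_set(rep(1, 200), seq(1, 0.005, length.out = 200))
  res <- apply_filter(p, filter_spec("A", "prob", "desc", percent = 1))
  expect_equal(res$kept, 2L)

  # percent = 100 reproduces the global tally
  set.seed(12)
  truth <- rbinom(150, 1, 0.4)
  prob <- runif(150)
  ps <- prediction_set(truth, prob)
  res100 <- apply_filter(ps, filter_spec("A", "prob", "desc", percent = 100))
  cc <- confusion_counts(truth, ps$hard)
  expect_equal(res100$tp, cc$tp)
  expect_equal(res100$fn, cc$fn)

  # hand-enumerated fixture: 10 positives, descending probabilities,
  # first five above threshold; keeping the best half gives tp=5, fn=0
  fix <- prediction_set(rep(1, 10), seq(0.95, 0.05, length.out = 10))
  res50 <- apply_filter(fix, filter_spec("A", "prob", "desc", percent = 50))
  expect_equal(res50$tp, 5L)
  expect_equal(res50$fn, 0L)
  # worst-first on the same fixture keeps only sub-threshold rows
  resD <- apply_filter(fix, filter_spec("D", "prob", "asc", percent = 50))
  expect_equal(resD$tp, 0L)
  expect_equal(resD$fn, 5L)

  none <- prediction_set(rep(0, 5), runif(5))
  expect_error(apply_filter(none, filter_spec("A")), "no truly binding")
})

test_that("kept-subset size is monotone in the percentage", {
  p <- prediction_set(rep(1, 37), runif(37))
  sizes <- vapply(c(0.5, 1, 5, 10, 50, 100), function(pct)
    apply_filter(p, filter_spec("A", percent = pct))$kept, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_equal(sizes[length(sizes)], 37)
})

test_that("enrichment reports cover the grid and bound correctly", {
  n <- 400
  truth <- rep(c(1, 0), c(80, 320))
  # perfect classifier: every cell has ml = 1, final = 1/base
  perfect <- prediction_set(truth, ifelse(truth == 1, 0.9, 0.1),
                            stage1_prob = ifelse(truth == 1, 0.8, 0.2))
  rep1 <- enrichment_report(perfect)
  expect_equal(nrow(rep1$cells), 16L)
  expect_true(all(rep1$cells$ml_ratio == 1))
  expect_equal(rep1$cells$final_ratio, rep(1 / 0.2, 16))
  expect_equal(rep1$maxima$final_ratio, 5)

  # all-FN classifier: zero everywhere
  allfn <- prediction_set(truth, ifelse(truth == 1, 0.1, 0.9),
                          stage1_prob = rep(0.1, n))
  rep0 <- enrichment_report(allfn)
  expect_true(all(rep0$cells$final_ratio == 0))

  # random fixture: every cell matches an independent recomputation
  set.seed(20)
  ps <- prediction_set(rbinom(n, 1, 0.25), runif(n), stage1_prob = runif(n))
  rep2 <- enrichment_report(ps)
  base <- mean(ps$truth)
  for (i in seq_len(nrow(rep2$cells))) {
    cell <- rep2$cells[i, ]
    pos <- ps[ps$truth == 1L, ]
    key <- switch(cell$ranking_key, mean = (pos$prob + pos$stage1_prob) / 2,
                  pos[[cell$ranking_key]])
    ord <- if (cell$direction == "desc") order(-key, seq_along(key))
           else order(key, seq_along(key))
    kept <- pos[ord[seq_len(ceiling(cell$percent / 100 * nrow(pos)))], ]
    expect_equal(cell$tp, sum(kept$hard == 1L))
    expect_equal(cell$fn, sum(kept$hard == 0L))
    expect_equal(cell$final_ratio, (cell$tp / (cell$tp + cell$fn)) / base)
  }
})

test_that("final enrichment is 1 when the subset hit rate equals the base rate", {
  # 40 positives of 160 rows (base 0.25); exactly a quarter of every
  # ranked prefix is predicted positive
  truth <- rep(c(1, 0), c(40, 120))
  prob <- numeric(160)
  prob[truth == 1] <- rep(c(0.9, 0.1, 0.1, 0.1), 10)  # 1 in 4 above threshold
  ps <- prediction_set(truth, prob)
  res <- apply_filter(ps, filter_spec("X", "row", "asc", percent = 100))
  ml <- ml_enrichment_ratio(res$tp, res$fn)
  expect_equal(final_enrichment_ratio(ml, base_enrichment_ratio(truth)), 1.0)
})
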