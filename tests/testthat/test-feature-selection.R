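test_that("ANOVA F matches hand computation and handles degenerate variance", {
  ds <- tiny_ds(f = c(1, 2, 3, 2, 3, 4), labels = c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(anova_f_scores(ds)$scores), 1.5)

  same <- tiny_ds(f = c(1, 2, 3, 1, 2, 3), labels = c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(anova_f_scores(same)$scores), 0)

  # zero within-group variance, distinct means: infinite F, ranked first
  degen <- tiny_ds(f = c(1, 1, 2, 2), g = c(1, 2, 3, 4), labels = c(0, 0, 1, 1))
  r <- anova_f_scores(degen, top_x = 1)
  expect_equal(unname(r$scores["f"]), Inf)
  expect_equal(r$selected, "f")
  flat <- tiny_ds(f = c(2, 2, 2, 2), labels = c(0, 0, 1, 1))
  expect_equal(unname(anova_f_scores(flat)$scores), 0)
})

test_that("all four scorers match brute-force oracles on small instances", {
  for (seed in 1:6) {
    ds <- random_ds(n = 25 + seed, d = 4, seed = seed, discrete = TRUE)
    y <- ds$labels
    fr <- anova_f_scores(ds)
    mir <- mutual_information_scores(ds)
    rr <- rqa_entropy_scores(ds)
    sr <- spearman_scores(ds)
    for (j in 1:4) {
      x <- ds$features[, j]
      expect_equal(unname(fr$scores[j]), oracle_anova_f(x, y), tolerance = 1e-9)
      expect_equal(unname(mir$scores[j]), oracle_mi(x, y), tolerance = 1e-9)
      expect_equal(unname(rr$scores[j]),
                   oracle_entr(oracle_rqa_census(x, rqa_config())),
                   tolerance = 1e-9)
      expect_equal(unname(sr$scores[j]), abs(oracle_spearman(x, y)),
                   tolerance = 1e-9)
    }
  }
})

test_that("mutual information behaves like information", {
  # independence: permuted labels carry ~no information
  set.seed(21)
  x <- rnorm(2000)
  vals <- vapply(1:20, function(i) {
    ds <- conformation_dataset(matrix(x, ncol = 1, dimnames = list(NULL, "f")),
                               sample(rep(c(0L, 1L), 1000)))
    unname(mutual_information_scores(ds)$scores)
  }, numeric(1))
  expect_lt(mean(vals), 0.01)

  # feature equal to the label: exactly ln 2 at balance
  ds <- conformation_dataset(matrix(rep(c(0, 1), 500), ncol = 1,
                                    dimnames = list(NULL, "f")),
                             rep(c(0L, 1L), 500))
  expect_equal(unname(mutual_information_scores(ds)$scores), log(2))

  # exact joint [[0.4, 0.1], [0.1, 0.4]] as 1000 samples vs the direct sum
  x <- c(rep(0, 400), rep(0, 100), rep(1, 100), rep(1, 400))
  y <- c(rep(0L, 400), rep(1L, 100), rep(0L, 100), rep(1L, 400))
  ds2 <- conformation_dataset(matrix(x, ncol = 1, dimnames = list(NULL, "f")), y)
  pj <- c(0.4, 0.1, 0.1, 0.4)          # joint cells; both marginals are 1/2
  direct <- sum(pj * log(pj / 0.25))
  expect_equal(unname(mutual_information_scores(ds2)$scores), direct,
               tolerance = 1e-9)
  expect_gte(direct, 0)

  # constant feature: a single occupied bin carries zero information
  flat <- tiny_ds(f = rep(3, 20), labels = rep(c(0, 1), 10))
  expect_equal(unname(mutual_information_scores(flat)$scores), 0)
})

test_that("Spearman scoring captures monotone association and ranks by |rho|", {
  y <- rep(c(0L, 1L), 10)
  ds <- tiny_ds(f = as.numeric(y), labels = y)
  expect_equal(unname(spearman_scores(ds)$scores), 1)
  ds2 <- tiny_ds(f = 1 - as.numeric(y), labels = y)
  r2 <- spearman_scores(ds2)
  expect_equal(unname(r2$scores), 1)
  expect_equal(unname(attr(r2, "rho")["f"]), -1)
  # nonlinear but monotone in the label
  ds3 <- tiny_ds(f = exp(as.numeric(y) * 3), labels = y)
  expect_equal(unname(spearman_scores(ds3)$scores), 1)
  ds4 <- tiny_ds(f = rep(2, 20), g = as.numeric(y), labels = y)
  expect_warning(r4 <- spearman_scores(ds4), "constant feature 'f'")
  expect_equal(unname(r4$scores["f"]), 0)
})

test_that("consensus voting counts method selections and respects the threshold", {
  mk <- function(method, sel, feats = c("a", "b", "c", "d")) {
    scores <- stats::setNames(rep(0, length(feats)), feats)
    scores[sel] <- rev(seq_along(sel))
    confcascade:::new_feature_ranking(method, scores, top_x = length(sel))
  }
  rk <- list(mk("anova", c("a", "b")), mk("mi", c("a", "b")),
             mk("rqa", c("a", "c")), mk("spearman", c("a", "b")))
  cons4 <- consensus_select(rk, threshold = 4)
  expect_equal(unname(cons4$votes), c(4L, 3L, 1L, 0L))
  expect_equal(cons4$selected, "a")
  cons3 <- consensus_select(rk, threshold = 3)
  expect_equal(cons3$selected, c("a", "b"))

  disjoint <- list(mk("anova", "a"), mk("mi", "b"), mk("rqa", "c"),
                   mk("spearman", "d"))
  expect_length(consensus_select(disjoint, threshold = 4)$selected, 0)

  other <- mk("mi", "x", feats = c("x", "y", "z", "w"))
  expect_error(consensus_select(list(rk[[1]], other), threshold = 2),
               "different feature sets")
  expect_error(consensus_select(rk, threshold = 5), "exceeds")
})

test_that("label-based scorers ignore row order; the recurrence scorer does not", {
  ds <- generate_dataset(synthetic_spec(n = 300, d = 4, minority_count = 60,
                                        informative = 1, ar_coeff = 0.8,
                                        ar_features = 1:4, seed = 8))
  set.seed(42)
  perm <- sample(nrow(ds$features))
  dsp <- conformation_dataset(ds$features[perm, ], ds$labels[perm],
                              feature_names = ds$feature_names)
  expect_equal(anova_f_scores(dsp)$scores, anova_f_scores(ds)$scores)
  expect_equal(mutual_information_scores(dsp)$scores,
               mutual_information_scores(ds)$scores)
  expect_equal(spearman_scores(dsp)$scores, spearman_scores(ds)$scores)
  expect_false(isTRUE(all.equal(rqa_entropy_scores(dsp)$scores,
                                rqa_entropy_scores(ds)$scores)))
})

test_that("scores are scale-equivariant the way each statistic promises", {
  ds <- random_ds(60, 3, seed = 14)
  scaled <- ds
  scaled$features[, 2] <- ds$features[, 2] * 37.5
  expect_equal(anova_f_scores(scaled)$scores, anova_f_scores(ds)$scores)
  expect_equal(spearman_scores(scaled)$scores, spearman_scores(ds)$scores)
  expect_equal(rqa_entropy_scores(scaled)$scores, rqa_entropy_scores(ds)$scores)
  # MI with quantile bins is invariant under strictly monotone transforms
  mono <- ds
  mono$features[, 1] <- exp(ds$features[, 1] / 2)
  expect_equal(mutual_information_scores(mono)$scores[1],
               mutual_information_scores(ds)$scores[1])
})

test_that("a strongly planted feature is ranked first by ANOVA", {
  wins <- vapply(1:10, function(seed) {
    ds <- generate_dataset(synthetic_spec(n = 3000, d = 10, minority_count = 300,
                                          informative = 1, effect_size = 1.5,
                                          seed = seed))
    names(which.max(anova_f_scores(ds)$scores)) == ds$feature_names[1]
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("rankings break ties by column order and cap at d", {
  scores <- stats::setNames(c(1, 2, 2, 0.5), c("w", "x", "y", "z"))
  r <- confcascade:::new_feature_ranking("anova", scores, top_x = 3)
  expect_equal(r$selected, c("x", "y", "w"))
  r2 <- confcascade:::new_feature_ranking("anova", scores, top_x = 99)
  expect_length(r2$selected, 4)
})
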