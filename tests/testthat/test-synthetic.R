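test_that("label counts and preset shapes are exact", {
  ds <- generate_dataset(synthetic_spec(n = 123, d = 4, minority_count = 17,
                                        seed = 1))
  expect_equal(sum(ds$labels), 17L)
  ado <- generate_dataset(preset_spec("ADORA2A"))
  expect_equal(dim(ado), c(2998L, 50L))
  expect_equal(sum(ado$labels), 851L)
  shapes <- vapply(preset_catalog()[c("ADORA2A", "ADRB2", "OPRD1", "OPRK1")],
                   function(s) c(s$n, s$minority_count, s$d), numeric(3))
  expect_equal(unname(shapes[1, ]), c(2998, 2565, 3004, 2998))
  expect_equal(unname(shapes[2, ]), c(851, 156, 72, 138))
  expect_equal(unname(shapes[3, ]), c(50, 51, 51, 50))
})

test_that("generation is bit-reproducible per seed and varies across seeds", {
  spec <- synthetic_spec(n = 60, d = 5, minority_count = 12, informative = 1,
                         ar_coeff = 0.5, seed = 77)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$features, b$features)
  expect_identical(a$labels, b$labels)
  spec2 <- spec; spec2$seed <- 78L
  c <- generate_dataset(spec2)
  expect_false(identical(a$features, c$features))
  expect_equal(dim(c), dim(a))
})

test_that("zero effect size leaves informative features class-neutral", {
  hits <- 0L
  for (seed in 1:20) {
    ds <- generate_dataset(synthetic_spec(n = 100, d = 5, minority_count = 25,
                                          informative = 1, effect_size = 0,
                                          seed = seed))
    p <- t.test(ds$features[ds$labels == 1, 1],
                ds$features[ds$labels == 0, 1])$p.value
    if (p < 0.01) hits <- hits + 1L
  }
  expect_lte(hits, 2L)  # ~alpha * 20 false positives expected
})

test_that("planted standardized mean difference matches the requested effect", {
  smds <- vapply(1:10, function(seed) {
    ds <- generate_dataset(synthetic_spec(n = 3000, d = 6, minority_count = 300,
                                          informative = 1:2, effect_size = 2,
                                          seed = seed))
    mean(vapply(1:2, function(j) {
      x1 <- ds$features[ds$labels == 1, j]
      x0 <- ds$features[ds$labels == 0, j]
      sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
                   (length(x1) + length(x0) - 2))
      (mean(x1) - mean(x0)) / sp
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(smds) - 2.0), 0.15)
})

test_that("AR(1) control produces the requested serial correlation", {
  ac <- function(ar) {
    mean(vapply(1:20, function(seed) {
      ds <- generate_dataset(synthetic_spec(n = 500, d = 2, minority_count = 100,
                                            ar_coeff = ar, seed = seed))
      mean(apply(ds$features, 2, function(x)
        stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]))
    }, numeric(1)))
  }
  expect_lt(abs(ac(0)), 0.05)
  expect_gt(ac(0.8), 0.6)
})

test_that("ar_features restricts the serial correlation to designated columns", {
  ds <- generate_dataset(synthetic_spec(n = 800, d = 4, minority_count = 100,
                                        ar_coeff = 0.8, ar_features = 1:2,
                                        seed = 12))
  lag1 <- apply(ds$features, 2, function(x)
    stats::acf(x, lag.max = 1, plot = FALSE)$acf[2])
  expect_true(all(lag1[1:2] > 0.5))
  expect_true(all(abs(lag1[3:4]) < 0.15))
})

test_that("generate_suite writes the four preset files deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  generate_suite(dir1, seed = 5)
  generate_suite(dir2, seed = 5)
  files <- c("ADORA2A.csv", "ADRB2.csv", "OPRD1.csv", "OPRK1.csv")
  expect_true(all(file.exists(file.path(dir1, files))))
  rows <- vapply(file.path(dir1, files),
                 function(p) length(readLines(p)) - 1L, integer(1))
  expect_equal(unname(rows), c(2998L, 2565L, 3004L, 2998L))
  for (f in files)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  dir3 <- withr::local_tempdir()
  generate_suite(dir3, seed = 6)
  expect_false(identical(readLines(file.path(dir1, "ADORA2A.csv")),
                         readLines(file.path(dir3, "ADORA2A.csv"))))
  manifest <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_named(manifest, c("ADORA2A", "ADRB2", "OPRD1", "OPRK1"))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(n = 10, d = 3, minority_count = 10), "smaller than n")
  expect_error(synthetic_spec(n = 10, d = 3, minority_count = 2,
                              informative = 5), "1..3")
  expect_error(synthetic_spec(n = 10, d = 3, minority_count = 2,
                              ar_coeff = 1), "ar_coeff")
})
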