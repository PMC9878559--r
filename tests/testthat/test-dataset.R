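test_that("CSV parsing preserves shape, order and the descriptor dialect", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c,label", "1,2,3,0", "4,5,6,1", "7,8,9,0", "1,1,1,1"), tmp)
  ds <- read_dataset(tmp)
  expect_equal(dim(ds), c(4L, 3L))
  expect_equal(ds$feature_names, c("a", "b", "c"))
  expect_equal(ds$labels, c(0L, 1L, 0L, 1L))
  expect_equal(ds$features[2, ], c(a = 4, b = 5, c = 6))

  # 51-column dialect: pro_pl_seq present is just another column
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pro_asa_vdw,pro_pl_seq,label", "1,2,0", "3,4,1"), tmp2)
  expect_equal(read_dataset(tmp2)$feature_names, c("pro_asa_vdw", "pro_pl_seq"))

  # a "frame" index column is ignored by name
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,a,label", "1,5,0", "2,6,1"), tmp3)
  expect_equal(read_dataset(tmp3)$feature_names, "a")
})

test_that("load errors are descriptive: blank cells, bad labels, missing columns", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,label", "1,2,0", "3,,1"), tmp)
  expect_error(read_dataset(tmp), "column 'b'.*row 2")

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,label", "1,2,0", "3,x,1"), tmp2)
  expect_error(read_dataset(tmp2), "non-numeric.*column 'b'")

  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,y", "1,2,0", "3,4,1"), tmp3)
  expect_error(read_dataset(tmp3), "label column 'label' not found")

  tmp4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,label", "1,0", "3,0"), tmp4)
  expect_error(read_dataset(tmp4), "single class")

  tmp5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,label", "1,0", "3,2"), tmp5)
  expect_error(read_dataset(tmp5), "only 0/1")
})

test_that("write then read is the identity, including on a preset-sized table", {
  ds <- generate_dataset(synthetic_spec(n = 40, d = 6, minority_count = 9,
                                        informative = 1:2, seed = 5))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, tmp)
  back <- read_dataset(tmp, name = ds$name)
  expect_identical(back$features, ds$features)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$feature_names, ds$feature_names)

  big <- generate_dataset(preset_spec("ADORA2A"))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(big, tmp2)
  back2 <- read_dataset(tmp2)
  expect_identical(back2$features, big$features)
  expect_identical(back2$labels, big$labels)
})

test_that("dataset construction enforces its invariants", {
  m <- matrix(1:8, 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(conformation_dataset(m[1, , drop = FALSE], labels = 1),
               "at least 2 rows")
  expect_error(conformation_dataset(m, labels = c(0, 1, 2, 0)), "only 0 and 1")
  expect_error(conformation_dataset(m, labels = c(0, 1)), "length 2")
  m2 <- m; colnames(m2) <- c("a", "a")
  expect_error(conformation_dataset(m2, labels = c(0, 1, 0, 1)), "unique")
  m3 <- m; m3[2, 1] <- NA
  expect_error(conformation_dataset(m3, labels = c(0, 1, 0, 1)), "missing")
})

test_that("project_features keeps requested columns in order and rejects unknowns", {
  ds <- random_ds(20, 4, seed = 2)
  expect_identical(project_features(ds, ds$feature_names), ds)
  sub <- project_features(ds, c("f03", "f01"))
  expect_equal(sub$feature_names, c("f03", "f01"))
  expect_equal(sub$features[, "f01"], ds$features[, "f01"])
  expect_equal(sub$labels, ds$labels)
  expect_error(project_features(ds, "nope"), "unknown feature name.*nope")
  expect_error(project_features(ds, character(0)), "at least one")
})
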