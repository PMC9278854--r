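test_that("stratified folds spread every class evenly", {
  labels <- rep(1:8, each = 8)
  fp <- make_fold_plan(labels, k = 8, seed = 3)
  expect_length(fp$folds, 8)
  expect_setequal(unlist(fp$folds), seq_along(labels))
  for (f in fp$folds) {
    expect_equal(as.integer(table(factor(labels[f], levels = 1:8))), rep(1L, 8))
  }
})

test_that("leave-one-class-out yields one fold per class with all its rows", {
  labels <- rep(1:5, times = c(3, 4, 2, 5, 6))
  fp <- make_fold_plan(labels, scheme = "leave_one_class_out")
  expect_length(fp$folds, 5)
  for (cl in 1:5) expect_setequal(fp$folds[[cl]], which(labels == cl))
})

test_that("classes smaller than k still partition with no empty fold", {
  labels <- rep(1:8, each = 2)  # 2 rows per class, k = 8
  fp <- make_fold_plan(labels, k = 8, seed = 1)
  expect_setequal(unlist(fp$folds), seq_along(labels))
  expect_equal(sum(lengths(fp$folds)), 16)
  expect_true(all(lengths(fp$folds) >= 1))
  expect_error(make_fold_plan(1:3, k = 10), "more folds than rows")
})
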