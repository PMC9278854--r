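test_that("pairwise AUC matches hand-computed U statistics", {
  expect_equal(pairwise_auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(pairwise_auc(c(0.3, 0.3, 0.3), c(0.3, 0.3)), 0.5)
  # pairs: 0.9>0.5, 0.9>0.1, 0.3<0.5, 0.3>0.1 -> 3/4
  expect_equal(pairwise_auc(c(0.9, 0.3), c(0.5, 0.1)), 0.75)
  expect_error(pairwise_auc(numeric(0), 1), "nonempty")
})

test_that("multiclass AUC hits its closed-form anchors", {
  labels <- rep(1:3, each = 4)
  onehot <- matrix(0, 12, 3)
  onehot[cbind(1:12, labels)] <- 1
  expect_equal(multiclass_auc(onehot, labels), 1.0)
  uniform <- matrix(1 / 3, 12, 3)
  expect_equal(multiclass_auc(uniform, labels), 0.5)
  expect_error(multiclass_auc(uniform, rep(1, 12)), "two classes")
})

test_that("multiclass AUC equals the brute-force triple-enumeration oracle", {
  set.seed(11)
  for (i in 1:10) {
    m <- sample(2:5, 1)
    n <- sample(10:40, 1)
    labels <- sample(m, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- 1:2
    P <- matrix(stats::runif(n * m), n, m)
    P <- P / rowSums(P)
    expect_equal(multiclass_auc(P, labels),
                 brute_force_multiclass_auc(P, labels), tolerance = 1e-12)
  }
})

test_that("two-class case agrees with rank-based ROC AUC", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- sample(1:2, 60, replace = TRUE)
  P <- matrix(stats::runif(120), 60, 2)
  P <- P / rowSums(P)
  ours <- multiclass_auc(P, labels)
  ref <- suppressMessages(as.numeric(pROC::auc(labels == 2, P[, 2],
                                               direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("row-wise KL divergence behaves like a divergence", {
  P <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE)
  expect_equal(as.numeric(kl_rows(P, P)), c(0, 0))
  # reference (1,0) vs approximation (.5,.5): ln 2 after clipping
  v <- kl_rows(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1))
  expect_equal(as.numeric(v), log(2), tolerance = 1e-6)
  set.seed(2)
  A <- matrix(stats::runif(50), 10); A <- A / rowSums(A)
  B <- matrix(stats::runif(50), 10); B <- B / rowSums(B)
  expect_true(all(kl_rows(A, B) >= 0))
  expect_error(kl_rows(A, B[1:5, ]), "identical shape")
  # direction flag flips the arguments
  expect_equal(as.numeric(kl_rows(A, B, direction = "approx_vs_ref")),
               as.numeric(kl_rows(B, A)))
})
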