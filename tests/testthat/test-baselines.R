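test_that("all three MVPA classifiers master separable Gaussian blobs", {
  set.seed(1)
  n_per <- 30
  centers <- matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(n_per * 2), n_per) + rep(centers[k, ], each = n_per)))
  labels <- rep(1:3, each = n_per)
  fp <- make_fold_plan(labels, k = 4, seed = 2)
  res <- mvpa_suite(x, labels, fold_plan = fp, seed = 3)
  expect_true(all(res$results$auc >= 0.95))
  expect_setequal(res$results$method,
                  c("logistic", "nearest_neighbor", "linear_svm"))
})

test_that("pure-noise recordings decode at chance", {
  set.seed(4)
  x <- matrix(rnorm(120 * 10), 120)
  labels <- rep(1:10, each = 12)
  res <- mvpa_suite(x, labels, fold_plan = make_fold_plan(labels, k = 4, seed = 5),
                    seed = 6)
  expect_true(all(abs(res$results$auc - 0.5) < 0.07))
})

test_that("neural predictivity recovers exact linear readouts", {
  net <- tiny_net()
  imgs <- tiny_images()
  rec <- simulate_region(net, imgs, "fc1", d = 16, noise_sd = 0, seed = 7)
  fp <- make_fold_plan(imgs$labels, k = 4, seed = 8)
  res <- neural_predictivity(net, imgs, rec, "fc1", fold_plan = fp,
                             n_pcs = 20, n_pls = 8, seed = 9)
  expect_gte(res$results$median_r, 0.95)
  # shuffling rows destroys predictivity
  shuf <- recording_set(rec$data[with_seed(10, sample(nrow(rec$data))), ])
  res0 <- neural_predictivity(net, imgs, shuf, "fc1", fold_plan = fp,
                              n_pcs = 20, n_pls = 8, seed = 9)
  expect_lt(abs(res0$results$median_r), 0.1)
})

test_that("predictivity shows the canonical early-to-early shared-variance pattern", {
  net <- tiny_net()
  imgs <- tiny_images()
  # a region that is a readout of an early layer
  rec <- simulate_region(net, imgs, "pool1", d = 16, noise_sd = 0.2, seed = 11)
  fp <- make_fold_plan(imgs$labels, k = 4, seed = 12)
  r_early <- neural_predictivity(net, imgs, rec, "pool1", fold_plan = fp,
                                 n_pcs = 20, n_pls = 8, seed = 13)
  r_late <- neural_predictivity(net, imgs, rec, "fc1", fold_plan = fp,
                                n_pcs = 20, n_pls = 8, seed = 13)
  expect_gte(r_early$results$median_r, r_late$results$median_r)
})

test_that("feature permutation leaves the median predictivity unchanged", {
  net <- tiny_net()
  imgs <- tiny_images()
  rec <- simulate_region(net, imgs, "fc1", d = 12, noise_sd = 0.3, seed = 14)
  fp <- make_fold_plan(imgs$labels, k = 4, seed = 15)
  r1 <- neural_predictivity(net, imgs, rec, "fc1", fold_plan = fp,
                            n_pcs = 16, n_pls = 6, seed = 16)
  perm <- with_seed(17, sample(12))
  r2 <- neural_predictivity(net, imgs, recording_set(rec$data[, perm]), "fc1",
                            fold_plan = fp, n_pcs = 16, n_pls = 6, seed = 16)
  expect_equal(sort(r1$per_feature_r), sort(r2$per_feature_r), tolerance = 1e-8)
  expect_equal(r1$results$median_r, r2$results$median_r, tolerance = 1e-8)
})

test_that("a one-component pixel code is an information bottleneck", {
  net <- tiny_net()
  imgs <- tiny_images()
  fp <- make_fold_plan(imgs$labels, k = 4, seed = 18)
  res <- pixel_interface(imgs, n_components = 1, net, layers = c("conv1", "fc1"),
                         fold_plan = fp, seed = 19)
  expect_true(all(res$grid$auc < 0.75))
})
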