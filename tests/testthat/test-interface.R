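test_that("interfacing a noise-free late-layer region recovers late layers", {
  net <- tiny_net()
  imgs <- tiny_images()
  rec <- simulate_region(net, imgs, "fc1", d = 32, noise_sd = 0, seed = 3,
                         region_name = "lateR")
  fp <- make_fold_plan(imgs$labels, k = 4, seed = 5)
  res <- run_interface_grid(net, imgs, rec, layers = c("conv1", "conv2", "fc1"),
                            fold_plan = fp, seed = 6)
  expect_s3_class(res$grid, "tbl_df")
  expect_equal(nrow(res$grid), 3)
  b <- best_layer(res, by = "mean_kl")
  expect_equal(b$layer, "fc1")
  expect_gte(max(res$grid$auc), res$auc_image - 0.02)
  # pooled AUC is computed once over all held-out predictions; per-fold values
  # are dispersion only
  expect_equal(nrow(res$per_fold), 12)
  preds <- res$predictions[["lateR/fc1"]]
  expect_equal(multiclass_auc(preds, imgs$labels),
               res$grid$auc[res$grid$layer == "fc1"])
})

test_that("label-shuffled recordings score at chance at every layer", {
  net <- tiny_net()
  imgs <- tiny_images()
  rec <- simulate_region(net, imgs, "fc1", d = 32, noise_sd = 0, seed = 3)
  shuf <- recording_set(rec$data[with_seed(8, sample(nrow(rec$data))), ],
                        region_name = "shuffled")
  res <- run_interface_grid(net, imgs, shuf, layers = c("conv2", "fc1"),
                            fold_plan = make_fold_plan(imgs$labels, k = 4, seed = 5),
                            seed = 6)
  expect_true(all(abs(res$grid$auc - 0.5) < 0.05))
})

test_that("interfaced AUC responds monotonically to recording noise", {
  net <- tiny_net()
  imgs <- tiny_images()
  fp <- make_fold_plan(imgs$labels, k = 4, seed = 5)
  aucs <- vapply(c(0, 1, 10), function(ns) {
    rec <- simulate_region(net, imgs, "fc1", d = 32, noise_sd = ns, seed = 3)
    run_interface_grid(net, imgs, rec, layers = "fc1", fold_plan = fp,
                       seed = 6)$grid$auc
  }, 1)
  expect_true(all(diff(aucs) <= 0.02))  # non-increasing with 0.02 slack
  # with few trials and features the tenfold noise drowns the signal to chance
  small <- imgs[seq(1, 240, by = 3)]
  rec_s <- simulate_region(net, small, "fc1", d = 8, noise_sd = 10, seed = 3)
  auc_s <- run_interface_grid(net, small, rec_s, layers = "fc1",
                              fold_plan = make_fold_plan(small$labels, k = 4,
                                                         seed = 5),
                              seed = 6)$grid$auc
  expect_lt(abs(auc_s - 0.5), 0.06)
})

test_that("tidy, glance and autoplot summarize the grid", {
  net <- tiny_net()
  imgs <- tiny_images()
  rec <- simulate_region(net, imgs, "fc1", d = 32, noise_sd = 0, seed = 3)
  res <- run_interface_grid(net, imgs, rec, layers = c("conv2", "fc1"),
                            fold_plan = make_fold_plan(imgs$labels, k = 4, seed = 5),
                            seed = 6)
  td <- generics::tidy(res)
  expect_setequal(unique(td$metric), c("auc", "mean_kl"))
  gl <- generics::glance(res)
  expect_equal(gl$layers, 2)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("temporal recordings are rejected with guidance", {
  net <- tiny_net()
  imgs <- tiny_images()[1:20]
  arr <- array(stats::runif(20 * 3 * 4), c(20, 3, 4))
  tmp <- recording_set(arr, bin_width = 10, bin_onsets = c(0, 10, 20))
  expect_error(run_interface_grid(net, imgs, tmp), "binwise_interface_kl")
})
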