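test_that("identity projection reproduces layer activations exactly", {
  net <- tiny_net()
  imgs <- tiny_images()[1:20]
  acts <- activations_at(net, imgs, "fc1")
  rec <- simulate_region(net, imgs, "fc1", d = 32, noise_sd = 0,
                         projection = "identity", seed = 1)
  expect_equal(rec$data, acts$values, ignore_attr = TRUE)
  expect_error(simulate_region(net, imgs, "fc1", d = 5, projection = "identity"),
               "identity projection")
  expect_error(simulate_region(net, imgs, "nolayer", d = 5), "valid layers")
})

test_that("region simulation is reproducible and noise scales with signal", {
  net <- tiny_net()
  imgs <- tiny_images()[1:40]
  r1 <- simulate_region(net, imgs, "pool2", d = 12, noise_sd = 0.5, seed = 9)
  r2 <- simulate_region(net, imgs, "pool2", d = 12, noise_sd = 0.5, seed = 9)
  expect_identical(r1$data, r2$data)
  clean <- simulate_region(net, imgs, "pool2", d = 12, noise_sd = 0, seed = 9)
  resid <- r1$data - clean$data
  # per-feature noise SD ~ 0.5 x signal SD
  ratio <- apply(resid, 2, sd) / apply(clean$data, 2, sd)
  expect_gt(mean(ratio), 0.3)
  expect_lt(mean(ratio), 0.8)
})

test_that("mixing blends several source layers", {
  net <- tiny_net()
  imgs <- tiny_images()[1:30]
  rec <- simulate_region(net, imgs, source_layer = NULL, d = 10, noise_sd = 0,
                         mixing = c(conv1 = 1, fc1 = 0.5), seed = 2)
  expect_equal(dim(rec$data), c(30, 10))
  expect_equal(attr(rec, "source_layer"), "conv1+fc1")
})

test_that("two-region dynamics carry the configured lag structure", {
  net <- tiny_net()
  imgs <- tiny_images()
  trials <- with_seed(3, imgs[sample(160, 120, replace = TRUE)])
  spec <- dynamics_spec()
  two <- simulate_two_region_dynamics(net, trials, spec, seed = 5)
  expect_true(two$v4$temporal && two$it$temporal)
  expect_equal(dim(two$v4$data), c(120, spec$t_bins, 24))
  expect_true(all(two$v4$data >= 0))  # rectified rate-like values
  # determinism
  two2 <- simulate_two_region_dynamics(net, trials, spec, seed = 5)
  expect_identical(two$it$data, two2$it$data)
  # stimulus-driven mean rate peaks in V4 feedforward_lag bins before IT
  rv <- colMeans(apply(two$v4$data, c(1, 2), mean))
  ri <- colMeans(apply(two$it$data, c(1, 2), mean))
  expect_equal(which.max(ri) - which.max(rv), spec$feedforward_lag)
  # invalid specs are rejected
  expect_error(dynamics_spec(feedforward_lag = 0), "lags")
  expect_error(dynamics_spec(t_bins = 10, stimulus_on = 6, stimulus_off = 16),
               "stimulus_on")
  expect_error(dynamics_spec(t_bins = 12, stimulus_on = 6, stimulus_off = 10,
                             feedforward_lag = 4, feedback_lag = 4),
               "exceed")
})

test_that("zero feedback gain leaves the V4-like region without class information", {
  net <- tiny_net()
  imgs <- tiny_images()
  trials <- with_seed(4, imgs[sample(160, 120, replace = TRUE)])
  spec <- dynamics_spec(class_gain_feedback = 0)
  two <- simulate_two_region_dynamics(net, trials, spec, seed = 6)
  fp <- make_fold_plan(trials$labels, k = 4, seed = 7)
  kl <- binwise_interface_kl(net, "fc1", two$v4, trials, fold_plan = fp, seed = 8)
  kl_shuf <- binwise_interface_kl(net, "fc1", two$v4, trials, fold_plan = fp,
                                  shuffle_labels = TRUE, seed = 8)
  # post-feedback-window bins: real vs label-shuffled KL indistinguishable
  post <- (spec$stimulus_on + spec$feedforward_lag + spec$feedback_lag):spec$t_bins
  diff_mean <- mean(kl$values[, post]) - mean(kl_shuf$values[, post])
  expect_lt(abs(diff_mean), 0.1)
  # while the IT-like region is decodable in the same window
  kl_it <- binwise_interface_kl(net, "fc1", two$it, trials, fold_plan = fp, seed = 8)
  kl_it_shuf <- binwise_interface_kl(net, "fc1", two$it, trials, fold_plan = fp,
                                     shuffle_labels = TRUE, seed = 8)
  expect_lt(mean(kl_it$values[, post]) + 0.2, mean(kl_it_shuf$values[, post]))
})
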