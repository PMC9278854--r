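test_that("zero noise scale produces exactly zero deviation", {
  net <- tiny_net()
  imgs <- tiny_images()[1:30]
  r <- perturb_and_propagate(net, imgs, "conv1", gamma = 0, n_repeats = 2,
                             seed = 1)
  expect_identical(r$deviation, 0)
  expect_identical(max(abs(r$per_repeat)), 0)
})

test_that("deviation grows monotonically with the noise scale", {
  net <- tiny_net()
  imgs <- tiny_images()[1:40]
  devs <- vapply(c(0, 1, 4), function(g)
    perturb_and_propagate(net, imgs, "conv1", gamma = g, n_repeats = 4,
                          seed = 2)$deviation, 1)
  expect_true(all(diff(devs) > 0))
})

test_that("layer ordering is validated and metrics are selectable", {
  net <- tiny_net()
  imgs <- tiny_images()[1:20]
  expect_error(perturb_and_propagate(net, imgs, "fc1",
                                     reference_layer = "conv1"),
               "precede")
  r_mse <- perturb_and_propagate(net, imgs, "conv1", gamma = 1,
                                 metric = "mse", n_repeats = 2, seed = 3)
  r_cos <- perturb_and_propagate(net, imgs, "conv1", gamma = 1,
                                 metric = "cosine", n_repeats = 2, seed = 3)
  expect_gte(r_mse$deviation, 0)
  expect_gte(r_cos$deviation, 0)
})

test_that("repeat averaging stabilizes the estimate", {
  net <- tiny_net()
  imgs <- tiny_images()[1:30]
  r <- perturb_and_propagate(net, imgs, "conv1", gamma = 2, n_repeats = 8,
                             seed = 4)
  # SD across single-repeat estimates is small relative to the mean
  expect_lt(stats::sd(r$per_repeat) / r$deviation, 0.5)
  expect_length(r$per_repeat, 8)
})
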