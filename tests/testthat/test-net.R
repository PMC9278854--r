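test_that("substitution identity holds at every injectable layer", {
  net <- tiny_net()
  imgs <- tiny_images()[seq(1, 160, by = 8)]
  P <- forward_full(net, imgs)
  expect_equal(range(rowSums(unclass(P))), c(1, 1), tolerance = 1e-6)
  for (q in setdiff(layer_names(net), "logits")) {
    P2 <- forward_from(net, q, activations_at(net, imgs, q))
    expect_lte(max(abs(unclass(P2) - unclass(P))), 1e-5)
  }
})

test_that("evaluation-mode forward pass is pure and shape-checked", {
  net <- tiny_net()
  imgs <- tiny_images()
  x <- imgs$images[c(1, 1, 2), , , , drop = FALSE]
  P <- forward_full(net, x)
  expect_equal(P[1, ], P[2, ])
  expect_error(forward_full(net, imgs$images[1:2, 1:8, , , drop = FALSE]),
               "does not match")
})

test_that("injection semantics: injected activations fully determine output", {
  net <- tiny_net()
  imgs <- tiny_images()
  # all-zero activations give one shared prediction row
  z <- matrix(0, 5, layer_width(net, "conv2"))
  Pz <- forward_from(net, "conv2", z)
  expect_true(all(apply(unclass(Pz), 2, function(col) diff(range(col)) == 0)))
  # activations of image A "claiming" image B predict image A
  aA <- activations_at(net, imgs[1], "pool2")
  PA <- forward_full(net, imgs[1])
  PB <- forward_from(net, "pool2", aA$values)  # no image identity attached
  expect_equal(as.numeric(PB), as.numeric(PA), tolerance = 1e-12)
  expect_error(forward_from(net, "conv2", z[, 1:10]), "width mismatch")
  expect_error(activations_at(net, imgs, "nope"), "valid layers")
  # layer order is total, input-adjacent first
  expect_equal(layer_names(net)[1], "conv1")
  expect_equal(utils::tail(layer_names(net), 1), "logits")
})

test_that("training is deterministic for a fixed seed and learns", {
  imgs <- generate_images(3, 12, size = c(16, 16), seed = 9)
  spec <- net_spec(input_shape = c(16, 16, 3), conv_widths = c(4, 8),
                   dense_widths = 16, m = 3, dropout = 0)
  h <- list(max_epochs = 2, lr = 0.01)
  n1 <- train_net(spec, imgs, hyper = h, seed = 21)
  n2 <- train_net(spec, imgs, hyper = h, seed = 21)
  expect_identical(n1$layers, n2$layers)
  n3 <- train_net(spec, imgs, hyper = h, seed = 22)
  expect_false(identical(n1$layers, n3$layers))
  # the memoized tiny net has converged on its training distribution
  net <- tiny_net()
  P <- forward_full(net, tiny_images())
  acc <- mean(max.col(unclass(P), ties.method = "first") == tiny_images()$labels)
  expect_gte(acc, 0.95)
})

test_that("learning-rate halving follows the plateau patience rule", {
  net <- tiny_net()
  h <- net$history
  drops <- which(diff(h$lr) < 0)
  for (d in drops) {
    # the 4 epochs before a drop never improved on the running best loss
    best_before <- min(h$val_loss[seq_len(max(1, d - 4))])
    expect_true(all(h$val_loss[(d - 3):d] >= best_before - 1e-5) || d <= 4)
  }
  # and lr never drops without at least lr_patience epochs of history
  if (length(drops)) expect_true(min(drops) >= 4)
  expect_true(all(h$lr <= h$lr[1]))
})

test_that("checkpoint save/load reproduces the forward pass bit-exactly", {
  net <- tiny_net()
  f <- withr::local_tempfile(fileext = ".rds")
  save_net(net, f)
  net2 <- load_net(f)
  imgs <- tiny_images()[1:10]
  expect_identical(unclass(forward_full(net, imgs)),
                   unclass(forward_full(net2, imgs)))
})
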