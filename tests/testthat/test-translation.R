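test_that("neural preprocessing centers and scales on training rows only", {
  set.seed(4)
  x <- scale(matrix(rnorm(200), 20))  # already centered, unit scale
  p <- preprocess_neural(x)
  expect_equal(p$rows, unclass(x), tolerance = 1e-8, ignore_attr = TRUE)
  # constant column maps to zeros, no division failure
  x2 <- cbind(x, 5)
  p2 <- preprocess_neural(x2)
  expect_equal(p2$rows[, 11], rep(0, 20))
  expect_equal(p2$params$scale[11], 1)
  # held-out rows transformed with train params keep nonzero column means
  ho <- matrix(rnorm(50, mean = 2), 5)
  ho_t <- apply_preproc(preprocess_neural(matrix(rnorm(200), 20))$params, ho)
  expect_gt(max(abs(colMeans(ho_t))), 0.1)
})

test_that("noise-free linear targets are recovered with high held-out R2", {
  net <- tiny_net()
  imgs <- tiny_images()
  acts <- activations_at(net, imgs, "fc1")
  rec <- simulate_region(net, imgs, "fc1", d = 32, noise_sd = 0, seed = 3)
  set.seed(9)
  ho <- sample(160, 40); tr <- setdiff(1:160, ho)
  targets <- layer_activation("fc1", acts$values[tr, ], 32)
  r2 <- function(map) {
    pred <- apply_translation(map, rec$data[ho, ])$values
    truth <- acts$values[ho, ]
    1 - sum((pred - truth)^2) / sum(sweep(truth, 2, colMeans(truth))^2)
  }
  map_r <- fit_translation_mse(rec$data[tr, ], targets,
                               hyper = list(optimizer = "ridge"), seed = 4)
  expect_gte(r2(map_r), 0.99)
  map_s <- fit_translation_mse(rec$data[tr, ], targets,
                               hyper = list(optimizer = "sgd",
                                            stop_patience = 100,
                                            lr_patience = 10,
                                            min_delta = 1e-9,
                                            max_epochs = 400), seed = 4)
  expect_gte(r2(map_s), 0.99)
  # the SGD reference and the closed-form fast path agree
  expect_lt(abs(r2(map_s) - r2(map_r)), 0.01)
  expect_equal(map_r$target_layer, "fc1")
})

test_that("zero targets drive W toward zero under the l2 penalty", {
  set.seed(6)
  x <- matrix(rnorm(600), 60)
  zero_t <- matrix(0, 60, 16)
  map <- fit_translation_mse(x, zero_t, hyper = list(optimizer = "sgd",
                                                     max_epochs = 200), seed = 1)
  expect_lt(max(abs(map$W)), 0.05)
  pred <- apply_translation(map, matrix(rnorm(100), 10))
  expect_lt(max(abs(pred$values)), 0.2)
})

test_that("jointly permuting rows and targets leaves the fit unchanged", {
  set.seed(8)
  x <- matrix(rnorm(400), 40)
  y <- x %*% matrix(rnorm(50), 10, 5) + 1
  perm <- sample(40)
  m1 <- fit_translation_mse(x, y, hyper = list(optimizer = "ridge"), seed = 1)
  m2 <- fit_translation_mse(x[perm, ], y[perm, ], hyper = list(optimizer = "ridge"),
                            seed = 1)
  expect_equal(m1$W, m2$W, tolerance = 1e-9)
  expect_equal(m1$resid_mse, m2$resid_mse, tolerance = 1e-9)
})

test_that("translation application is linear after preprocessing", {
  set.seed(3)
  x <- matrix(rnorm(300), 30)
  y <- x %*% matrix(rnorm(40), 10, 4)
  map <- fit_translation_mse(x, y, hyper = list(optimizer = "ridge"), seed = 2)
  # operate in preprocessed coordinates: invert the preprocessing for inputs
  px <- map$preproc
  unprep <- function(z) sweep(sweep(z, 2, px$scale, "*"), 2, px$center, "+")
  a <- matrix(rnorm(20), 2); b <- matrix(rnorm(20), 2)
  lhs <- apply_translation(map, unprep(2 * a + 3 * b))$values
  rhs <- 2 * apply_translation(map, unprep(a))$values +
    3 * apply_translation(map, unprep(b))$values -
    4 * rep(map$target_center, each = 2)  # bias enters once per application
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("no training information leaks from held-out rows", {
  set.seed(12)
  x <- matrix(rnorm(500), 50)
  y <- x %*% matrix(rnorm(30), 10, 3)
  tr <- 1:35; ho <- 36:50
  before <- sum(x[ho, ]^2)
  map <- fit_translation_mse(x[tr, ], y[tr, ], hyper = list(optimizer = "ridge"),
                             seed = 1)
  expect_identical(sum(x[ho, ]^2), before)
  # preprocessing params derived from training rows only
  expect_equal(map$preproc$center, colMeans(x[tr, ]))
})

test_that("end-to-end mode trains only W and needs real labels", {
  net <- tiny_net()
  imgs <- tiny_images()
  rec <- simulate_region(net, imgs, "fc1", d = 32, noise_sd = 0, seed = 3)
  set.seed(10)
  ho <- sample(160, 40); tr <- setdiff(1:160, ho)
  weights_before <- net$layers
  map <- fit_translation_end_to_end(rec$data[tr, ], imgs$labels[tr], net, "fc1",
                                    hyper = list(max_epochs = 25), seed = 2)
  expect_identical(net$layers, weights_before)
  P <- forward_from(net, "fc1", apply_translation(map, rec$data[ho, ]))
  expect_gt(multiclass_auc(P, imgs$labels[ho]), 0.8)
  # shuffled labels carry no signal
  shuf <- with_seed(5, sample(imgs$labels[tr]))
  map0 <- fit_translation_end_to_end(rec$data[tr, ], shuf, net, "fc1",
                                     hyper = list(max_epochs = 25), seed = 2)
  P0 <- forward_from(net, "fc1", apply_translation(map0, rec$data[ho, ]))
  expect_lt(abs(multiclass_auc(P0, imgs$labels[ho]) - 0.5), 0.12)
})

test_that("PCA-latent translation reduces to the direct fit at full rank", {
  net <- tiny_net()
  imgs <- tiny_images()
  acts <- activations_at(net, imgs, "fc1")
  rec <- simulate_region(net, imgs, "fc1", d = 32, noise_sd = 0, seed = 3)
  set.seed(13)
  ho <- sample(160, 40); tr <- setdiff(1:160, ho)
  targets <- layer_activation("fc1", acts$values[tr, ], 32)
  pca_ind <- activations_at(net, generate_images(4, 30, size = c(16, 16),
                                                 seed = 77), "fc1")
  full <- fit_translation_pca_target(rec$data[tr, ], targets, r = 30,
                                     pca_fit_set = pca_ind,
                                     hyper = list(optimizer = "ridge"), seed = 5)
  direct <- fit_translation_mse(rec$data[tr, ], targets,
                                hyper = list(optimizer = "ridge"), seed = 5)
  P_full <- forward_from(net, "fc1", apply_translation(full, rec$data[ho, ]))
  P_dir <- forward_from(net, "fc1", apply_translation(direct, rec$data[ho, ]))
  auc_full <- multiclass_auc(P_full, imgs$labels[ho])
  auc_dir <- multiclass_auc(P_dir, imgs$labels[ho])
  expect_lt(abs(auc_full - auc_dir), 0.03)
  # a rank-1 bottleneck loses task information
  r1 <- fit_translation_pca_target(rec$data[tr, ], targets, r = 1,
                                   pca_fit_set = pca_ind,
                                   hyper = list(optimizer = "ridge"), seed = 5)
  P_r1 <- forward_from(net, "fc1", apply_translation(r1, rec$data[ho, ]))
  expect_lt(multiclass_auc(P_r1, imgs$labels[ho]), auc_full - 0.05)
  expect_error(fit_translation_pca_target(rec$data[tr, ], targets, r = 10000,
                                          pca_fit_set = pca_ind),
               "exceeds")
})
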