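test_that("stationarization yields zero-mean unit-variance bins, idempotently", {
  set.seed(1)
  m <- matrix(rnorm(50 * 12, mean = 3, sd = 2), 50)
  m[, 6] <- m[, 6] + 10  # strong stimulus-locked bump
  s <- stationarize(m)
  expect_lt(max(abs(colMeans(s))), 1e-6)
  expect_lt(max(abs(apply(s, 2, sd) - 1)), 1e-6)
  s2 <- stationarize(s)
  expect_equal(s, s2, tolerance = 1e-6)
  # a constant trial falls back to scale 1 (zeros after its own centering)
  # and never produces non-finite values
  m[3, ] <- 7
  expect_true(all(is.finite(stationarize(m))))
  expect_true(all(is.finite(stationarize(matrix(5, 4, 6)))))
})

test_that("Granger LR machinery is nested, symmetric and affine-invariant", {
  set.seed(2)
  mx <- matrix(rnorm(15 * 25), 15)
  my <- matrix(rnorm(15 * 25), 15)
  g <- fit_granger_pair(mx, my, p_max = 4)
  expect_gte(g$x_to_y$loglik_causal, g$x_to_y$loglik_null)
  expect_gte(g$y_to_x$loglik_causal, g$y_to_x$loglik_null)
  expect_gte(g$x_to_y$p, 1)
  # swapping the series swaps the two results exactly
  g2 <- fit_granger_pair(my, mx, p_max = 4)
  expect_equal(g$x_to_y$lr_statistic, g2$y_to_x$lr_statistic)
  expect_equal(g$y_to_x$p_value, g2$x_to_y$p_value)
  # affine rescaling of the inputs leaves the LR unchanged
  g3 <- fit_granger_pair(3 * mx + 1, -2 * my + 5, p_max = 4)
  expect_equal(g$x_to_y$lr_statistic, g3$x_to_y$lr_statistic, tolerance = 1e-8)
  expect_error(fit_granger_pair(mx[, 1:4], my[, 1:4], p_max = 4), "too short")
})

test_that("BIC prefers small lag orders on white noise", {
  set.seed(3)
  ps <- replicate(40, {
    fit_granger_pair(matrix(rnorm(10 * 30), 10), matrix(rnorm(10 * 30), 10),
                     p_max = 5)$x_to_y$p
  })
  expect_gt(mean(ps == 1), 0.5)
})

test_that("single-trial fits agree with the standard Granger test", {
  skip_if_not_installed("lmtest")
  set.seed(4)
  Tt <- 250
  x <- rnorm(Tt)
  y <- 0.8 * c(0, 0, x[1:(Tt - 2)]) + rnorm(Tt, sd = 0.7)
  g <- fit_granger_pair(matrix(x, 1), matrix(y, 1), p_max = 3)
  ref <- lmtest::grangertest(y ~ x, order = g$x_to_y$p)
  # same decision and comparable p-values (LR chi-square vs Wald F)
  expect_true(g$x_to_y$significant)
  expect_lt(ref$`Pr(>F)`[2], 0.05)
  expect_equal(log10(g$x_to_y$p_value), log10(ref$`Pr(>F)`[2]), tolerance = 0.35)
})

test_that("expanding-window timeline localizes a late-onset coupling", {
  set.seed(5)
  n <- 40; Tt <- 30
  mx <- matrix(rnorm(n * Tt), n)
  my <- matrix(rnorm(n * Tt), n)
  # coupling switches on at bin 16 with lag 2
  my[, 18:Tt] <- my[, 18:Tt] + 1.2 * mx[, 16:(Tt - 2)]
  tl <- run_granger_timeline(mx, my, start_bin = 1, p_max = 3)
  expect_false(is.na(tl$onset_x_to_y))
  expect_gte(tl$onset_x_to_y, 17)
  expect_true(is.na(tl$onset_y_to_x) || tl$onset_y_to_x > tl$onset_x_to_y)
  expect_s3_class(generics::tidy(tl), "tbl_df")
  expect_s3_class(ggplot2::autoplot(tl), "ggplot")
  expect_error(run_granger_timeline(mx, my, min_len = 2, p_max = 3),
               "p_max")
})

test_that("bin-wise KL interfacing separates informative from pre-stimulus bins", {
  net <- tiny_net()
  imgs <- tiny_images()
  trials <- with_seed(6, imgs[sample(160, 100, replace = TRUE)])
  spec <- dynamics_spec()
  two <- simulate_two_region_dynamics(net, trials, spec, seed = 7)
  fp <- make_fold_plan(trials$labels, k = 4, seed = 8)
  kl <- binwise_interface_kl(net, "fc1", two$it, trials, fold_plan = fp, seed = 9)
  expect_equal(dim(kl$values), c(100, spec$t_bins))
  expect_true(all(kl$values >= 0))
  kl_shuf <- binwise_interface_kl(net, "fc1", two$it, trials, fold_plan = fp,
                                  shuffle_labels = TRUE, seed = 9)
  pre <- 1:(spec$stimulus_on - 1)
  post <- (spec$stimulus_on + spec$feedforward_lag + 1):(spec$stimulus_off)
  # pre-stimulus bins: indistinguishable from the shuffled control (medians --
  # per-trial KL of noise fits is heavy-tailed, means are unstable)
  expect_lt(abs(median(kl$values[, pre]) - median(kl_shuf$values[, pre])), 0.15)
  # post-onset bins: clearly below the shuffled control
  expect_lt(median(kl$values[, post]) + 0.2, median(kl_shuf$values[, post]))
})

test_that("constant recordings at a bin degrade gracefully", {
  net <- tiny_net()
  imgs <- tiny_images()[1:40]
  arr <- array(stats::runif(40 * 4 * 6), c(40, 4, 6))
  arr[, 2, ] <- 1  # dead bin
  rec <- recording_set(arr, bin_width = 10, bin_onsets = c(0, 10, 20, 30))
  kl <- binwise_interface_kl(net, "fc1", rec, imgs,
                             fold_plan = make_fold_plan(imgs$labels, k = 4, seed = 2),
                             seed = 3)
  expect_true(all(is.finite(kl$values)))
})
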