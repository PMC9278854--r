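#' Center and scale neural features using training rows only
#'
#' Columns of the training slice are centered and scaled so each has mean 0
#' and, under the default `"zscore"` convention, unit standard deviation
#' (`"unitnorm"` scales to unit Euclidean norm instead). The returned
#' parameters are reusable on held-out rows via [apply_preproc()], which is
#' how all translation fits avoid leaking evaluation statistics. Zero-variance
#' (dead) columns get scale 1, so they map to all-zeros after centering and
#' never error.
#'
#' @param rows numeric matrix (training rows x features) or a static
#'   `recording_set`.
#' @param method `"zscore"` (default) or `"unitnorm"`.
#' @return A list with `params` (class `neural_preproc`: `center`, `scale`,
#'   `method`) and `rows` (the transformed training rows).
#' @export
preprocess_neural <- function(rows, method = c("zscore", "unitnorm")) {
  method <- match.arg(method)
  x <- as_feature_matrix(rows)
  assert_that(nrow(x) >= 2, "need at least two training rows")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  scale <- if (method == "zscore") {
    apply(xc, 2, stats::sd)
  } else {
    sqrt(colSums(xc^2))
  }
  scale[!is.finite(scale) | scale <= 0] <- 1
  params <- structure(list(center = center, scale = scale, method = method),
                      class = "neural_preproc")
  list(params = params, rows = sweep(xc, 2, scale, "/"))
}

#' Apply stored preprocessing parameters to new rows
#' @param params a `neural_preproc` from [preprocess_neural()].
#' @param rows matrix or static `recording_set` with matching feature count.
#' @return Transformed matrix.
#' @export
apply_preproc <- function(params, rows) {
  x <- as_feature_matrix(rows)
  assert_that(ncol(x) == length(params$center),
              "feature count does not match preprocessing parameters")
  sweep(sweep(x, 2, params$center), 2, params$scale, "/")
}

as_feature_matrix <- function(rows) {
  if (inherits(rows, "recording_set")) {
    assert_that(length(dim(rows$data)) == 2,
                "temporal recordings must be sliced to one bin first")
    rows$data
  } else if (inherits(rows, "layer_activation")) {
    rows$values
  } else {
    as.matrix(rows)
  }
}

default_translation_hyper <- function() {
  list(optimizer = "sgd", batch_size = 64, momentum = 0.9, l2 = 3e-4,
       lr = 0.1, lr_factor = 0.5, lr_patience = 4, max_epochs = 400,
       stop_patience = 20, val_fraction = 0.1, min_delta = 1e-7,
       adadelta_rho = 0.95, adadelta_eps = 1e-6, verbose = FALSE)
}

# Closed-form ridge solution of the same objective the SGD engine minimizes:
# mean squared residual over all entries plus l2 * ||W||_F^2, whose stationary
# point is (X'X + n*u*l2 I) W = X'Y.
fit_linear_ridge <- function(X, Y, l2) {
  n <- nrow(X); u <- ncol(Y)
  lam <- n * u * l2
  A <- crossprod(X)
  diag(A) <- diag(A) + max(lam, 1e-10)
  W <- solve(A, crossprod(X, Y))
  list(W = W, history = NULL)
}

# Mini-batch linear regression engine: SGD with momentum or Adadelta, l2
# penalty, plateau-halving schedule, early stopping on a held-in validation
# split of the training rows.
fit_linear_sgd <- function(X, Y, hp, seed) {
  n <- nrow(X); d <- ncol(X); u <- ncol(Y)
  with_seed(derive_seed(seed, "translation_sgd"), {
    n_val <- max(2L, round(n * hp$val_fraction))
    val <- sample(n, n_val)
    tr <- setdiff(seq_len(n), val)
    Xtr <- X[tr, , drop = FALSE]; Ytr <- Y[tr, , drop = FALSE]
    Xva <- X[val, , drop = FALSE]; Yva <- Y[val, , drop = FALSE]
    W <- matrix(rnorm(d * u, sd = sqrt(2 / (d + u))), d, u)
    vel <- W * 0
    eg2 <- W * 0; ed2 <- W * 0   # adadelta accumulators
    lr <- hp$lr
    best <- Inf; lr_wait <- 0L; stop_wait <- 0L
    hist <- numeric(0)
    adadelta <- identical(hp$optimizer, "adadelta")
    bs <- if (adadelta) max(hp$batch_size, 128) else hp$batch_size
    for (epoch in seq_len(hp$max_epochs)) {
      ord <- sample(length(tr))
      for (bidx in batched(length(ord), bs)) {
        rows <- ord[bidx]
        Xb <- Xtr[rows, , drop = FALSE]
        R <- Xb %*% W - Ytr[rows, , drop = FALSE]
        g <- (2 / (length(rows) * u)) * crossprod(Xb, R) + 2 * hp$l2 * W
        if (!all(is.finite(g))) stop("non-finite loss in translation fit", call. = FALSE)
        if (adadelta) {
          eg2 <- hp$adadelta_rho * eg2 + (1 - hp$adadelta_rho) * g * g
          delta <- -sqrt(ed2 + hp$adadelta_eps) / sqrt(eg2 + hp$adadelta_eps) * g
          ed2 <- hp$adadelta_rho * ed2 + (1 - hp$adadelta_rho) * delta * delta
          W <- W + lr * delta
        } else {
          vel <- hp$momentum * vel - lr * g
          W <- W + vel
        }
      }
      vloss <- mean((Xva %*% W - Yva)^2)
      hist <- c(hist, vloss)
      if (!is.finite(vloss)) stop("non-finite loss in translation fit", call. = FALSE)
      if (hp$verbose && epoch %% 10 == 0)
        message(sprintf("  translation epoch %d val mse %.5g lr %.3g", epoch, vloss, lr))
      if (vloss < best - hp$min_delta) {
        best <- vloss; lr_wait <- 0L; stop_wait <- 0L
      } else {
        lr_wait <- lr_wait + 1L; stop_wait <- stop_wait + 1L
        if (lr_wait >= hp$lr_patience) { lr <- lr * hp$lr_factor; lr_wait <- 0L }
        if (stop_wait >= hp$stop_patience) break
      }
    }
    list(W = W, history = hist)
  })
}

new_translation_map <- function(W, preproc, mode, target_layer, spatial_shape,
                                source_region = NA_character_, latent = NULL,
                                resid_mse = NA_real_, history = NULL,
                                target_center = NULL) {
  structure(list(W = W, preproc = preproc, mode = mode,
                 target_layer = target_layer, spatial_shape = spatial_shape,
                 source_region = source_region, latent = latent,
                 resid_mse = resid_mse, history = history,
                 target_center = target_center),
            class = "translation_map")
}

#' @export
print.translation_map <- function(x, ...) {
  cat(sprintf("<translation_map> %s: %d features -> layer %s (%d units%s)\n",
              x$mode, nrow(x$W), x$target_layer, prod(x$spatial_shape),
              if (!is.null(x$latent)) sprintf(", latent rank %d", ncol(x$W)) else ""))
  if (is.finite(x$resid_mse))
    cat(sprintf("  training residual mean square: %.5g\n", x$resid_mse))
  invisible(x)
}

#' Learn a linear brain-to-layer translation by mean squared error
#'
#' Fits the linear transform W mapping preprocessed neural features to a
#' layer's activations, minimizing mean squared error. W has no bias and no
#' nonlinearity. The reference optimizer is mini-batch SGD with momentum
#' (batch 64, momentum 0.9, l2 3e-4, initial learning rate 0.1, halved after 4
#' epochs without validation improvement, stopping at 400 epochs or after 20
#' without improvement); `optimizer = "adadelta"` (batch 128) is the
#' trial-level variant and `optimizer = "ridge"` is a closed-form solution of
#' the same penalized objective, used as a fast path.
#'
#' @param rows training-partition neural rows (matrix or static
#'   `recording_set`). Preprocessing (centering/scaling) is fitted on these
#'   rows only and stored in the map.
#' @param targets `layer_activation` (or matrix) of the corresponding images'
#'   activations at the target layer, training partition only.
#' @param hyper named list overriding [default_translation_hyper()]; notably
#'   `optimizer` ("sgd", "adadelta", "ridge") and `l2`.
#' @param seed seed for the fit.
#' @param source_region optional region name stored in the map.
#' @return A `translation_map`.
#' @export
fit_translation_mse <- function(rows, targets, hyper = list(), seed = 1,
                                source_region = NA_character_) {
  hp <- utils::modifyList(default_translation_hyper(), hyper)
  Y <- if (inherits(targets, "layer_activation")) targets$values else as.matrix(targets)
  pre <- preprocess_neural(rows, method = hp$preproc_method %||% "zscore")
  X <- pre$rows
  assert_that(nrow(X) == nrow(Y), "row counts of recordings and targets differ")
  # Targets are centered with training means (restored at application): with
  # exactly centered inputs a bias-free W cannot represent the target means.
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)
  fit <- if (identical(hp$optimizer, "ridge")) fit_linear_ridge(X, Yc, hp$l2)
         else fit_linear_sgd(X, Yc, hp, seed)
  resid <- X %*% fit$W - Yc
  new_translation_map(
    fit$W, pre$params, mode = "mse",
    target_layer = if (inherits(targets, "layer_activation")) targets$layer else NA_character_,
    spatial_shape = if (inherits(targets, "layer_activation")) targets$spatial_shape else ncol(Y),
    source_region = source_region, resid_mse = mean(resid^2),
    history = fit$history, target_center = y_center)
}

#' Learn the translation end to end from class labels
#'
#' Alternative training mode: W is composed with the frozen downstream network
#' from layer `q` and trained by back-propagating categorical cross-entropy
#' from the softmax output against the ground-truth labels. Only W's entries
#' change; every network parameter stays bit-identical.
#'
#' @param rows training neural rows.
#' @param labels integer class labels (1-based) for those rows.
#' @param net a `trained_net`, frozen.
#' @param q injection layer name.
#' @param hyper overrides: `lr` (default 0.05 for this mode), `l2`,
#'   `batch_size`, `max_epochs` (default 80), patience settings.
#' @param seed seed.
#' @param source_region optional region name.
#' @return A `translation_map` with mode `"end_to_end"`.
#' @export
fit_translation_end_to_end <- function(rows, labels, net, q, hyper = list(),
                                       seed = 1, source_region = NA_character_) {
  hp <- utils::modifyList(
    utils::modifyList(default_translation_hyper(),
                      list(lr = 0.05, max_epochs = 80)),
    hyper)
  check_layer(net, q)
  pre <- preprocess_neural(rows, method = hp$preproc_method %||% "zscore")
  X <- pre$rows
  labels <- as.integer(labels)
  assert_that(nrow(X) == length(labels), "row/label counts differ")
  d <- ncol(X); u <- layer_width(net, q)
  start <- net$points[[q]] + 1L
  logits_i <- net$points[["logits"]]
  with_seed(derive_seed(seed, "translation_e2e"), {
    n <- nrow(X)
    n_val <- max(2L, round(n * hp$val_fraction))
    val <- sample(n, n_val)
    tr <- setdiff(seq_len(n), val)
    W <- matrix(rnorm(d * u, sd = 0.01), d, u)
    vel <- W * 0
    lr <- hp$lr
    best <- Inf; lr_wait <- 0L; stop_wait <- 0L
    hist <- numeric(0)
    for (epoch in seq_len(hp$max_epochs)) {
      ord <- sample(length(tr))
      for (bidx in batched(length(ord), hp$batch_size)) {
        rows_b <- tr[ord[bidx]]
        Xb <- X[rows_b, , drop = FALSE]
        yb <- labels[rows_b]
        acts <- Xb %*% W
        fwd <- nf_forward(net, acts, train = FALSE, start = start,
                          stop_at = "logits", keep_cache = TRUE)
        probs <- softmax_rows(fwd$out)
        loss <- cross_entropy(probs, yb)
        if (!is.finite(loss)) stop("non-finite loss in end-to-end fit", call. = FALSE)
        dlogits <- probs
        dlogits[cbind(seq_along(yb), yb)] <- dlogits[cbind(seq_along(yb), yb)] - 1
        dlogits <- dlogits / length(yb)
        bwd <- nf_backward(net, fwd$caches, dlogits, from = logits_i, to = start)
        g <- crossprod(Xb, bwd$dx) + 2 * hp$l2 * W
        vel <- hp$momentum * vel - lr * g
        W <- W + vel
      }
      # validation cross-entropy
      av <- X[val, , drop = FALSE] %*% W
      pv <- forward_from(net, q, layer_activation(q, av, net$shapes[[q]]))
      vloss <- cross_entropy(unclass(pv), labels[val])
      hist <- c(hist, vloss)
      if (vloss < best - hp$min_delta) {
        best <- vloss; lr_wait <- 0L; stop_wait <- 0L
      } else {
        lr_wait <- lr_wait + 1L; stop_wait <- stop_wait + 1L
        if (lr_wait >= hp$lr_patience) { lr <- lr * hp$lr_factor; lr_wait <- 0L }
        if (stop_wait >= hp$stop_patience) break
      }
    }
    new_translation_map(W, pre$params, mode = "end_to_end", target_layer = q,
                        spatial_shape = net$shapes[[q]],
                        source_region = source_region, history = hist)
  })
}

#' Learn the translation into a PCA latent space of layer activations
#'
#' Principal axes are fitted on an independent activation sample (never the
#' training targets themselves unless explicitly passed); the training targets
#' are reduced to the leading `r` components, W maps neural features to that
#' r-dimensional code, and application reconstructs full-width activations
#' through the stored axes.
#'
#' @param rows training neural rows.
#' @param targets training-partition `layer_activation` targets.
#' @param r latent rank, at most `min(pca sample rows - 1, layer width)`.
#' @param pca_fit_set `layer_activation` sample used to fit the principal
#'   axes; should be independent of `rows`/`targets`.
#' @param hyper optimizer overrides as in [fit_translation_mse()].
#' @param seed seed.
#' @param source_region optional region name.
#' @return A `translation_map` with mode `"pca_target"` and a stored latent
#'   projection.
#' @export
fit_translation_pca_target <- function(rows, targets, r, pca_fit_set,
                                       hyper = list(), seed = 1,
                                       source_region = NA_character_) {
  hp <- utils::modifyList(default_translation_hyper(), hyper)
  Y <- if (inherits(targets, "layer_activation")) targets$values else as.matrix(targets)
  S <- if (inherits(pca_fit_set, "layer_activation")) pca_fit_set$values else as.matrix(pca_fit_set)
  assert_that(r >= 1, "latent rank must be at least 1")
  assert_that(r <= min(nrow(S) - 1L, ncol(S)),
              sprintf("latent rank %d exceeds the PCA sample capacity (%d)",
                      r, min(nrow(S) - 1L, ncol(S))))
  center <- colMeans(S)
  sv <- svd(sweep(S, 2, center), nu = 0, nv = r)
  rot <- sv$v
  codes <- sweep(Y, 2, center) %*% rot
  pre <- preprocess_neural(rows, method = hp$preproc_method %||% "zscore")
  X <- pre$rows
  code_center <- colMeans(codes)
  codes_c <- sweep(codes, 2, code_center)
  fit <- if (identical(hp$optimizer, "ridge")) fit_linear_ridge(X, codes_c, hp$l2)
         else fit_linear_sgd(X, codes_c, hp, seed)
  resid <- X %*% fit$W - codes_c
  new_translation_map(
    fit$W, pre$params, mode = "pca_target",
    target_layer = if (inherits(targets, "layer_activation")) targets$layer else NA_character_,
    spatial_shape = if (inherits(targets, "layer_activation")) targets$spatial_shape else ncol(Y),
    source_region = source_region,
    latent = list(rotation = rot, center = center, rank = r),
    resid_mse = mean(resid^2), history = fit$history,
    target_center = code_center)
}

#' Translate neural rows into layer activations
#'
#' Applies the stored training-set preprocessing, then W (and, for PCA-latent
#' maps, the reconstruction through the stored axes). The result is tagged
#' with the target layer so [forward_from()] can verify the injection point.
#'
#' @param map a `translation_map`.
#' @param rows neural rows (matrix or static `recording_set`) with the
#'   training feature count.
#' @return A `layer_activation` at the map's target layer.
#' @export
apply_translation <- function(map, rows) {
  X <- apply_preproc(map$preproc, rows)
  assert_that(ncol(X) == nrow(map$W), "row width does not match the translation map")
  Z <- X %*% map$W
  if (!is.null(map$target_center)) Z <- sweep(Z, 2, map$target_center, "+")
  if (!is.null(map$latent)) {
    Z <- sweep(Z %*% t(map$latent$rotation), 2, map$latent$center, "+")
  }
  layer_activation(map$target_layer, Z, map$spatial_shape)
}
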