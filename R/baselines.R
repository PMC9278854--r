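#' MVPA classifier baselines on neural recordings
#'
#' The conventional decoding comparison: three standard classifiers are fitted
#' per cross-validation fold directly on the (per-fold z-scored) recordings --
#' multinomial logistic regression, a single nearest neighbor under Euclidean
#' distance, and a linear support vector machine with a one-versus-rest
#' multiclass strategy and `C = 1e-3` (decision-function values as scores, no
#' probability calibration). Held-out scores are pooled and converted to the
#' same Hand-Till multiclass AUC used by the interfacing analyses, so the two
#' approaches are directly comparable.
#'
#' @param recordings static `recording_set` or matrix.
#' @param labels integer class labels (1-based).
#' @param fold_plan a [make_fold_plan()]; defaults to stratified 8-fold.
#' @param methods subset of `c("logistic", "nearest_neighbor", "linear_svm")`.
#' @param seed seed.
#' @return A `baseline_result` with a tibble `results` (method, auc) and
#'   per-fold details.
#' @export
mvpa_suite <- function(recordings, labels, fold_plan = NULL,
                       methods = c("logistic", "nearest_neighbor", "linear_svm"),
                       seed = 1) {
  x <- as_feature_matrix(recordings)
  labels <- as.integer(labels)
  assert_that(nrow(x) == length(labels), "row/label counts differ")
  m <- max(labels)
  if (is.null(fold_plan)) fold_plan <- make_fold_plan(labels, k = 8, seed = seed)
  scores <- lapply(methods, function(i) matrix(NA_real_, nrow(x), m))
  names(scores) <- methods
  for (f in seq_along(fold_plan$folds)) {
    hold <- fold_plan$folds[[f]]
    train <- setdiff(seq_len(nrow(x)), hold)
    assert_that(length(unique(labels[train])) >= 2,
                "fewer than two classes in a training fold")
    pre <- preprocess_neural(x[train, , drop = FALSE])
    xtr <- pre$rows
    xho <- apply_preproc(pre$params, x[hold, , drop = FALSE])
    ytr <- factor(labels[train], levels = seq_len(m))
    if ("logistic" %in% methods) {
      fit <- with_seed(derive_seed(seed, paste("logit", f)),
        nnet::multinom(ytr ~ ., data = data.frame(xtr), maxit = 1000,
                       MaxNWts = 100000, trace = FALSE))
      pr <- predict(fit, newdata = data.frame(xho), type = "probs")
      if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two-class case
      # multinom drops empty levels from its output columns
      cols <- as.integer(colnames(pr) %||% seq_len(ncol(pr)))
      tmp <- matrix(0, length(hold), m); tmp[, cols] <- pr
      scores$logistic[hold, ] <- tmp
    }
    if ("nearest_neighbor" %in% methods) {
      pred <- class::knn(xtr, xho, cl = ytr, k = 1)
      oh <- matrix(0, length(hold), m)
      oh[cbind(seq_along(hold), as.integer(as.character(pred)))] <- 1
      scores$nearest_neighbor[hold, ] <- oh
    }
    if ("linear_svm" %in% methods) {
      # one-versus-rest with decision values, as in the reference analysis
      dv <- matrix(NA_real_, length(hold), m)
      for (k in sort(unique(labels[train]))) {
        yk <- factor(labels[train] == k, levels = c(FALSE, TRUE))
        fit <- e1071::svm(xtr, yk, kernel = "linear", cost = 1e-3,
                          scale = FALSE)
        d <- attr(predict(fit, xho, decision.values = TRUE), "decision.values")
        # orient scores so larger = more class-k
        sgn <- if (grepl("^TRUE", colnames(d)[1])) 1 else -1
        dv[, k] <- sgn * d[, 1]
      }
      dv[is.na(dv)] <- min(dv, na.rm = TRUE) - 1
      scores$linear_svm[hold, ] <- dv
    }
  }
  results <- purrr::map_dfr(methods, function(meth) {
    tibble::tibble(method = meth, auc = multiclass_auc(scores[[meth]], labels))
  })
  structure(list(results = results, scores = scores, labels = labels,
                 fold_plan = fold_plan, seed = seed),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat("<baseline_result>\n")
  print(x$results)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.baseline_result <- function(x, ...) x$results

#' Shared-variance neural predictivity (PCA + PLS encoding baseline)
#'
#' The conventional correspondence measure, mapping model to brain (the
#' opposite direction to interfacing): per fold, the principal axes of the
#' probed layer's activations are computed on training images, a partial least
#' squares regression predicts each recording feature from the reduced
#' activations, and predictivity is the Pearson correlation between predicted
#' and observed held-out values per feature, summarized by the median feature
#' (the "median electrode").
#'
#' @param net a `trained_net`.
#' @param images paired [image_set()].
#' @param recordings static `recording_set` or matrix.
#' @param layer probed layer name.
#' @param fold_plan a [make_fold_plan()]; defaults to stratified 8-fold.
#' @param n_pcs number of principal components of the layer activations
#'   (capped at training rank).
#' @param n_pls number of PLS components.
#' @param seed seed.
#' @return A `baseline_result` whose `results` tibble has `median_r` and the
#'   per-feature correlations in `per_feature_r`.
#' @export
neural_predictivity <- function(net, images, recordings, layer,
                                fold_plan = NULL, n_pcs = 40, n_pls = 10,
                                seed = 1) {
  x <- as_feature_matrix(recordings)
  labels <- images$labels
  assert_that(nrow(x) == n_images(images), "recordings not row-aligned with images")
  if (is.null(fold_plan)) fold_plan <- make_fold_plan(labels, k = 8, seed = seed)
  acts <- activations_at(net, images, layer)$values
  n <- nrow(x)
  pred <- matrix(NA_real_, n, ncol(x))
  for (f in seq_along(fold_plan$folds)) {
    hold <- fold_plan$folds[[f]]
    train <- setdiff(seq_len(n), hold)
    a_tr <- acts[train, , drop = FALSE]
    keep <- apply(a_tr, 2, stats::sd) > 0
    pc <- stats::prcomp(a_tr[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    k <- min(n_pcs, ncol(pc$x), length(train) - 1L)
    z_tr <- pc$x[, seq_len(k), drop = FALSE]
    z_ho <- predict(pc, acts[hold, keep, drop = FALSE])[, seq_len(k), drop = FALSE]
    ncomp <- min(n_pls, k)
    fit <- mixOmics::pls(z_tr, x[train, , drop = FALSE], ncomp = ncomp,
                         mode = "regression")
    pr <- predict(fit, z_ho)
    pred[hold, ] <- pr$predict[, , ncomp]
  }
  r <- vapply(seq_len(ncol(x)), function(j) {
    if (stats::sd(x[, j]) == 0 || stats::sd(pred[, j]) == 0) return(NA_real_)
    stats::cor(pred[, j], x[, j])
  }, 1)
  structure(list(results = tibble::tibble(method = "pls_predictivity",
                                          layer = layer,
                                          median_r = stats::median(r, na.rm = TRUE),
                                          n_features = sum(!is.na(r))),
                 per_feature_r = r, fold_plan = fold_plan, seed = seed),
            class = "baseline_result")
}

#' Interface pixel-level codes in place of neural data
#'
#' Control analysis: flattened images are reduced to their first
#' `n_components` principal components (axes fitted on an independent image
#' pool) and the codes substitute for recordings in [run_interface_grid()].
#' With ample components the pixel code is nearly lossless, and the best
#' interfaced layer is expected at the earliest conv layer -- showing the
#' substitution approach carries no inherent bias toward late layers.
#'
#' @param images evaluation [image_set()].
#' @param n_components number of pixel principal components.
#' @param net a `trained_net`.
#' @param layers layers to interface (default as in [run_interface_grid()]).
#' @param fold_plan a [make_fold_plan()].
#' @param pca_pool independent [image_set()] for fitting the axes (defaults
#'   to a fresh synthetic pool matched to `images`).
#' @param translation,seed as in [run_interface_grid()].
#' @return A `correspondence_result` (region name `"pixels"`).
#' @export
pixel_interface <- function(images, n_components, net, layers = NULL,
                            fold_plan = NULL, pca_pool = NULL,
                            translation = list(), seed = 1) {
  px <- flatten_images(images$images)
  assert_that(n_components >= 1 && n_components <= ncol(px),
              "n_components must be in 1..pixel count")
  if (is.null(pca_pool)) {
    d <- dim(images$images)
    pca_pool <- generate_images(length(images$class_names),
                                max(2L, ceiling(2 * n_components / length(images$class_names))),
                                size = d[2:3], channels = d[4],
                                seed = derive_seed(seed, "pixel_pool"))
  }
  pool_px <- flatten_images(pca_pool$images)
  center <- colMeans(pool_px)
  r <- min(n_components, nrow(pool_px) - 1L, ncol(pool_px))
  sv <- svd(sweep(pool_px, 2, center), nu = 0, nv = r)
  codes <- sweep(px, 2, center) %*% sv$v
  rec <- recording_set(codes, region_name = "pixels")
  run_interface_grid(net, images, rec, layers = layers,
                     fold_plan = fold_plan, translation = translation,
                     seed = seed)
}
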