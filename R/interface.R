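#' Score region-layer correspondence by direct interfacing
#'
#' For each (region, layer) pair: per cross-validation fold, a linear
#' translation is fitted on the training rows (recordings -> layer
#' activations of the corresponding images), applied to the held-out rows, and
#' the forward pass resumed from the translated activations. Predictions are
#' pooled over folds; correspondence is scored by Hand-Till multiclass AUC
#' against the ground-truth labels and by per-row KL divergence against the
#' image-driven predictions on the same rows (lower KL = better
#' correspondence). Per-fold values are retained for dispersion only.
#'
#' @param net a `trained_net`.
#' @param images paired [image_set()].
#' @param recordings a static `recording_set` or named list of them,
#'   row-aligned with `images`.
#' @param layers character vector of target layer names (default: all conv
#'   block outputs plus hidden dense layers).
#' @param mode translation mode: `"mse"`, `"end_to_end"` or `"pca_target"`.
#' @param fold_plan a [make_fold_plan()]; defaults to stratified 8-fold on the
#'   labels.
#' @param translation hyperparameter overrides passed to the translation fit.
#'   The grid default optimizer is the closed-form ridge fast path; set
#'   `translation = list(optimizer = "sgd")` for the mini-batch reference fit.
#' @param pca_rank latent rank for `mode = "pca_target"`.
#' @param pca_fit_images optional independent [image_set()] used to fit the
#'   principal axes in `pca_target` mode (defaults to `images`, with the
#'   caveat documented in [fit_translation_pca_target()]).
#' @param seed master seed (fans out per region, layer and fold).
#' @return A `correspondence_result`: `grid` tibble (region, layer, auc,
#'   mean_kl, image-driven reference values), `per_fold` tibble, `per_row_kl`,
#'   pooled predictions, and provenance.
#' @export
run_interface_grid <- function(net, images, recordings, layers = NULL,
                               mode = c("mse", "end_to_end", "pca_target"),
                               fold_plan = NULL, translation = list(),
                               pca_rank = NULL, pca_fit_images = NULL,
                               seed = 1) {
  mode <- match.arg(mode)
  if (inherits(recordings, "recording_set")) {
    recordings <- stats::setNames(list(recordings), recordings$region_name)
  }
  assert_that(all(vapply(recordings, function(r) !r$temporal, TRUE)),
              "run_interface_grid expects static recordings; see binwise_interface_kl")
  labels <- images$labels
  n <- n_images(images)
  for (r in recordings) {
    assert_that(dim(r$data)[1] == n, "recordings are not row-aligned with the images")
  }
  if (is.null(layers)) {
    layers <- grep("^(conv[0-9]+[a-z]?|fc[0-9]+)$", layer_names(net), value = TRUE)
  }
  for (q in layers) check_layer(net, q)
  if (is.null(fold_plan)) fold_plan <- make_fold_plan(labels, k = 8, seed = seed)
  P_i <- forward_full(net, images)
  auc_image <- multiclass_auc(P_i, labels)

  trans_hyper <- utils::modifyList(list(optimizer = "ridge"), translation)
  grid_rows <- list(); fold_rows <- list(); kl_store <- list(); pred_store <- list()
  for (rn in names(recordings)) {
    rec <- recordings[[rn]]
    for (q in layers) {
      acts <- activations_at(net, images, q)
      pca_sample <- NULL
      if (mode == "pca_target") {
        pca_sample <- if (is.null(pca_fit_images)) acts
                      else activations_at(net, pca_fit_images, q)
      }
      preds <- matrix(NA_real_, n, net$spec$m)
      fold_metrics <- list()
      for (f in seq_along(fold_plan$folds)) {
        hold <- fold_plan$folds[[f]]
        train <- setdiff(seq_len(n), hold)
        fseed <- derive_seed(seed, paste(rn, q, f, sep = "/"))
        rows_tr <- rec$data[train, , drop = FALSE]
        rows_ho <- rec$data[hold, , drop = FALSE]
        map <- switch(mode,
          mse = fit_translation_mse(
            rows_tr, layer_activation(q, acts$values[train, , drop = FALSE],
                                      acts$spatial_shape),
            hyper = trans_hyper, seed = fseed, source_region = rn),
          end_to_end = fit_translation_end_to_end(
            rows_tr, labels[train], net, q, hyper = trans_hyper,
            seed = fseed, source_region = rn),
          pca_target = fit_translation_pca_target(
            rows_tr, layer_activation(q, acts$values[train, , drop = FALSE],
                                      acts$spatial_shape),
            r = pca_rank %||% min(64L, ncol(rows_tr), ncol(acts$values)),
            pca_fit_set = pca_sample, hyper = trans_hyper, seed = fseed,
            source_region = rn))
        ho_acts <- apply_translation(map, rows_ho)
        P_fold <- forward_from(net, q, ho_acts)
        preds[hold, ] <- P_fold
        fold_auc <- if (length(unique(labels[hold])) >= 2)
          multiclass_auc(P_fold, labels[hold]) else NA_real_
        fold_kl <- mean(kl_rows(P_fold, unclass(P_i)[hold, , drop = FALSE]))
        fold_metrics[[f]] <- tibble::tibble(region = rn, layer = q, fold = f,
                                            n_holdout = length(hold),
                                            auc = fold_auc, mean_kl = fold_kl)
      }
      kl_vec <- kl_rows(preds, unclass(P_i))
      auc <- multiclass_auc(preds, labels)
      grid_rows[[paste(rn, q)]] <- tibble::tibble(
        region = rn, layer = q, auc = auc, mean_kl = mean(kl_vec),
        auc_image = auc_image)
      fold_rows[[paste(rn, q)]] <- dplyr::bind_rows(fold_metrics)
      kl_store[[paste(rn, q, sep = "/")]] <- as.numeric(kl_vec)
      pred_store[[paste(rn, q, sep = "/")]] <- preds
    }
  }
  grid <- dplyr::bind_rows(grid_rows)
  structure(list(grid = grid, per_fold = dplyr::bind_rows(fold_rows),
                 per_row_kl = kl_store, predictions = pred_store,
                 image_predictions = P_i, auc_image = auc_image,
                 layers = layers, mode = mode, fold_plan = fold_plan,
                 seed = seed, translation = trans_hyper),
            class = "correspondence_result")
}

#' @export
print.correspondence_result <- function(x, ...) {
  cat(sprintf("<correspondence_result> mode %s, image-driven AUC %.3f\n",
              x$mode, x$auc_image))
  print(x$grid)
  invisible(x)
}

#' Best-corresponding layer per region
#'
#' By AUC (maximized; exact ties -- common when AUC saturates at 1 -- are
#' broken in favor of the layer with the smaller mean KL, i.e. whose outputs
#' track the image-driven predictions most closely) or by mean KL (minimized).
#'
#' @param x a `correspondence_result`.
#' @param by `"auc"` or `"mean_kl"`.
#' @return Tibble with one row per region.
#' @export
best_layer <- function(x, by = c("auc", "mean_kl")) {
  by <- match.arg(by)
  x$grid |>
    dplyr::group_by(.data$region) |>
    dplyr::arrange(if (by == "auc") dplyr::desc(.data$auc) else .data$mean_kl,
                   .data$mean_kl, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.correspondence_result <- function(x, ...) {
  x$grid |>
    tidyr::pivot_longer(c("auc", "mean_kl"), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(layer = factor(.data$layer, levels = x$layers))
}

#' @exportS3Method generics::glance
glance.correspondence_result <- function(x, ...) {
  b <- best_layer(x)
  tibble::tibble(regions = length(unique(x$grid$region)),
                 layers = length(x$layers), mode = x$mode,
                 auc_image = x$auc_image,
                 best_auc = max(x$grid$auc),
                 best_layer = b$layer[which.max(b$auc)])
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the correspondence grid
#'
#' AUC (and mean KL) by layer, one line per region; the dashed horizontal
#' reference marks the image-driven AUC ceiling and the dotted line chance
#' (0.5).
#'
#' @param object a `correspondence_result`.
#' @param metric `"auc"`, `"mean_kl"`, or `"both"`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.correspondence_result <- function(object, metric = "auc", ...) {
  df <- tidy(object)
  if (metric != "both") df <- dplyr::filter(df, .data$metric == !!metric)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$value,
                                        colour = .data$region,
                                        group = .data$region)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "model layer", y = NULL, colour = "region") +
    ggplot2::theme_minimal()
  if (metric == "both") {
    p <- p + ggplot2::facet_wrap(~metric, scales = "free_y")
  } else if (metric == "auc") {
    p <- p +
      ggplot2::geom_hline(yintercept = object$auc_image, linetype = "dashed") +
      ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
      ggplot2::labs(y = "multiclass AUC (pooled held-out)")
  } else {
    p <- p + ggplot2::labs(y = "mean KL divergence (nats)")
  }
  p
}
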