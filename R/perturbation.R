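#' Perturb a layer's activations and measure downstream deviation
#'
#' Gaussian noise with per-unit standard deviation `gamma` times the unit's
#' activation SD (estimated from the clean activations of `images`) is added
#' at layer `q`; the forward pass is resumed and the activations at
#' `reference_layer` are compared with the unperturbed ones. The default
#' deviation metric is the mean absolute difference normalized by each
#' reference unit's SD (`"nmae"`; `"mse"` and `"cosine"` are available),
#' averaged over units, images and `n_repeats` independent noise draws.
#' A network that attenuates upstream error shows smaller deviation when the
#' perturbed layer lies further from the reference.
#'
#' @param net a `trained_net`.
#' @param images evaluation [image_set()] (also the set over which unit SDs
#'   are estimated).
#' @param layer perturbed layer name; must precede `reference_layer`.
#' @param gamma noise scale (the headline setting is 4.0).
#' @param reference_layer layer at which deviation is measured (default: the
#'   last conv block output).
#' @param metric `"nmae"`, `"mse"` or `"cosine"`.
#' @param n_repeats number of independent noise draws averaged over.
#' @param seed seed for the noise.
#' @return A `perturbation_result`: `deviation` (scalar summary), `per_repeat`
#'   (length `n_repeats`), `per_image` (averaged over repeats), and the
#'   configuration.
#' @export
perturb_and_propagate <- function(net, images, layer, gamma = 4.0,
                                  reference_layer = NULL, metric = c("nmae", "mse", "cosine"),
                                  n_repeats = 8, seed = 1) {
  metric <- match.arg(metric)
  check_layer(net, layer)
  if (is.null(reference_layer)) {
    convs <- grep("^conv[0-9]+[a-z]?$", layer_names(net), value = TRUE)
    reference_layer <- utils::tail(convs, 1)
  }
  check_layer(net, reference_layer)
  assert_that(net$points[[layer]] < net$points[[reference_layer]],
              "the perturbed layer must precede the reference layer")
  assert_that(gamma >= 0, "gamma must be nonnegative")
  both <- activations_at(net, images, c(layer, reference_layer))
  clean_q <- both[[layer]]$values
  clean_ref <- both[[reference_layer]]$values
  sigma_q <- apply(clean_q, 2, stats::sd)
  sigma_ref <- apply(clean_ref, 2, stats::sd)
  live <- sigma_ref > 0
  n <- nrow(clean_q)
  per_repeat <- numeric(n_repeats)
  per_image <- matrix(NA_real_, n, n_repeats)
  with_seed(derive_seed(seed, "perturb"), {
    for (r in seq_len(n_repeats)) {
      if (gamma == 0) {
        pert <- clean_q
      } else {
        noise <- matrix(rnorm(length(clean_q)), n) *
          rep(gamma * sigma_q, each = n)
        pert <- clean_q + noise
      }
      ref <- forward_from(net, layer,
                          layer_activation(layer, pert, both[[layer]]$spatial_shape),
                          stop_at = reference_layer)$values
      diffs <- ref - clean_ref
      per_image[, r] <- switch(metric,
        nmae = rowMeans(sweep(abs(diffs[, live, drop = FALSE]), 2,
                              sigma_ref[live], "/")),
        mse = rowMeans(diffs^2),
        cosine = {
          num <- rowSums(ref * clean_ref)
          den <- sqrt(rowSums(ref^2) * rowSums(clean_ref^2))
          1 - ifelse(den > 0, num / den, 1)
        })
      per_repeat[r] <- mean(per_image[, r])
    }
  })
  structure(list(perturbed_layer = layer, reference_layer = reference_layer,
                 gamma = gamma, metric = metric,
                 deviation = mean(per_repeat), per_repeat = per_repeat,
                 per_image = rowMeans(per_image), n_repeats = n_repeats,
                 seed = seed),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("<perturbation_result> %s perturbed (gamma %.2g) -> %s: %s deviation %.4g\n",
              x$perturbed_layer, x$gamma, x$reference_layer, x$metric,
              x$deviation))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.perturbation_result <- function(x, ...) {
  tibble::tibble(perturbed_layer = x$perturbed_layer,
                 reference_layer = x$reference_layer, gamma = x$gamma,
                 metric = x$metric, repeat_id = seq_along(x$per_repeat),
                 deviation = x$per_repeat)
}

#' Perturbation deviation profile across layers
#'
#' Runs [perturb_and_propagate()] for every layer preceding the reference and
#' returns the deviation profile (the error-attenuation analysis).
#'
#' @inheritParams perturb_and_propagate
#' @param layers layers to perturb (default: all conv block outputs preceding
#'   the reference).
#' @return Tibble with one row per (layer, repeat).
#' @export
perturbation_profile <- function(net, images, layers = NULL, gamma = 4.0,
                                 reference_layer = NULL, metric = "nmae",
                                 n_repeats = 8, seed = 1) {
  if (is.null(reference_layer)) {
    convs <- grep("^conv[0-9]+[a-z]?$", layer_names(net), value = TRUE)
    reference_layer <- utils::tail(convs, 1)
  }
  if (is.null(layers)) {
    layers <- grep("^conv[0-9]+[a-z]?$", layer_names(net), value = TRUE)
    layers <- layers[vapply(layers, function(q)
      net$points[[q]] < net$points[[reference_layer]], TRUE)]
  }
  purrr::map_dfr(layers, function(q) {
    r <- perturb_and_propagate(net, images, q, gamma = gamma,
                               reference_layer = reference_layer,
                               metric = metric, n_repeats = n_repeats,
                               seed = seed)
    tidy(r)
  })
}
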