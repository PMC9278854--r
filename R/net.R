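#' Specify a miniature VGG-style convolutional classifier
#'
#' A desk-scale stand-in for a large image classifier: stacked 3x3 convolution
#' blocks (convolution, optional batch normalization, ReLU) each followed by
#' 2x2 max pooling, then fully connected layers with dropout during training,
#' and a softmax output. Every block output is a named, injectable point: its
#' activations can be extracted exactly and the forward pass resumed from
#' externally supplied (e.g. brain-derived) activations at that point.
#'
#' @param input_shape `c(H, W, C)`; H and W must be divisible by
#'   `2^(number of blocks)` so pooling stays exact.
#' @param conv_widths conv block layout: a list of integer vectors, one per
#'   block, giving the channel width of each convolution in the block (the
#'   VGG pattern; pooling follows each block), or a plain integer vector for
#'   one convolution per block. At least 2 blocks so early/late contrasts
#'   exist. Injectable names are `"conv1a"`, `"conv1b"`, ... for multi-conv
#'   blocks and `"conv1"`, `"conv2"`, ... for single-conv blocks.
#' @param kernel odd convolution kernel size.
#' @param use_batch_norm place batch normalization between each convolution
#'   and its ReLU.
#' @param dense_widths integer vector of hidden fully connected widths
#'   (at least one).
#' @param m number of output classes (>= 2).
#' @param dropout dropout probability on hidden dense layers, training only.
#' @param weight_decay l2 penalty coefficient on conv/dense weights.
#' @return A `net_spec` object.
#' @export
net_spec <- function(input_shape = c(32, 32, 3),
                     conv_widths = list(c(16, 16), c(32, 32), c(64, 64)),
                     kernel = 3, use_batch_norm = TRUE, dense_widths = 128,
                     m = 10, dropout = 0.4, weight_decay = 5e-4) {
  if (!is.list(conv_widths)) conv_widths <- as.list(conv_widths)
  assert_that(length(conv_widths) >= 2, "need at least two conv blocks")
  assert_that(all(lengths(conv_widths) >= 1), "every block needs a conv width")
  assert_that(length(dense_widths) >= 1, "need at least one dense layer")
  assert_that(m >= 2, "need at least two output classes")
  assert_that(kernel %% 2 == 1, "kernel must be odd")
  down <- 2^length(conv_widths)
  assert_that(input_shape[1] %% down == 0 && input_shape[2] %% down == 0,
              "input H and W must be divisible by 2^(number of conv blocks)")
  structure(list(input_shape = input_shape, conv_widths = conv_widths,
                 kernel = kernel, use_batch_norm = use_batch_norm,
                 dense_widths = dense_widths, m = m, dropout = dropout,
                 weight_decay = weight_decay),
            class = "net_spec")
}

glorot_normal <- function(nr, nc, fan_in, fan_out) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / (fan_in + fan_out))), nr, nc)
}

# Build the layer sequence with freshly initialized parameters.
# Injectable points (named, post-nonlinearity) follow the design rule:
# "convI" = output of block I (conv -> bn -> ReLU), "poolI" = after its max
# pool, "fcJ" = after a hidden dense ReLU, "logits" = pre-softmax scores.
build_net <- function(spec, seed) {
  with_seed(derive_seed(seed, "net_init"), {
    H <- spec$input_shape[1]; W <- spec$input_shape[2]; C <- spec$input_shape[3]
    k <- spec$kernel
    layers <- list()
    shapes <- list()
    add <- function(ly) layers[[length(layers) + 1]] <<- ly
    blocks <- spec$conv_widths
    for (i in seq_along(blocks)) {
      widths <- blocks[[i]]
      for (j in seq_along(widths)) {
        Cout <- widths[j]
        pname <- if (length(widths) == 1) sprintf("conv%d", i)
                 else sprintf("conv%d%s", i, letters[j])
        idx <- conv_indices(H, W, C, k)
        add(list(type = "conv", name = paste0(pname, "_conv"),
                 W = glorot_normal(idx$K, Cout, k * k * C, k * k * Cout),
                 b = if (spec$use_batch_norm) NULL else rep(0, Cout),
                 Cout = Cout, idx = idx, point = NA_character_))
        if (spec$use_batch_norm) {
          add(list(type = "bn", name = paste0(pname, "_bn"),
                   gamma = rep(1, Cout), beta = rep(0, Cout),
                   running_mean = rep(0, Cout), running_var = rep(1, Cout),
                   eps = 1e-5, momentum = 0.9, C = Cout, HW = H * W,
                   chan = rep(seq_len(Cout), H * W), point = NA_character_))
        }
        add(list(type = "relu", name = pname, point = pname))
        shapes[[pname]] <- c(H, W, Cout)
        C <- Cout
      }
      pidx <- pool_indices(H, W, C)
      H <- H %/% 2L; W <- W %/% 2L
      ppname <- sprintf("pool%d", i)
      add(list(type = "pool", name = ppname, idx = pidx, point = ppname))
      shapes[[ppname]] <- c(H, W, C)
    }
    u <- H * W * C
    for (j in seq_along(spec$dense_widths)) {
      width <- spec$dense_widths[j]
      add(list(type = "dense", name = sprintf("dense%d", j),
               W = glorot_normal(u, width, u, width), b = rep(0, width),
               point = NA_character_))
      pname <- sprintf("fc%d", j)
      add(list(type = "relu", name = pname, point = pname))
      shapes[[pname]] <- width
      add(list(type = "dropout", name = sprintf("dropout%d", j),
               rate = spec$dropout, point = NA_character_))
      u <- width
    }
    add(list(type = "dense", name = "dense_out",
             W = glorot_normal(u, spec$m, u, spec$m), b = rep(0, spec$m),
             point = "logits"))
    shapes[["logits"]] <- spec$m
    add(list(type = "softmax", name = "softmax", point = NA_character_))
    points <- list()
    for (i in seq_along(layers)) {
      p <- layers[[i]]$point
      if (!is.na(p)) points[[p]] <- i
    }
    structure(list(spec = spec, layers = layers, points = points,
                   shapes = shapes, history = NULL, final_val_acc = NA_real_,
                   seed = seed),
              class = "trained_net")
  })
}

#' @export
print.trained_net <- function(x, ...) {
  cat(sprintf("<trained_net> %d classes, layers: %s\n", x$spec$m,
              paste(layer_names(x), collapse = ", ")))
  if (!is.na(x$final_val_acc))
    cat(sprintf("  final validation accuracy: %.3f\n", x$final_val_acc))
  invisible(x)
}

#' Injectable layer names of a network
#'
#' Ordered input-adjacent to output-adjacent. Each name is both an extraction
#' point for [activations_at()] and an injection point for [forward_from()].
#'
#' @param net a `trained_net`.
#' @return Character vector of layer names.
#' @export
layer_names <- function(net) names(net$points)

#' Flat width of an injectable layer
#' @param net a `trained_net`.
#' @param layer layer name.
#' @return Integer number of units (flattened).
#' @export
layer_width <- function(net, layer) {
  check_layer(net, layer)
  prod(net$shapes[[layer]])
}

check_layer <- function(net, layer) {
  if (!layer %in% names(net$points))
    stop(sprintf("unknown layer '%s'; valid layers: %s", layer,
                 paste(names(net$points), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# Core forward engine. start = index of first layer to apply; capture =
# point names whose outputs are recorded; stop_at = point name after which to
# stop (output then equals that point's activations).
nf_forward <- function(net, x, train = FALSE, start = 1L,
                       capture = character(), stop_at = NULL,
                       keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  captured <- list()
  last <- length(net$layers)
  for (i in seq(start, length(net$layers))) {
    ly <- net$layers[[i]]
    r <- switch(ly$type,
      conv    = conv_forward(ly, x, keep_cache),
      bn      = bn_forward(ly, x, train, keep_cache),
      pool    = pool_forward(ly, x, keep_cache),
      dense   = dense_forward(ly, x, keep_cache),
      relu    = relu_forward(x, keep_cache),
      dropout = dropout_forward(ly, x, train, keep_cache),
      softmax = list(out = softmax_rows(x), cache = NULL)
    )
    x <- r$out
    if (keep_cache) caches[[i]] <- r$cache
    if (!is.null(r$batch_mean)) {
      # running-statistics update (training mode only); mutate in place
      net$layers[[i]]$running_mean <-
        ly$momentum * ly$running_mean + (1 - ly$momentum) * r$batch_mean
      net$layers[[i]]$running_var <-
        ly$momentum * ly$running_var + (1 - ly$momentum) * r$batch_var
    }
    if (!is.na(ly$point) && ly$point %in% capture) captured[[ly$point]] <- x
    if (!is.null(stop_at) && !is.na(ly$point) && ly$point == stop_at) {
      last <- i
      break
    }
  }
  list(out = x, captured = captured, caches = caches, last = last, net = net)
}

# Backward pass from dout at layer `from` down to layer `to`; returns
# parameter gradients (named by layer index) and the gradient at the input
# of layer `to`.
nf_backward <- function(net, caches, dout, from, to = 1L) {
  grads <- vector("list", length(net$layers))
  for (j in seq(from, to)) {
    ly <- net$layers[[j]]
    r <- switch(ly$type,
      conv    = conv_backward(ly, caches[[j]], dout),
      bn      = bn_backward(ly, caches[[j]], dout),
      pool    = pool_backward(ly, caches[[j]], dout),
      dense   = dense_backward(ly, caches[[j]], dout),
      relu    = list(dx = dout * caches[[j]]$mask, grads = NULL),
      dropout = if (isTRUE(caches[[j]]$identity)) list(dx = dout, grads = NULL)
                else list(dx = dout * caches[[j]]$keep, grads = NULL),
      softmax = stop("backward through softmax is folded into the loss")
    )
    dout <- r$dx
    if (!is.null(r$grads)) grads[[j]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

images_to_matrix <- function(images) {
  if (inherits(images, "image_set")) flatten_images(images$images)
  else if (length(dim(images)) == 4) flatten_images(images)
  else as.matrix(images)
}

batched <- function(n, batch) split(seq_len(n), ceiling(seq_len(n) / batch))

#' Full forward pass: images to class probabilities
#'
#' Evaluation-mode (deterministic) forward pass of the whole network.
#'
#' @param net a `trained_net`.
#' @param images an [image_set()] or `n x H x W x C` array.
#' @param batch evaluation batch size.
#' @return A `prediction_matrix`: `n x m` matrix of row-stochastic class
#'   probabilities with `class_names` attribute.
#' @export
forward_full <- function(net, images, batch = 128) {
  x <- images_to_matrix(images)
  assert_that(ncol(x) == prod(net$spec$input_shape),
              "image size does not match the network input shape")
  out <- matrix(NA_real_, nrow(x), net$spec$m)
  for (idx in batched(nrow(x), batch)) {
    out[idx, ] <- nf_forward(net, x[idx, , drop = FALSE])$out
  }
  new_prediction_matrix(out, net)
}

new_prediction_matrix <- function(probs, net) {
  if (inherits(net, "trained_net") && !is.null(net$class_names))
    colnames(probs) <- net$class_names
  class(probs) <- c("prediction_matrix", class(probs))
  probs
}

#' Extract exact activations at one or more named layers
#'
#' @param net a `trained_net`.
#' @param images an [image_set()] or image array.
#' @param layers character vector of layer names (see [layer_names()]).
#' @param batch evaluation batch size.
#' @return A `layer_activation` (single layer) or named list of them:
#'   `values` is `n x u` in the row-major (h, w, c) flatten order,
#'   `spatial_shape` the unflattened shape.
#' @export
activations_at <- function(net, images, layers, batch = 128) {
  for (q in layers) check_layer(net, q)
  x <- images_to_matrix(images)
  # stop at the deepest requested point to avoid wasted compute
  ord <- vapply(layers, function(q) net$points[[q]], 1L)
  deepest <- layers[which.max(ord)]
  acc <- lapply(layers, function(q) matrix(NA_real_, nrow(x), layer_width(net, q)))
  names(acc) <- layers
  for (idx in batched(nrow(x), batch)) {
    r <- nf_forward(net, x[idx, , drop = FALSE], capture = layers,
                    stop_at = deepest)
    for (q in layers) acc[[q]][idx, ] <- r$captured[[q]]
  }
  res <- lapply(layers, function(q)
    layer_activation(q, acc[[q]], net$shapes[[q]]))
  names(res) <- layers
  if (length(layers) == 1) res[[1]] else res
}

#' Construct a layer activation container
#' @param layer layer name.
#' @param values `n x u` activation matrix (flattened row-major over (h,w,c)).
#' @param spatial_shape original shape, `c(h, w, c)` or scalar width.
#' @export
layer_activation <- function(layer, values, spatial_shape) {
  values <- as.matrix(values)
  assert_that(ncol(values) == prod(spatial_shape),
              "activation width does not match spatial shape")
  structure(list(layer = layer, values = values,
                 spatial_shape = spatial_shape),
            class = "layer_activation")
}

#' @export
print.layer_activation <- function(x, ...) {
  cat(sprintf("<layer_activation> layer %s: %d x %d (shape %s)\n", x$layer,
              nrow(x$values), ncol(x$values),
              paste(x$spatial_shape, collapse = "x")))
  invisible(x)
}

#' Resume the forward pass from injected activations
#'
#' Replaces the activations at named point `q` with `acts` and computes the
#' remaining layers (strictly after `q`; q's own nonlinearity is not
#' re-applied), yielding class probabilities. This is the substitution step of
#' direct interfacing: `acts` may come from [activations_at()] (in which case
#' the result equals [forward_full()]) or from a translated neural recording.
#'
#' @param net a `trained_net`.
#' @param q layer name to inject at.
#' @param acts a `layer_activation` (its `layer` must equal `q`) or a matrix
#'   of matching width.
#' @param batch evaluation batch size.
#' @param stop_at optional downstream point name: return that layer's
#'   activations instead of output probabilities.
#' @return A `prediction_matrix`, or a `layer_activation` when `stop_at` is
#'   given.
#' @export
forward_from <- function(net, q, acts, batch = 256, stop_at = NULL) {
  check_layer(net, q)
  if (inherits(acts, "layer_activation")) {
    assert_that(acts$layer == q,
                sprintf("activations are tagged for layer '%s', not '%s'",
                        acts$layer, q))
    x <- acts$values
  } else {
    x <- as.matrix(acts)
  }
  assert_that(ncol(x) == layer_width(net, q),
              sprintf("width mismatch: layer '%s' has %d units, got %d",
                      q, layer_width(net, q), ncol(x)))
  if (!is.null(stop_at)) {
    check_layer(net, stop_at)
    assert_that(net$points[[stop_at]] > net$points[[q]],
                "stop_at must lie after the injection layer")
  }
  start <- net$points[[q]] + 1L
  width_out <- if (is.null(stop_at)) net$spec$m else layer_width(net, stop_at)
  out <- matrix(NA_real_, nrow(x), width_out)
  for (idx in batched(nrow(x), batch)) {
    r <- nf_forward(net, x[idx, , drop = FALSE], start = start,
                    stop_at = stop_at)
    out[idx, ] <- r$out
  }
  if (is.null(stop_at)) new_prediction_matrix(out, net)
  else layer_activation(stop_at, out, net$shapes[[stop_at]])
}
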