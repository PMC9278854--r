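# Training loop for the miniature classifier: mini-batch SGD with Nesterov
# momentum, plateau-halving learning-rate schedule, early stopping, and
# togglable flip/translation augmentation.

param_fields <- list(conv = c("W", "b"), bn = c("gamma", "beta"),
                     dense = c("W", "b"))

default_train_hyper <- function() {
  list(batch_size = 64, lr = 0.001, momentum = 0.90561, nesterov = TRUE,
       lr_factor = 0.5, lr_patience = 4, stop_patience = 10, max_epochs = 60,
       val_fraction = 0.1, augment = TRUE, max_shift = 2, verbose = FALSE,
       min_delta = 1e-5)
}

stratified_split <- function(labels, fraction, seed) {
  with_seed(seed, {
    val <- integer(0)
    for (k in unique(labels)) {
      idx <- which(labels == k)
      n_val <- max(1L, round(length(idx) * fraction))
      val <- c(val, sample(idx, n_val))
    }
    sort(val)
  })
}

# flip (mirror width) and integer-shift index maps on the flat layout
flip_cols <- function(H, W, C) {
  h <- rep(seq_len(H), each = W * C)
  w <- rep(rep(seq_len(W), each = C), H)
  c <- rep(seq_len(C), H * W)
  flat_index(h, W + 1L - w, c, W, C)
}

shift_map <- function(H, W, C, dy, dx) {
  h <- rep(seq_len(H), each = W * C)
  w <- rep(rep(seq_len(W), each = C), H)
  c <- rep(seq_len(C), H * W)
  hs <- h - dy; ws <- w - dx
  ok <- hs >= 1 & hs <= H & ws >= 1 & ws <= W
  src <- ifelse(ok, flat_index(pmax(hs, 1L), pmax(ws, 1L), c, W, C), NA_integer_)
  src
}

# all shift index maps for one geometry, computed once per training run
shift_cache <- function(H, W, C, max_shift) {
  maps <- list()
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    maps[[paste(dy, dx)]] <- shift_map(H, W, C, dy, dx)
  }
  maps
}

augment_batch <- function(x, max_shift, fcols, smaps) {
  n <- nrow(x)
  flips <- runif(n) < 0.5
  if (any(flips)) x[flips, ] <- x[flips, fcols, drop = FALSE]
  dy <- sample(seq(-max_shift, max_shift), n, replace = TRUE)
  dx <- sample(seq(-max_shift, max_shift), n, replace = TRUE)
  for (i in seq_len(n)) {
    if (dy[i] == 0 && dx[i] == 0) next
    src <- smaps[[paste(dy[i], dx[i])]]
    row <- x[i, ]
    row2 <- numeric(length(row))
    ok <- !is.na(src)
    row2[ok] <- row[src[ok]]
    x[i, ] <- row2
  }
  x
}

cross_entropy <- function(probs, labels) {
  p <- pmax(probs[cbind(seq_along(labels), labels)], 1e-12)
  -mean(log(p))
}

eval_net <- function(net, x, labels, batch = 256) {
  probs <- matrix(NA_real_, nrow(x), net$spec$m)
  for (idx in batched(nrow(x), batch)) {
    probs[idx, ] <- nf_forward(net, x[idx, , drop = FALSE])$out
  }
  list(loss = cross_entropy(probs, labels),
       acc = mean(max.col(probs, ties.method = "first") == labels))
}

#' Train the miniature convolutional classifier
#'
#' Mini-batch stochastic gradient descent with Nesterov momentum. The learning
#' rate is halved when validation loss has not improved for `lr_patience`
#' epochs and training stops after `stop_patience` epochs without improvement
#' (or at `max_epochs`). An internal stratified validation split is carved out
#' of `images`. Horizontal flips and small translations augment the training
#' stream when `augment = TRUE`. Fully deterministic for a fixed seed
#' (single-threaded evaluation).
#'
#' @param spec a [net_spec()].
#' @param images an [image_set()]; split into train/validation internally.
#' @param hyper named list overriding defaults: `batch_size` (64), `lr`
#'   (0.001), `momentum` (0.90561), `nesterov`, `lr_factor` (0.5),
#'   `lr_patience` (4), `stop_patience` (10), `max_epochs` (60),
#'   `val_fraction` (0.1), `augment`, `max_shift`, `min_delta`, `verbose`.
#' @param seed master seed; fans out to weight initialization, the validation
#'   split, shuffling and augmentation.
#' @return A `trained_net` with a `history` tibble (epoch, train_loss,
#'   val_loss, val_acc, lr) and `final_val_acc`.
#' @export
train_net <- function(spec, images, hyper = list(), seed = 1) {
  hp <- utils::modifyList(default_train_hyper(), hyper)
  stopifnot(inherits(spec, "net_spec"), inherits(images, "image_set"))
  net <- build_net(spec, seed)
  net$class_names <- images$class_names
  x_all <- flatten_images(images$images)
  y_all <- images$labels
  val_idx <- stratified_split(y_all, hp$val_fraction, derive_seed(seed, "val_split"))
  tr_idx <- setdiff(seq_along(y_all), val_idx)
  x_tr <- x_all[tr_idx, , drop = FALSE]; y_tr <- y_all[tr_idx]
  x_va <- x_all[val_idx, , drop = FALSE]; y_va <- y_all[val_idx]
  H <- spec$input_shape[1]; W <- spec$input_shape[2]; C <- spec$input_shape[3]
  fcols <- flip_cols(H, W, C)
  smaps <- if (hp$augment) shift_cache(H, W, C, hp$max_shift) else NULL

  vel <- lapply(net$layers, function(ly) {
    pf <- param_fields[[ly$type]]
    if (is.null(pf)) return(NULL)
    out <- list()
    for (f in pf) if (!is.null(ly[[f]])) out[[f]] <- ly[[f]] * 0
    out
  })

  lr <- hp$lr
  best <- Inf; lr_wait <- 0L; stop_wait <- 0L
  history <- list()
  logits_i <- net$points[["logits"]]

  with_seed(derive_seed(seed, "train_loop"), {
    for (epoch in seq_len(hp$max_epochs)) {
      ord <- sample(length(y_tr))
      ep_loss <- 0; nb <- 0L
      for (bidx in batched(length(ord), hp$batch_size)) {
        rows <- ord[bidx]
        xb <- x_tr[rows, , drop = FALSE]
        if (hp$augment) xb <- augment_batch(xb, hp$max_shift, fcols, smaps)
        yb <- y_tr[rows]
        fwd <- nf_forward(net, xb, train = TRUE, keep_cache = TRUE,
                          stop_at = "logits")
        net <- fwd$net  # running BN statistics updated
        probs <- softmax_rows(fwd$out)
        loss <- cross_entropy(probs, yb)
        if (!is.finite(loss)) {
          stop(sprintf(
            "training diverged (non-finite loss) at epoch %d after %d batches; last lr %.2g",
            epoch, nb, lr), call. = FALSE)
        }
        ep_loss <- ep_loss + loss; nb <- nb + 1L
        dlogits <- probs
        dlogits[cbind(seq_along(yb), yb)] <- dlogits[cbind(seq_along(yb), yb)] - 1
        dlogits <- dlogits / length(yb)
        bwd <- nf_backward(net, fwd$caches, dlogits, from = logits_i, to = 1L)
        for (li in seq_along(net$layers)) {
          g <- bwd$grads[[li]]
          if (is.null(g)) next
          for (f in names(g)) {
            grad <- g[[f]]
            if (is.null(grad)) next
            if (f == "W" && net$layers[[li]]$type %in% c("conv", "dense"))
              grad <- grad + spec$weight_decay * net$layers[[li]][[f]]
            v <- hp$momentum * vel[[li]][[f]] - lr * grad
            vel[[li]][[f]] <- v
            upd <- if (hp$nesterov) hp$momentum * v - lr * grad else v
            net$layers[[li]][[f]] <- net$layers[[li]][[f]] + upd
          }
        }
      }
      ev <- eval_net(net, x_va, y_va)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss / nb, val_loss = ev$loss,
        val_acc = ev$acc, lr = lr)
      if (hp$verbose)
        message(sprintf("epoch %2d loss %.4f val_loss %.4f val_acc %.3f lr %.2g",
                        epoch, ep_loss / nb, ev$loss, ev$acc, lr))
      if (ev$loss < best - hp$min_delta) {
        best <- ev$loss; lr_wait <- 0L; stop_wait <- 0L
      } else {
        lr_wait <- lr_wait + 1L; stop_wait <- stop_wait + 1L
        if (lr_wait >= hp$lr_patience) {
          lr <- lr * hp$lr_factor
          lr_wait <- 0L
        }
        if (stop_wait >= hp$stop_patience) break
      }
    }
  })
  net$history <- dplyr::bind_rows(history)
  net$final_val_acc <- utils::tail(net$history$val_acc, 1)
  net
}
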