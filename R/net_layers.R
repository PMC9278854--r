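# Layer primitives for the miniature convolutional classifier.
#
# All feature maps travel as n x (H*W*C) matrices in the package-wide flatten
# convention: row-major over (h, w, c), channel fastest (see flat_index()).
# Convolutions use im2col gathers so every heavy step is a single BLAS matmul.

# Precompute gather indices for a k x k "same" convolution on an H x W x C map.
conv_indices <- function(H, W, C, k = 3) {
  pad <- (k - 1L) %/% 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  hh <- rep(seq_len(H), each = W * C)
  ww <- rep(rep(seq_len(W), each = C), H)
  cc <- rep(seq_len(C), H * W)
  pad_cols <- ((hh + pad - 1L) * Wp + (ww + pad - 1L)) * C + cc
  HW <- H * W
  pos_h <- rep(seq_len(H), each = W)
  pos_w <- rep(seq_len(W), H)
  K <- k * k * C
  gidx <- integer(HW * K)
  kk <- 0L
  for (dh in 0:(k - 1L)) for (dw in 0:(k - 1L)) for (c in seq_len(C)) {
    kk <- kk + 1L
    src <- ((pos_h + dh - 1L) * Wp + (pos_w + dw - 1L)) * C + c
    gidx[((kk - 1L) * HW + 1L):(kk * HW)] <- src
  }
  list(pad_cols = pad_cols, gidx = gidx, Hp = Hp, Wp = Wp, K = K, HW = HW,
       pad_width = Hp * Wp * C, n_offsets = k * k, Cin = C)
}

conv_forward <- function(ly, x, keep_cache = FALSE) {
  N <- nrow(x)
  idx <- ly$idx
  xp <- matrix(0, N, idx$pad_width)
  xp[, idx$pad_cols] <- x
  cols <- xp[, idx$gidx]
  dim(cols) <- c(N * idx$HW, idx$K)
  out <- cols %*% ly$W
  if (!is.null(ly$b)) out <- out + rep(ly$b, each = nrow(out))
  dim(out) <- c(N, idx$HW, ly$Cout)
  out <- aperm(out, c(1, 3, 2))
  dim(out) <- c(N, ly$Cout * idx$HW)
  cache <- if (keep_cache) list(cols = cols, N = N) else NULL
  list(out = out, cache = cache)
}

conv_backward <- function(ly, cache, dout) {
  idx <- ly$idx
  N <- cache$N
  dim(dout) <- c(N, ly$Cout, idx$HW)
  dout <- aperm(dout, c(1, 3, 2))
  dim(dout) <- c(N * idx$HW, ly$Cout)
  dW <- crossprod(cache$cols, dout)
  g <- list(W = dW)
  if (!is.null(ly$b)) g$b <- colSums(dout)
  dcols <- dout %*% t(ly$W)
  dim(dcols) <- c(N, idx$HW * idx$K)
  dxp <- matrix(0, N, idx$pad_width)
  HW <- idx$HW
  C <- idx$Cin
  # scatter-add per spatial offset: for a fixed (dh, dw) the source columns
  # over all (position, channel) pairs are distinct, so k*k block updates
  # suffice instead of one per kernel entry
  for (o in seq_len(idx$n_offsets)) {
    rng <- ((o - 1L) * HW * C + 1L):(o * HW * C)
    s <- idx$gidx[rng]
    dxp[, s] <- dxp[, s] + dcols[, rng]
  }
  list(dx = dxp[, idx$pad_cols], grads = g)
}

# per-channel sums for the c-fastest flat layout
channel_sum <- function(x, C, HW) {
  s <- colSums(x)
  rowSums(matrix(s, C, HW))
}

bn_forward <- function(ly, x, train, keep_cache = FALSE) {
  N <- nrow(x); C <- ly$C; HW <- ly$HW; chan <- ly$chan
  if (train) {
    Nd <- N * HW
    mu <- channel_sum(x, C, HW) / Nd
    xc <- x - rep(mu[chan], each = N)
    v <- channel_sum(xc * xc, C, HW) / Nd
    inv <- 1 / sqrt(v + ly$eps)
    xhat <- xc * rep(inv[chan], each = N)
    out <- xhat * rep(ly$gamma[chan], each = N) + rep(ly$beta[chan], each = N)
    cache <- if (keep_cache) list(xhat = xhat, inv = inv, N = N, mode = "train") else NULL
    list(out = out, cache = cache, batch_mean = mu, batch_var = v)
  } else {
    inv <- 1 / sqrt(ly$running_var + ly$eps)
    scale <- (ly$gamma * inv)[chan]
    shift <- (ly$beta - ly$gamma * inv * ly$running_mean)[chan]
    out <- x * rep(scale, each = N) + rep(shift, each = N)
    cache <- if (keep_cache) list(scale = scale, N = N, mode = "eval") else NULL
    list(out = out, cache = cache)
  }
}

bn_backward <- function(ly, cache, dout) {
  N <- cache$N; C <- ly$C; HW <- ly$HW; chan <- ly$chan
  if (cache$mode == "eval") {
    return(list(dx = dout * rep(cache$scale, each = N), grads = NULL))
  }
  Nd <- N * HW
  xhat <- cache$xhat
  dgamma <- channel_sum(dout * xhat, C, HW)
  dbeta <- channel_sum(dout, C, HW)
  dxhat <- dout * rep(ly$gamma[chan], each = N)
  s1 <- channel_sum(dxhat, C, HW) / Nd
  s2 <- channel_sum(dxhat * xhat, C, HW) / Nd
  dx <- rep(cache$inv[chan], each = N) *
    (dxhat - rep(s1[chan], each = N) - xhat * rep(s2[chan], each = N))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

pool_indices <- function(H, W, C) {
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  oh <- rep(seq_len(Ho), each = Wo * C)
  ow <- rep(rep(seq_len(Wo), each = C), Ho)
  oc <- rep(seq_len(C), Ho * Wo)
  f <- function(dh, dw) ((2L * oh - 2L + dh) * W + (2L * ow - 2L + dw)) * C + oc
  list(i = list(f(0L, 0L), f(0L, 1L), f(1L, 0L), f(1L, 1L)),
       in_width = H * W * C, out_width = Ho * Wo * C)
}

pool_forward <- function(ly, x, keep_cache = FALSE) {
  idx <- ly$idx
  a <- x[, idx$i[[1]], drop = FALSE]; b <- x[, idx$i[[2]], drop = FALSE]
  cc <- x[, idx$i[[3]], drop = FALSE]; d <- x[, idx$i[[4]], drop = FALSE]
  out <- pmax(a, b, cc, d)
  cache <- NULL
  if (keep_cache) {
    m1 <- a == out
    m2 <- (b == out) & !m1
    m3 <- (cc == out) & !m1 & !m2
    m4 <- !(m1 | m2 | m3)
    cache <- list(masks = list(m1, m2, m3, m4), N = nrow(x))
  }
  list(out = out, cache = cache)
}

pool_backward <- function(ly, cache, dout) {
  idx <- ly$idx
  dx <- matrix(0, cache$N, idx$in_width)
  for (j in 1:4) dx[, idx$i[[j]]] <- dout * cache$masks[[j]]
  list(dx = dx, grads = NULL)
}

dense_forward <- function(ly, x, keep_cache = FALSE) {
  out <- x %*% ly$W + rep(ly$b, each = nrow(x))
  list(out = out, cache = if (keep_cache) list(x = x) else NULL)
}

dense_backward <- function(ly, cache, dout) {
  list(dx = dout %*% t(ly$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

relu_forward <- function(x, keep_cache = FALSE) {
  out <- x * (x > 0)
  list(out = out, cache = if (keep_cache) list(mask = x > 0) else NULL)
}

dropout_forward <- function(ly, x, train, keep_cache = FALSE) {
  if (!train || ly$rate <= 0) return(list(out = x, cache = list(identity = TRUE)))
  keep <- matrix(runif(length(x)) > ly$rate, nrow(x), ncol(x)) / (1 - ly$rate)
  list(out = x * keep, cache = if (keep_cache) list(keep = keep) else NULL)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
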