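#' @importFrom stats rnorm runif sd prcomp pchisq setNames predict cor var
#' @importFrom utils head tail write.csv read.csv
NULL

# Deterministic fan-out of a master seed into named substreams, so that
# re-running one stage never perturbs the RNG stream of another.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(label)) * (seq_along(utf8ToInt(as.character(label))) + 7L))
  as.integer((abs(seed) * 1000003 + h * 2654435) %% .Machine$integer.max)
}

# Run `expr` under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), expr)
}

# Flatten convention for feature maps: row-major over (h, w, c), channel
# fastest. Column index of unit (h, w, c) in an n x (H*W*C) matrix:
#   ((h-1)*W + (w-1)) * C + c
flat_index <- function(h, w, c, W, C) {
  ((h - 1L) * W + (w - 1L)) * C + c
}

# Flatten an n x H x W x C array into the n x (H*W*C) matrix convention above.
flatten_images <- function(images) {
  stopifnot(length(dim(images)) == 4)
  n <- dim(images)[1]; H <- dim(images)[2]; W <- dim(images)[3]; C <- dim(images)[4]
  # array index order is (n, h, w, c); target column order is c fastest,
  # then w, then h -> permute to (n, c, w, h) reversed: want (h, w, c) row-major
  # = h slowest among the three. aperm to (n, c, w, h) then dim gives
  # (c, w, h) with c fastest.
  x <- aperm(images, c(1, 4, 3, 2))
  dim(x) <- c(n, C * W * H)
  x
}

# Inverse of flatten_images.
unflatten_images <- function(x, H, W, C) {
  n <- nrow(x)
  dim(x) <- c(n, C, W, H)
  aperm(x, c(1, 4, 3, 2))
}

clip_probs <- function(p, eps = 1e-9) {
  p <- pmax(p, eps)
  p / rowSums(p)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
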