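# Shared fixtures, built once per test run and memoized. The "tiny" net keeps
# unit tests fast; the "full" net is the desk-scale study configuration used
# by the acceptance checks.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_images <- function() {
  memo("tiny_images", generate_images(4, 60, size = c(16, 16), seed = 42))
}

tiny_net <- function() {
  memo("tiny_net", {
    spec <- net_spec(input_shape = c(16, 16, 3), conv_widths = c(12, 24),
                     dense_widths = 32, m = 4, dropout = 0.2)
    train_net(spec, tiny_images(), hyper = list(max_epochs = 20, lr = 0.01),
              seed = 7)
  })
}

# Desk-scale study conditions: 10 classes x 200 images, 32x32, the default
# three-block VGG-style architecture.
full_images <- function() {
  memo("full_images", generate_images(10, 200, size = c(32, 32), seed = 101))
}

full_net <- function() {
  memo("full_net", train_net(net_spec(), full_images(),
                             hyper = list(max_epochs = 10), seed = 202))
}

# Independent brute-force Hand-Till oracle: enumerates every
# (class pair, instance, instance) triple.
brute_force_multiclass_auc <- function(P, labels) {
  present <- sort(unique(labels))
  pair_vals <- c()
  for (i in seq_along(present)) {
    for (j in seq_along(present)) {
      if (j <= i) next
      a <- present[i]; b <- present[j]
      dir_auc <- function(cls_hi, cls_lo, col) {
        hi <- which(labels == cls_hi); lo <- which(labels == cls_lo)
        s <- 0
        for (x in hi) for (y in lo) {
          s <- s + (if (P[x, col] > P[y, col]) 1
                    else if (P[x, col] == P[y, col]) 0.5 else 0)
        }
        s / (length(hi) * length(lo))
      }
      pair_vals <- c(pair_vals, (dir_auc(a, b, a) + dir_auc(b, a, b)) / 2)
    }
  }
  mean(pair_vals)
}
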