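#' Neural recording set
#'
#' Trials x features recordings (static mode) or trials x time-bins x features
#' (temporal mode), row-aligned with a paired [image_set()].
#'
#' @param data `n x d` matrix (static) or `n x T x d` array (temporal).
#' @param region_name region label, e.g. `"V4"` or `"IT"`.
#' @param bin_width time per bin in ms (temporal mode only, > 0).
#' @param bin_onsets length-T vector of strictly increasing signed bin onset
#'   times in ms relative to stimulus onset (temporal mode only).
#' @param alignment integer row index into the paired image set (defaults to
#'   `1:n`).
#' @return A `recording_set`.
#' @export
recording_set <- function(data, region_name = "region", bin_width = NULL,
                          bin_onsets = NULL, alignment = NULL) {
  nd <- length(dim(data))
  assert_that(nd %in% c(2, 3), "data must be n x d or n x T x d")
  temporal <- nd == 3
  if (temporal) {
    assert_that(!is.null(bin_width) && bin_width > 0,
                "temporal mode requires bin_width > 0")
    assert_that(!is.null(bin_onsets) && length(bin_onsets) == dim(data)[2] &&
                  all(diff(bin_onsets) > 0),
                "bin_onsets must be strictly increasing and match T")
  }
  d <- if (temporal) dim(data)[3] else dim(data)[2]
  assert_that(d >= 1, "need at least one feature")
  structure(list(data = data, region_name = region_name,
                 temporal = temporal, bin_width = bin_width,
                 bin_onsets = bin_onsets,
                 alignment = alignment %||% seq_len(dim(data)[1])),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  if (x$temporal) {
    cat(sprintf("<recording_set> %s: %d trials x %d bins (%g ms) x %d features\n",
                x$region_name, dim(x$data)[1], dim(x$data)[2], x$bin_width,
                dim(x$data)[3]))
  } else {
    cat(sprintf("<recording_set> %s: %d trials x %d features\n",
                x$region_name, nrow(x$data), ncol(x$data)))
  }
  invisible(x)
}

#' @export
dim.recording_set <- function(x) dim(x$data)

#' Extract one time bin of a temporal recording set as a static matrix
#' @param rec temporal `recording_set`.
#' @param bin bin index in `1..T`.
#' @return `n x d` matrix.
#' @export
recording_bin <- function(rec, bin) {
  assert_that(rec$temporal, "recording set is not temporal")
  assert_that(bin >= 1 && bin <= dim(rec$data)[2], "bin out of range")
  rec$data[, bin, , drop = TRUE]
}

#' Simulate a brain region as a noisy linear readout of a network layer
#'
#' Generates recordings with the linear structure the translation model
#' assumes: `data = activations(source_layer) %*% A + noise`, with A a fixed
#' random full-rank map (standard normal entries scaled by 1/sqrt(source
#' width)) or the identity, and noise i.i.d. Gaussian with standard deviation
#' `noise_sd` times each projected feature's signal SD (measurement noise,
#' applied after the projection). Optional `mixing` blends several source
#' layers before projection. Reproducible from the seed.
#'
#' @param net a `trained_net`.
#' @param images paired [image_set()].
#' @param source_layer layer name whose activations drive the region.
#' @param d number of recorded features; must equal the layer width when
#'   `projection = "identity"`.
#' @param noise_sd nonnegative noise scale relative to per-feature signal SD.
#' @param projection `"random"` (default) or `"identity"`.
#' @param mixing optional named numeric vector of per-layer weights; when
#'   given, the weighted, per-layer standardized activations of several layers
#'   are concatenated before projection and `source_layer` is ignored.
#' @param seed seed controlling A and the noise.
#' @param region_name stored region label.
#' @return A static `recording_set` with attribute `"source_layer"`.
#' @export
simulate_region <- function(net, images, source_layer, d, noise_sd = 0,
                            projection = c("random", "identity"),
                            mixing = NULL, seed = 1,
                            region_name = source_layer) {
  projection <- match.arg(projection)
  assert_that(d >= 1, "d must be at least 1")
  if (is.null(mixing)) {
    check_layer(net, source_layer)
    acts <- activations_at(net, images, source_layer)$values
  } else {
    assert_that(!is.null(names(mixing)), "mixing must be a named vector of layer weights")
    parts <- lapply(names(mixing), function(q) {
      a <- activations_at(net, images, q)$values
      s <- apply(a, 2, stats::sd); s[s <= 0] <- 1
      mixing[[q]] * sweep(a, 2, s, "/")
    })
    acts <- do.call(cbind, parts)
    source_layer <- paste(names(mixing), collapse = "+")
  }
  u <- ncol(acts)
  with_seed(derive_seed(seed, "simulate_region"), {
    if (projection == "identity") {
      assert_that(d == u, "identity projection requires d equal to the layer width")
      signal <- acts
    } else {
      A <- matrix(rnorm(u * d), u, d) / sqrt(u)
      signal <- acts %*% A
    }
    if (noise_sd > 0) {
      sds <- apply(signal, 2, stats::sd)
      sds[sds <= 0] <- mean(sds[sds > 0]) %||% 1
      noise <- matrix(rnorm(length(signal)), nrow(signal)) *
        rep(noise_sd * sds, each = nrow(signal))
      signal <- signal + noise
    }
    out <- recording_set(signal, region_name = region_name)
    attr(out, "source_layer") <- source_layer
    out
  })
}

#' Specify two-region temporal dynamics
#'
#' Parameters of the simulated feedforward/feedback interaction between an
#' early ("V4-like") and a late ("IT-like") region: the stimulus response
#' reaches V4 first and IT `feedforward_lag` bins later, while a
#' class-informative component (a late-layer code of the presented image)
#' enters IT first and is fed back into V4 `feedback_lag` bins later.
#'
#' @param t_bins number of time bins.
#' @param stimulus_on,stimulus_off bin indices (on < off <= t_bins).
#' @param feedforward_lag bins by which the V4 stimulus response leads IT
#'   (>= 1).
#' @param feedback_lag bins by which the IT class signal leads its V4 copy
#'   (>= 1).
#' @param class_gain_it gain of the class code in IT.
#' @param class_gain_feedback gain of the fed-back class code in V4 (0
#'   removes all class information from V4).
#' @param stimulus_gain gain of the stimulus-driven rate response.
#' @param noise_sd SD of the additive Gaussian noise (latent and measurement).
#' @param bin_width_ms bin width in ms.
#' @param first_onset_ms onset time of bin 1 in ms relative to stimulus onset.
#' @return A `dynamics_spec`.
#' @export
dynamics_spec <- function(t_bins = 30, stimulus_on = 6, stimulus_off = 16,
                          feedforward_lag = 2, feedback_lag = 3,
                          class_gain_it = 1.0, class_gain_feedback = 0.8,
                          stimulus_gain = 1.0, noise_sd = 0.3,
                          bin_width_ms = 10, first_onset_ms = -50) {
  assert_that(feedforward_lag >= 1 && feedback_lag >= 1, "lags must be >= 1")
  assert_that(stimulus_on < stimulus_off && stimulus_off <= t_bins,
              "need stimulus_on < stimulus_off <= t_bins")
  assert_that(feedforward_lag + feedback_lag < t_bins - stimulus_on,
              "lags exceed the post-onset window")
  assert_that(noise_sd >= 0 && class_gain_it >= 0 && class_gain_feedback >= 0 &&
                stimulus_gain >= 0, "gains and noise_sd must be nonnegative")
  structure(list(t_bins = t_bins, stimulus_on = stimulus_on,
                 stimulus_off = stimulus_off,
                 feedforward_lag = feedforward_lag,
                 feedback_lag = feedback_lag, class_gain_it = class_gain_it,
                 class_gain_feedback = class_gain_feedback,
                 stimulus_gain = stimulus_gain, noise_sd = noise_sd,
                 bin_width_ms = bin_width_ms, first_onset_ms = first_onset_ms),
            class = "dynamics_spec")
}

# Rate-like response kernel: 0 before onset, single peak two bins after.
response_kernel <- function(t_bins, onset, off) {
  tau <- seq_len(t_bins) - onset
  k <- ifelse(tau >= 0, (tau + 1) * exp(-(tau + 1) / 3), 0)
  k <- k / max(k)
  # decay after stimulus offset
  post <- seq_len(t_bins) > off
  k[post] <- k[post] * exp(-(seq_len(t_bins)[post] - off) / 3)
  k
}

#' Simulate two-region temporal recordings with feedforward and feedback lags
#'
#' Generates trial-level, time-binned recordings for a "V4-like" and an
#' "IT-like" region embodying the hypothesized long-range recurrence: (i) the
#' stimulus-driven rate rises in V4 `feedforward_lag` bins before IT, with the
#' V4 rate fluctuations themselves transmitted forward (so rate causality runs
#' V4 to IT); (ii) a class-informative component -- the presented image's
#' late-layer code, with trial-specific gain fluctuations -- enters IT first
#' and enters V4 `feedback_lag` bins later as a scaled copy (so task-relevant
#' causality runs IT to V4). Gaussian noise is added throughout and signals
#' are rectified to nonnegative rates after noise addition. Deterministic per
#' seed.
#'
#' @param net a `trained_net` providing the class code (late-layer
#'   activations).
#' @param images paired [image_set()]; one trial per row.
#' @param spec a [dynamics_spec()].
#' @param d_v4,d_it feature counts of the two regions.
#' @param code_layer late layer whose activations define the class code.
#' @param seed seed.
#' @return Named list of two temporal `recording_set`s, `v4` and `it`.
#' @export
simulate_two_region_dynamics <- function(net, images, spec, d_v4 = 24,
                                         d_it = 24, code_layer = "fc1",
                                         seed = 1) {
  stopifnot(inherits(spec, "dynamics_spec"))
  check_layer(net, code_layer)
  n <- n_images(images)
  Tt <- spec$t_bins
  code <- activations_at(net, images, code_layer)$values
  cs <- apply(code, 2, stats::sd); cs[cs <= 0] <- 1
  code <- sweep(sweep(code, 2, colMeans(code)), 2, cs, "/")
  u <- ncol(code)
  with_seed(derive_seed(seed, "two_region"), {
    k_stim <- response_kernel(Tt, spec$stimulus_on, spec$stimulus_off)
    class_onset <- spec$stimulus_on + spec$feedforward_lag
    k_class <- response_kernel(Tt, class_onset, spec$stimulus_off + spec$feedforward_lag)
    lag <- function(m, l) {
      out <- matrix(0, nrow(m), ncol(m))
      if (l < ncol(m)) out[, (l + 1):ncol(m)] <- m[, 1:(ncol(m) - l)]
      out
    }
    # latent V4 stimulus rate (trials x T), noisy around the kernel
    a <- spec$stimulus_gain *
      (rep(1, n) %o% k_stim) * (1 + 0.2 * rnorm(n)) +
      matrix(rnorm(n * Tt, sd = spec$noise_sd), n, Tt)
    # feedforward transfer: IT rate copies V4's actual activity, gated to the
    # stimulus-driven period, plus its own noise
    gate <- as.numeric(k_stim > 0.05)
    b <- lag(a * (rep(1, n) %o% gate), spec$feedforward_lag) +
      matrix(rnorm(n * Tt, sd = spec$noise_sd), n, Tt)
    # class-signal gain in IT: kernel-shaped with bin-specific (temporally
    # white) fluctuations -- these fluctuations are what feeds back measurably;
    # a trial-constant gain would act as a shared random effect across regions
    # and blur the directionality of the transfer
    g_it <- spec$class_gain_it * (rep(1, n) %o% k_class) +
      matrix(rnorm(n * Tt, sd = spec$noise_sd * spec$class_gain_it), n, Tt) *
      (rep(1, n) %o% as.numeric(k_class > 0.05))
    g_v4 <- spec$class_gain_feedback * lag(g_it, spec$feedback_lag)
    # random feature loadings
    w_v4 <- abs(rnorm(d_v4, 1, 0.3))
    w_it <- abs(rnorm(d_it, 1, 0.3))
    P_v4 <- matrix(rnorm(u * d_v4), u, d_v4) / sqrt(u)
    P_it <- matrix(rnorm(u * d_it), u, d_it) / sqrt(u)
    proj_v4 <- code %*% P_v4   # n x d_v4 class pattern
    proj_it <- code %*% P_it
    make_region <- function(rate, g, proj, w, d, name) {
      dat <- array(0, c(n, Tt, d))
      for (t in seq_len(Tt)) {
        dat[, t, ] <- 0.5 + rate[, t] %o% w +
          0.15 * g[, t] %o% w +           # class signal mildly raises rate,
          g[, t] * proj +                  # without displacing the stimulus-
          matrix(rnorm(n * d, sd = spec$noise_sd), n, d)  # driven rate peak
      }
      dat <- pmax(dat, 0)  # rectified, rate-like
      recording_set(dat, region_name = name, bin_width = spec$bin_width_ms,
                    bin_onsets = spec$first_onset_ms +
                      spec$bin_width_ms * (seq_len(Tt) - 1))
    }
    list(v4 = make_region(a, g_v4, proj_v4, w_v4, d_v4, "V4"),
         it = make_region(b, g_it, proj_it, w_it, d_it, "IT"))
  })
}
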