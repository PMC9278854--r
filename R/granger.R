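#' Bin-wise interfacing of temporal recordings into a KL time series
#'
#' For each time bin independently, a translation is fitted on the training
#' trials' features at that bin (cross-validated), applied to held-out trials,
#' and the per-trial KL divergence of the interfaced predictions from the
#' image-driven predictions is computed. The result is a trials x T matrix of
#' task-relevant correspondence over time: low KL at a bin means that bin's
#' recording can drive the network to the image-appropriate output.
#'
#' @param net a `trained_net`.
#' @param layer target layer for the translation (a late layer, typically).
#' @param recordings a temporal `recording_set` (trials x T x d).
#' @param images paired [image_set()], one row per trial.
#' @param fold_plan a [make_fold_plan()]; defaults to stratified 4-fold.
#' @param translation hyperparameter overrides; default optimizer is the
#'   ridge fast path (the trial-level SGD variant uses
#'   `list(optimizer = "adadelta")`).
#' @param shuffle_labels if TRUE, recordings rows are permuted relative to the
#'   images before fitting (control analysis destroying stimulus information).
#' @param seed master seed.
#' @return A `kl_series`: `values` (trials x T, nats), `bin_onsets`, `region`,
#'   `layer`, `stationarized` flag.
#' @export
binwise_interface_kl <- function(net, layer, recordings, images,
                                 fold_plan = NULL, translation = list(),
                                 shuffle_labels = FALSE, seed = 1) {
  assert_that(inherits(recordings, "recording_set") && recordings$temporal,
              "binwise_interface_kl needs a temporal recording_set")
  check_layer(net, layer)
  n <- dim(recordings$data)[1]
  Tt <- dim(recordings$data)[2]
  assert_that(n == n_images(images), "trials are not row-aligned with images")
  if (is.null(fold_plan)) fold_plan <- make_fold_plan(images$labels, k = 4, seed = seed)
  perm <- seq_len(n)
  if (shuffle_labels) {
    perm <- with_seed(derive_seed(seed, "kl_shuffle"), sample(n))
  }
  acts <- activations_at(net, images, layer)
  P_i <- unclass(forward_full(net, images))
  trans_hyper <- utils::modifyList(list(optimizer = "ridge"), translation)
  kl <- matrix(NA_real_, n, Tt)
  for (t in seq_len(Tt)) {
    xt <- recordings$data[perm, t, , drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, ncol = 1)
    for (f in seq_along(fold_plan$folds)) {
      hold <- fold_plan$folds[[f]]
      train <- setdiff(seq_len(n), hold)
      map <- fit_translation_mse(
        xt[train, , drop = FALSE],
        layer_activation(layer, acts$values[train, , drop = FALSE],
                         acts$spatial_shape),
        hyper = trans_hyper,
        seed = derive_seed(seed, paste("bin", t, f)))
      P_r <- forward_from(net, layer, apply_translation(map, xt[hold, , drop = FALSE]))
      kl[hold, t] <- kl_rows(unclass(P_r), P_i[hold, , drop = FALSE])
    }
  }
  new_kl_series(kl, recordings$bin_onsets, recordings$region_name, layer)
}

new_kl_series <- function(values, bin_onsets, region, layer,
                          stationarized = FALSE) {
  structure(list(values = values, bin_onsets = bin_onsets, region = region,
                 layer = layer, stationarized = stationarized),
            class = "kl_series")
}

#' @export
print.kl_series <- function(x, ...) {
  cat(sprintf("<kl_series> %s -> %s: %d trials x %d bins%s\n", x$region,
              x$layer, nrow(x$values), ncol(x$values),
              if (x$stationarized) " (stationarized)" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kl_series <- function(x, ...) {
  tibble::tibble(
    trial = rep(seq_len(nrow(x$values)), ncol(x$values)),
    bin = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    onset_ms = rep(x$bin_onsets, each = nrow(x$values)),
    region = x$region,
    value = as.numeric(x$values))
}

#' Stationarize a trial x time series for Granger modeling
#'
#' Two-step preprocessing: (1) each trial's series is standardized over time
#' (subtract the trial's temporal mean, divide by its temporal SD); (2) each
#' bin is standardized across trials (subtract the bin mean, divide by the bin
#' SD), so every time step ends with zero mean and unit variance across
#' trials. Step 2 also removes the trial-averaged (deterministic,
#' stimulus-locked) waveform, leaving trial-specific fluctuations -- exactly
#' what directional temporal prediction should operate on. Because the two
#' standardizations do not commute, the pair is iterated to its mutual fixed
#' point (the first iteration is exactly the two steps above; convergence is
#' fast), which makes the operation idempotent and leaves every trial and
#' every bin simultaneously standardized. Zero-SD trials or bins fall back to
#' scale 1 rather than erroring.
#'
#' @param series a `kl_series`, or a plain trials x T matrix.
#' @param tol fixed-point tolerance.
#' @param max_iter iteration cap.
#' @return Same type, stationarized (flagged).
#' @export
stationarize <- function(series, tol = 1e-10, max_iter = 100) {
  m <- if (inherits(series, "kl_series")) series$values else as.matrix(series)
  assert_that(ncol(m) >= 2, "need at least two time bins")
  for (it in seq_len(max_iter)) {
    prev <- m
    mu_t <- rowMeans(m)
    sd_t <- apply(m, 1, stats::sd)
    sd_t[!is.finite(sd_t) | sd_t <= 0] <- 1
    m <- (m - mu_t) / sd_t
    mu_b <- colMeans(m)
    sd_b <- apply(m, 2, stats::sd)
    sd_b[!is.finite(sd_b) | sd_b <= 0] <- 1
    m <- sweep(sweep(m, 2, mu_b), 2, sd_b, "/")
    if (max(abs(m - prev)) < tol) break
  }
  if (inherits(series, "kl_series")) {
    new_kl_series(m, series$bin_onsets, series$region, series$layer,
                  stationarized = TRUE)
  } else {
    m
  }
}

series_matrix <- function(s) {
  if (inherits(s, "kl_series")) s$values else as.matrix(s)
}

# Pooled lagged design over trials, never letting a lag cross a trial
# boundary: rows are (trial, t) for t in (p_skip+1):T.
lagged_design <- function(m, p, p_skip = p) {
  Tt <- ncol(m); n <- nrow(m)
  ts <- (p_skip + 1):Tt
  y <- as.numeric(m[, ts])
  X <- matrix(NA_real_, n * length(ts), p)
  for (l in seq_len(p)) X[, l] <- as.numeric(m[, ts - l])
  list(y = y, X = X)
}

gaussian_loglik <- function(rss, n) {
  s2 <- rss / n
  -n / 2 * (log(2 * pi * s2) + 1)
}

ols_rss <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  sum(fit$residuals^2)
}

# Common lag order for the pair, selected on the bivariate VAR over a common
# estimation sample. Selecting per-direction on the target's own lags alone is
# blind to pure cross-lag structure (and would miss exactly the couplings of
# interest); selecting per-direction on each causal model adapts the order to
# the direction under test and inflates its type-I error. The VAR criterion is
# the symmetric middle ground.
select_lag_order <- function(mx, my, p_max, criterion) {
  Tt <- ncol(my)
  assert_that(Tt > p_max + 1, "series too short for the requested maximum lag")
  n_rows <- nrow(my) * (Tt - p_max)
  crit_val <- function(p) {
    dyn <- lagged_design(my, p, p_skip = p_max)
    dxn <- lagged_design(mx, p, p_skip = p_max)
    Xfull <- cbind(dyn$X, dxn$X)
    ll <- gaussian_loglik(ols_rss(dyn$y, Xfull), n_rows) +
      gaussian_loglik(ols_rss(dxn$y, Xfull), n_rows)
    k <- 2 * (2 * p + 2)
    if (criterion == "bic") -2 * ll + k * log(n_rows) else -2 * ll + 2 * k
  }
  which.min(vapply(seq_len(p_max), crit_val, 1))
}

granger_one_direction <- function(mx, my, p_max, criterion, alpha, p) {
  Tt <- ncol(my)
  n_rows <- nrow(my) * (Tt - p_max)
  dn <- lagged_design(my, p, p_skip = p_max)
  dx <- lagged_design(mx, p, p_skip = p_max)
  rss_null <- ols_rss(dn$y, dn$X)
  rss_causal <- ols_rss(dn$y, cbind(dn$X, dx$X))
  ll_null <- gaussian_loglik(rss_null, n_rows)
  ll_causal <- gaussian_loglik(rss_causal, n_rows)
  lr <- 2 * (ll_causal - ll_null)
  pval <- stats::pchisq(lr, df = p, lower.tail = FALSE)
  structure(list(direction = c(source = "x", target = "y"), p = p,
                 loglik_null = ll_null, loglik_causal = ll_causal,
                 lr_statistic = lr, p_value = pval, criterion = criterion,
                 alpha = alpha, significant = pval < alpha,
                 n_obs = n_rows),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("<granger_result> %s -> %s: p = %d, LR = %.3f, p-value = %.4g%s\n",
              x$direction[["source"]], x$direction[["target"]], x$p,
              x$lr_statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Directional Granger-causal comparison of two trial x time series
#'
#' For each direction, ordinary least squares fits of the null model (the
#' target's own lags 1..p) and the causal model (own plus the source's lags),
#' pooled across trials without letting lags cross trial boundaries. A common
#' lag order p is chosen for the pair by BIC (or AIC) on the bivariate VAR
#' over `1..p_max` on a common estimation sample, and each direction's
#' decision is a likelihood-ratio test,
#' chi-squared with p degrees of freedom at level `alpha`. Both series should
#' be stationarized first (see [stationarize()]).
#'
#' @param series_x,series_y `kl_series` or trials x T matrices with identical
#'   shape.
#' @param p_max maximum lag order considered.
#' @param criterion `"bic"` or `"aic"`.
#' @param alpha significance level of the LR test.
#' @return List with `x_to_y` and `y_to_x`, each a `granger_result` (`p`,
#'   log-likelihoods, `lr_statistic`, `p_value`, `significant`).
#' @export
fit_granger_pair <- function(series_x, series_y, p_max = 5,
                             criterion = c("bic", "aic"), alpha = 0.05) {
  criterion <- match.arg(criterion)
  mx <- series_matrix(series_x); my <- series_matrix(series_y)
  assert_that(all(dim(mx) == dim(my)), "series shapes differ")
  p <- select_lag_order(mx, my, p_max, criterion)
  xy <- granger_one_direction(mx, my, p_max, criterion, alpha, p)
  yx <- granger_one_direction(my, mx, p_max, criterion, alpha, p)
  xy$direction <- c(source = name_of(series_x, "x"), target = name_of(series_y, "y"))
  yx$direction <- c(source = name_of(series_y, "y"), target = name_of(series_x, "x"))
  list(x_to_y = xy, y_to_x = yx)
}

name_of <- function(s, default) {
  if (inherits(s, "kl_series") && !is.null(s$region)) s$region else default
}

#' Time-resolved directional Granger decisions over expanding windows
#'
#' Applies [fit_granger_pair()] on expanding windows of the two series
#' (starting at `start_bin`, growing one bin at a time) and reports, per
#' window, the directional decision (`none`, `x->y`, `y->x`, `x<->y`) and the
#' first window end at which each direction becomes significant (its onset).
#'
#' @param series_x,series_y stationarized series (`kl_series` or matrices).
#' @param start_bin first bin of every window (e.g. just before stimulus
#'   onset).
#' @param min_len minimum window length in bins (at least `p_max + 2`).
#' @param p_max,criterion,alpha as in [fit_granger_pair()].
#' @param adjust `"bonferroni"` (default) divides the per-window alpha by the
#'   number of windows scanned, so that "first onset" detection controls the
#'   family-wise error of the scan; `"none"` uses `alpha` per window.
#' @return A `granger_timeline`: tibble `timeline` (window_end, p_xy, p_yx,
#'   decision) plus `onset_x_to_y` / `onset_y_to_x` (window end bin index, NA
#'   if never significant).
#' @export
run_granger_timeline <- function(series_x, series_y, start_bin = 1,
                                 min_len = NULL, p_max = 5,
                                 criterion = "bic", alpha = 0.05,
                                 adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  mx <- series_matrix(series_x); my <- series_matrix(series_y)
  assert_that(all(dim(mx) == dim(my)), "series shapes differ")
  Tt <- ncol(mx)
  min_len <- min_len %||% (p_max + 3L)
  assert_that(min_len >= p_max + 2, "windows must be at least p_max + 2 bins")
  ends <- seq(start_bin + min_len - 1L, Tt)
  assert_that(length(ends) >= 1, "no window fits within the series")
  alpha_w <- if (adjust == "bonferroni") alpha / length(ends) else alpha
  rows <- lapply(ends, function(e) {
    w <- start_bin:e
    g <- fit_granger_pair(mx[, w, drop = FALSE], my[, w, drop = FALSE],
                          p_max = p_max, criterion = criterion, alpha = alpha_w)
    dec <- if (g$x_to_y$significant && g$y_to_x$significant) "x<->y"
           else if (g$x_to_y$significant) "x->y"
           else if (g$y_to_x$significant) "y->x"
           else "none"
    tibble::tibble(window_end = e, p_xy = g$x_to_y$p_value,
                   p_yx = g$y_to_x$p_value, lag_xy = g$x_to_y$p,
                   lag_yx = g$y_to_x$p, decision = dec)
  })
  tl <- dplyr::bind_rows(rows)
  onset_xy <- tl$window_end[tl$p_xy < alpha_w][1]
  onset_yx <- tl$window_end[tl$p_yx < alpha_w][1]
  structure(list(timeline = tl,
                 onset_x_to_y = if (is.na(onset_xy)) NA_integer_ else onset_xy,
                 onset_y_to_x = if (is.na(onset_yx)) NA_integer_ else onset_yx,
                 x_name = name_of(series_x, "x"), y_name = name_of(series_y, "y"),
                 alpha = alpha, p_max = p_max, start_bin = start_bin),
            class = "granger_timeline")
}

#' @export
print.granger_timeline <- function(x, ...) {
  cat(sprintf("<granger_timeline> %s vs %s: onset %s->%s at bin %s; %s->%s at bin %s\n",
              x$x_name, x$y_name, x$x_name, x$y_name,
              ifelse(is.na(x$onset_x_to_y), "never", x$onset_x_to_y),
              x$y_name, x$x_name,
              ifelse(is.na(x$onset_y_to_x), "never", x$onset_y_to_x)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.granger_timeline <- function(x, ...) x$timeline

#' Plot a Granger decision timeline
#' @param object a `granger_timeline`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.granger_timeline <- function(object, ...) {
  df <- object$timeline |>
    tidyr::pivot_longer(c("p_xy", "p_yx"), names_to = "direction",
                        values_to = "p_value") |>
    dplyr::mutate(direction = dplyr::recode(.data$direction,
      p_xy = paste(object$x_name, "→", object$y_name),
      p_yx = paste(object$y_name, "→", object$x_name)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_end,
                                   y = -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    ggplot2::labs(x = "window end (bin)", y = "-log10 p (LR test)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
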