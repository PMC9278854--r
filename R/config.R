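#' Default experiment configuration
#'
#' Nested defaults for every pipeline stage. [load_config()] fills these in
#' and rejects keys that do not appear here.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "neuriface_out",
    data = list(m = 10, n_per_class = 200, image_size = c(32, 32),
                channels = 3,
                region = list(source_layer = "fc1", d = 128, noise_sd = 0,
                              projection = "random"),
                dynamics = list(t_bins = 30, stimulus_on = 6, stimulus_off = 16,
                                feedforward_lag = 2, feedback_lag = 3,
                                class_gain_it = 1.0, class_gain_feedback = 0.8,
                                stimulus_gain = 1.0, noise_sd = 0.3,
                                d_v4 = 24, d_it = 24, n_trials = 200)),
    network = list(conv_widths = list(c(16, 16), c(32, 32), c(64, 64)),
                   dense_widths = 128,
                   use_batch_norm = TRUE, dropout = 0.4, weight_decay = 5e-4,
                   kernel = 3,
                   hyper = list(max_epochs = 12, lr = 0.001,
                                momentum = 0.90561, batch_size = 64,
                                augment = TRUE)),
    translation = list(mode = "mse", optimizer = "ridge", l2 = 3e-4,
                       pca_rank = 64),
    evaluation = list(k = 8, scheme = "stratified_kfold", layers = NULL),
    granger = list(p_max = 5, criterion = "bic", alpha = 0.05,
                   code_layer = "fc1"),
    perturbation = list(gamma = 4.0, n_repeats = 8, metric = "nmae"),
    baselines = list(n_pcs = 40, n_pls = 10, pixel_components = 192)
  )
}

check_unknown_keys <- function(cfg, defaults, path = "") {
  for (key in names(cfg)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown configuration key: '%s'", here), call. = FALSE)
    }
    if (is.list(cfg[[key]]) && is.list(defaults[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      check_unknown_keys(cfg[[key]], defaults[[key]], here)
    }
  }
  invisible(TRUE)
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML file, rejects unknown keys (naming the offending key and its
#' location), fills in all defaults from [default_config()], and attaches a
#' content hash sufficient to recognize bit-comparable re-runs.
#'
#' @param path YAML file path.
#' @return An `experiment_config` (nested list with attribute `"hash"`).
#' @export
load_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- default_config()
  check_unknown_keys(raw, defaults)
  cfg <- utils::modifyList(defaults, raw)
  attr(cfg, "hash") <- rlang::hash(cfg)
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> seed %s, hash %s\n", x$seed,
              substr(attr(x, "hash"), 1, 12)))
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

scenario_names <- c("substitution-identity", "layer-recovery", "zero-shot",
                    "granger-dissociation", "perturbation",
                    "baselines-comparison")

#' Run a named end-to-end scenario
#'
#' Each scenario generates its inputs from the configuration's synthesis
#' specs, executes the corresponding pipeline, and writes results, a config
#' echo, and a machine-readable pass/fail report (`report.json`) against the
#' scenario's property thresholds into the artifact directory. Re-running with
#' the same configuration reproduces the report.
#'
#' @param name one of `"substitution-identity"`, `"layer-recovery"`,
#'   `"zero-shot"`, `"granger-dissociation"`, `"perturbation"`,
#'   `"baselines-comparison"`.
#' @param config an `experiment_config` (or the result of [default_config()]).
#' @param net optionally, a pre-trained `trained_net` to reuse across
#'   scenarios (trained from the config otherwise).
#' @param images optionally, the [image_set()] the net was trained on.
#' @return The report list, invisibly; artifacts under
#'   `file.path(config$out_dir, name)`.
#' @export
run_scenario <- function(name, config, net = NULL, images = NULL) {
  assert_that(name %in% scenario_names,
              sprintf("unknown scenario '%s'; available: %s", name,
                      paste(scenario_names, collapse = ", ")))
  cfg <- config
  out <- file.path(cfg$out_dir, name)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  if (is.null(images)) {
    images <- generate_images(cfg$data$m, cfg$data$n_per_class,
                              size = cfg$data$image_size,
                              channels = cfg$data$channels,
                              seed = derive_seed(seed, "images"))
  }
  if (is.null(net)) {
    spec <- net_spec(input_shape = c(cfg$data$image_size, cfg$data$channels),
                     conv_widths = cfg$network$conv_widths,
                     dense_widths = cfg$network$dense_widths,
                     use_batch_norm = cfg$network$use_batch_norm,
                     dropout = cfg$network$dropout,
                     weight_decay = cfg$network$weight_decay,
                     kernel = cfg$network$kernel, m = cfg$data$m)
    net <- train_net(spec, images, hyper = cfg$network$hyper,
                     seed = derive_seed(seed, "net"))
  }
  report <- switch(name,
    "substitution-identity" = scenario_substitution(net, images),
    "layer-recovery" = scenario_layer_recovery(net, images, cfg),
    "zero-shot" = scenario_zero_shot(net, images, cfg),
    "granger-dissociation" = scenario_granger(net, images, cfg),
    "perturbation" = scenario_perturbation(net, images, cfg),
    "baselines-comparison" = scenario_baselines(net, images, cfg)
  )
  report$scenario <- name
  report$seed <- seed
  report$config_hash <- attr(cfg, "hash") %||% rlang::hash(unclass(cfg))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(cfg), file.path(out, "config_echo.yaml"))
  invisible(report)
}

scenario_substitution <- function(net, images) {
  errs <- vapply(setdiff(layer_names(net), "logits"), function(q) {
    P <- forward_from(net, q, activations_at(net, images, q))
    max(abs(unclass(P) - unclass(forward_full(net, images))))
  }, 1)
  list(max_error = max(errs), per_layer = as.list(errs),
       pass = max(errs) <= 1e-5)
}

scenario_layer_recovery <- function(net, images, cfg) {
  rg <- cfg$data$region
  d <- min(rg$d, layer_width(net, rg$source_layer))
  rec <- simulate_region(net, images, rg$source_layer, d = d,
                         noise_sd = rg$noise_sd, projection = rg$projection,
                         seed = derive_seed(cfg$seed, "region"))
  res <- run_interface_grid(net, images, rec, layers = cfg$evaluation$layers,
                            translation = cfg$translation[
                              intersect(names(cfg$translation), c("optimizer", "l2"))],
                            fold_plan = make_fold_plan(images$labels,
                                                       k = cfg$evaluation$k,
                                                       seed = cfg$seed),
                            seed = derive_seed(cfg$seed, "grid"))
  write_correspondence(res, file.path(cfg$out_dir, "layer-recovery"))
  b <- best_layer(res)
  list(best_layer = b$layer[1], best_auc = b$auc[1],
       best_mean_kl = res$grid$mean_kl[res$grid$layer == b$layer[1]],
       auc_image = res$auc_image,
       pass = (res$auc_image - b$auc[1]) <= 0.02)
}

scenario_zero_shot <- function(net, images, cfg) {
  rg <- cfg$data$region
  d <- min(rg$d, layer_width(net, rg$source_layer))
  rec <- simulate_region(net, images, rg$source_layer, d = d,
                         noise_sd = rg$noise_sd, projection = rg$projection,
                         seed = derive_seed(cfg$seed, "region"))
  fp <- make_fold_plan(images$labels, scheme = "leave_one_class_out")
  res <- run_interface_grid(net, images, rec, layers = rg$source_layer,
                            fold_plan = fp,
                            seed = derive_seed(cfg$seed, "zeroshot"))
  list(zero_shot_auc = res$grid$auc[1], auc_image = res$auc_image,
       pass = res$grid$auc[1] >= 0.7)
}

scenario_granger <- function(net, images, cfg) {
  dn <- cfg$data$dynamics
  trials <- with_seed(derive_seed(cfg$seed, "trials"),
                      images[sample(n_images(images),
                                    min(dn$n_trials, n_images(images)))])
  spec <- dynamics_spec(t_bins = dn$t_bins, stimulus_on = dn$stimulus_on,
                        stimulus_off = dn$stimulus_off,
                        feedforward_lag = dn$feedforward_lag,
                        feedback_lag = dn$feedback_lag,
                        class_gain_it = dn$class_gain_it,
                        class_gain_feedback = dn$class_gain_feedback,
                        stimulus_gain = dn$stimulus_gain,
                        noise_sd = dn$noise_sd)
  two <- simulate_two_region_dynamics(net, trials, spec, d_v4 = dn$d_v4,
                                      d_it = dn$d_it,
                                      code_layer = cfg$granger$code_layer,
                                      seed = derive_seed(cfg$seed, "dyn"))
  res <- granger_dissociation(net, trials, two, spec,
                              layer = cfg$granger$code_layer,
                              p_max = cfg$granger$p_max,
                              alpha = cfg$granger$alpha,
                              criterion = cfg$granger$criterion,
                              seed = derive_seed(cfg$seed, "granger"))
  list(rate_onset_v4_to_it = res$rate$onset_x_to_y,
       rate_onset_it_to_v4 = res$rate$onset_y_to_x,
       kl_onset_it_to_v4 = res$kl$onset_y_to_x,
       kl_onset_v4_to_it = res$kl$onset_x_to_y,
       pass = isTRUE(res$rate_ff_first) && isTRUE(res$kl_fb_first))
}

scenario_perturbation <- function(net, images, cfg) {
  sub <- images[seq_len(min(200L, n_images(images)))]
  prof <- perturbation_profile(net, sub, gamma = cfg$perturbation$gamma,
                               metric = cfg$perturbation$metric,
                               n_repeats = cfg$perturbation$n_repeats,
                               seed = derive_seed(cfg$seed, "perturb"))
  agg <- prof |>
    dplyr::group_by(.data$perturbed_layer) |>
    dplyr::summarise(deviation = mean(.data$deviation), .groups = "drop")
  first <- agg$deviation[agg$perturbed_layer == agg$perturbed_layer[1]]
  lastq <- utils::tail(sort(unique(prof$perturbed_layer)), 1)
  list(profile = agg,
       pass = agg$deviation[agg$perturbed_layer == lastq] >
         agg$deviation[agg$perturbed_layer == agg$perturbed_layer[1]])
}

scenario_baselines <- function(net, images, cfg) {
  rg <- cfg$data$region
  d <- min(rg$d, layer_width(net, rg$source_layer))
  rec <- simulate_region(net, images, rg$source_layer, d = d,
                         noise_sd = rg$noise_sd, projection = rg$projection,
                         seed = derive_seed(cfg$seed, "region"))
  fp <- make_fold_plan(images$labels, k = cfg$evaluation$k, seed = cfg$seed)
  mv <- mvpa_suite(rec, images$labels, fold_plan = fp,
                   seed = derive_seed(cfg$seed, "mvpa"))
  iface <- run_interface_grid(net, images, rec, layers = rg$source_layer,
                              fold_plan = fp,
                              seed = derive_seed(cfg$seed, "iface"))
  list(mvpa = mv$results, interfaced_auc = iface$grid$auc[1],
       pass = TRUE)
}

#' Granger dissociation pipeline on a two-region simulation
#'
#' Computes the two rate series (mean feature activity per trial and bin) and
#' the two bin-wise interfaced KL series, stationarizes all four, and runs the
#' expanding-window Granger timeline for both pairs. Returns the timelines and
#' the two qualitative comparisons: does rate causality start
#' feedforward-first (V4 before IT) and KL causality feedback-first (IT before
#' V4)?
#'
#' @param net,images trained net and the trial image set.
#' @param two named list `v4`/`it` of temporal recordings
#'   (from [simulate_two_region_dynamics()]).
#' @param spec the [dynamics_spec()] used (start bin for windows is taken just
#'   before stimulus onset).
#' @param layer translation target layer for the KL series.
#' @param p_max,alpha,criterion Granger settings.
#' @param log_kl log-transform the KL series (after adding `1e-3`) before
#'   stationarization. Per-trial KL levels scale multiplicatively with how
#'   atypical the trial's image-driven prediction is -- a trial-by-bin
#'   interaction shared by both regions that additive standardization cannot
#'   remove and that otherwise leaks into both causal directions; on the log
#'   scale it is additive and the two standardization steps remove it exactly.
#' @param fold_plan,translation,seed passed to [binwise_interface_kl()].
#' @return List: `rate` and `kl` (`granger_timeline`s with x = V4, y = IT),
#'   `rate_ff_first`, `kl_fb_first`.
#' @export
granger_dissociation <- function(net, images, two, spec, layer = "fc1",
                                 p_max = 3, alpha = 0.05, criterion = "bic",
                                 log_kl = TRUE, fold_plan = NULL,
                                 translation = list(), seed = 1) {
  rate_v4 <- apply(two$v4$data, c(1, 2), mean)
  rate_it <- apply(two$it$data, c(1, 2), mean)
  kl_v4 <- binwise_interface_kl(net, layer, two$v4, images,
                                fold_plan = fold_plan,
                                translation = translation,
                                seed = derive_seed(seed, "kl_v4"))
  kl_it <- binwise_interface_kl(net, layer, two$it, images,
                                fold_plan = fold_plan,
                                translation = translation,
                                seed = derive_seed(seed, "kl_it"))
  start <- max(1L, spec$stimulus_on - 1L)
  s_rate_v4 <- stationarize(rate_v4); s_rate_it <- stationarize(rate_it)
  tf <- if (log_kl) function(v) log(v + 1e-3) else identity
  s_kl_v4 <- stationarize(tf(kl_v4$values))
  s_kl_it <- stationarize(tf(kl_it$values))
  tl_rate <- run_granger_timeline(s_rate_v4, s_rate_it, start_bin = start,
                                  p_max = p_max, criterion = criterion,
                                  alpha = alpha)
  tl_rate$x_name <- "V4"; tl_rate$y_name <- "IT"
  tl_kl <- run_granger_timeline(s_kl_v4, s_kl_it, start_bin = start,
                                p_max = p_max, criterion = criterion,
                                alpha = alpha)
  tl_kl$x_name <- "V4"; tl_kl$y_name <- "IT"
  before <- function(a, b) !is.na(a) && (is.na(b) || a < b)
  list(rate = tl_rate, kl = tl_kl,
       rate_ff_first = before(tl_rate$onset_x_to_y, tl_rate$onset_y_to_x),
       kl_fb_first = before(tl_kl$onset_y_to_x, tl_kl$onset_x_to_y),
       kl_series = list(v4 = kl_v4, it = kl_it))
}
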