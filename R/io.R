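# Readers and writers for the package's containers. Plain-text formats
# (PNG + CSV label table for images, CSV for static recordings, long-format
# CSV + JSON sidecar for temporal recordings, JSON/CSV for results); nets and
# translation maps are serialized as RDS checkpoints.

#' Write an image set to a directory of PNGs plus a label table
#'
#' Files are `img_<i>.png`; `labels.csv` holds `filename`, `label` (0-based
#' class id, the on-disk convention), `class_name`, and optional `split_tag`.
#'
#' @param x an [image_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_image_set <- function(x, dir) {
  stopifnot(inherits(x, "image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_images(x)
  fnames <- sprintf("img_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(x$images[i, , , ], file.path(dir, fnames[i]))
  }
  df <- data.frame(filename = fnames, label = x$labels - 1L,
                   class_name = x$class_names[x$labels])
  if (!is.null(x$split_tags)) df$split_tag <- x$split_tags
  write.csv(df, file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(class_names = x$class_names),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an image set written by [write_image_set()]
#' @param dir directory containing PNGs and `labels.csv`.
#' @return An [image_set()].
#' @export
read_image_set <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  assert_that(file.exists(lab_path), sprintf("missing label table: %s", lab_path))
  df <- read.csv(lab_path, stringsAsFactors = FALSE)
  for (col in c("filename", "label")) {
    assert_that(col %in% names(df), sprintf("labels.csv lacks column '%s'", col))
  }
  bad <- which(is.na(df$label) | is.na(df$filename) | df$filename == "")
  if (length(bad)) stop(sprintf("labels.csv: missing label/filename at row %d", bad[1]),
                        call. = FALSE)
  meta_path <- file.path(dir, "meta.json")
  class_names <- if (file.exists(meta_path)) {
    unlist(jsonlite::read_json(meta_path)$class_names)
  } else {
    unique(df$class_name)
  }
  first <- png::readPNG(file.path(dir, df$filename[1]))
  if (length(dim(first)) == 2) dim(first) <- c(dim(first), 1)
  H <- dim(first)[1]; W <- dim(first)[2]; C <- dim(first)[3]
  images <- array(NA_real_, c(nrow(df), H, W, C))
  for (i in seq_len(nrow(df))) {
    p <- file.path(dir, df$filename[i])
    assert_that(file.exists(p), sprintf("labels.csv row %d: missing image %s", i, df$filename[i]))
    img <- png::readPNG(p)
    if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1)
    images[i, , , ] <- img
  }
  image_set(images, df$label + 1L, class_names,
            split_tags = df$split_tag)
}

#' Write a recording set to CSV (static) or long CSV (temporal)
#'
#' Static mode: one row per trial, columns `f1..fd`, plus a `<path>.meta.json`
#' sidecar. Temporal mode: long format with columns `trial`, `bin`, `feature`,
#' `value` and the sidecar carrying `bin_width` and `bin_onsets`.
#'
#' @param rec a `recording_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recordings <- function(rec, path) {
  stopifnot(inherits(rec, "recording_set"))
  meta <- list(region_name = rec$region_name, temporal = rec$temporal,
               bin_width = rec$bin_width, bin_onsets = rec$bin_onsets,
               alignment = rec$alignment)
  if (rec$temporal) {
    d <- dim(rec$data)
    df <- data.frame(
      trial = rep(seq_len(d[1]), times = d[2] * d[3]),
      bin = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      feature = rep(seq_len(d[3]), each = d[1] * d[2]),
      value = as.numeric(rec$data))
  } else {
    df <- as.data.frame(rec$data)
    names(df) <- paste0("f", seq_len(ncol(df)))
  }
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording set written by [write_recordings()]
#' @param path CSV path.
#' @return A `recording_set`.
#' @export
read_recordings <- function(path) {
  assert_that(file.exists(path), sprintf("missing file: %s", path))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
          else list(region_name = "region", temporal = FALSE)
  df <- read.csv(path)
  if (isTRUE(meta$temporal)) {
    for (col in c("trial", "bin", "feature", "value")) {
      assert_that(col %in% names(df), sprintf("temporal CSV lacks column '%s'", col))
    }
    n <- max(df$trial); Tt <- max(df$bin); d <- max(df$feature)
    assert_that(nrow(df) == n * Tt * d, "temporal CSV has missing (trial, bin, feature) cells")
    data <- array(NA_real_, c(n, Tt, d))
    data[cbind(df$trial, df$bin, df$feature)] <- df$value
    recording_set(data, region_name = meta$region_name,
                  bin_width = meta$bin_width, bin_onsets = meta$bin_onsets,
                  alignment = meta$alignment)
  } else {
    recording_set(as.matrix(df), region_name = meta$region_name,
                  alignment = meta$alignment)
  }
}

#' Save / load a trained network checkpoint
#'
#' The checkpoint is a single RDS file holding weights, architecture and
#' training history; reloading reproduces [forward_full()] bit-identically.
#'
#' @param net a `trained_net`.
#' @param path file path.
#' @return `path` invisibly (save); the `trained_net` (load).
#' @export
save_net <- function(net, path) {
  stopifnot(inherits(net, "trained_net"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_net
#' @export
load_net <- function(path) {
  net <- readRDS(path)
  assert_that(inherits(net, "trained_net"), "file does not hold a trained_net")
  net
}

#' Save / load a translation map
#' @param map a `translation_map`.
#' @param path file path.
#' @return `path` invisibly (save); the `translation_map` (load).
#' @export
save_translation_map <- function(map, path) {
  stopifnot(inherits(map, "translation_map"))
  saveRDS(map, path)
  invisible(path)
}

#' @rdname save_translation_map
#' @export
load_translation_map <- function(path) {
  map <- readRDS(path)
  assert_that(inherits(map, "translation_map"), "file does not hold a translation_map")
  map
}

#' Write a correspondence result to JSON (summary) and CSV (long format)
#' @param res a `correspondence_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_correspondence <- function(res, dir) {
  stopifnot(inherits(res, "correspondence_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(mode = res$mode, auc_image = res$auc_image, seed = res$seed,
         grid = res$grid),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  long <- res$per_fold |>
    tidyr::pivot_longer(c("auc", "mean_kl"), names_to = "metric",
                        values_to = "value")
  write.csv(long, file.path(dir, "per_fold.csv"), row.names = FALSE)
  invisible(dir)
}
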