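#' Build a cross-validation fold plan
#'
#' Stratified k-fold: within each stratum (class label or object id), rows are
#' shuffled (seeded) and dealt round-robin onto folds, with a single global
#' fold counter carried across strata so that strata smaller than `k` (e.g.
#' two rows per class) still spread evenly and no fold is left empty.
#' Leave-one-class-out: one fold per class, containing all of its rows, for
#' zero-shot generalization to classes absent from training.
#'
#' @param labels integer (or factor) stratification key per row: class labels,
#'   or object ids when stratification is at the object level.
#' @param k number of folds (ignored for leave-one-class-out).
#' @param scheme `"stratified_kfold"` or `"leave_one_class_out"`.
#' @param seed seed for the within-stratum shuffles.
#' @return A `fold_plan`: list with `folds` (list of held-out row index
#'   vectors partitioning all rows), `scheme`, `k`, and `assignments` (fold id
#'   per row).
#' @export
make_fold_plan <- function(labels, k = 8,
                           scheme = c("stratified_kfold", "leave_one_class_out"),
                           seed = 1) {
  scheme <- match.arg(scheme)
  n <- length(labels)
  labels <- as.integer(as.factor(labels))
  if (scheme == "leave_one_class_out") {
    classes <- sort(unique(labels))
    folds <- lapply(classes, function(cl) which(labels == cl))
    assignments <- labels
    k <- length(classes)
  } else {
    assert_that(k >= 2, "need at least two folds")
    assert_that(k <= n, "more folds than rows")
    assignments <- integer(n)
    with_seed(derive_seed(seed, "fold_plan"), {
      counter <- with_seed(derive_seed(seed, "fold_offset"), sample(k, 1)) - 1L
      for (cl in sample(sort(unique(labels)))) {
        idx <- which(labels == cl)
        idx <- idx[sample(length(idx))]
        for (i in idx) {
          assignments[i] <- (counter %% k) + 1L
          counter <- counter + 1L
        }
      }
    })
    folds <- lapply(seq_len(k), function(f) which(assignments == f))
  }
  structure(list(folds = folds, scheme = scheme, k = k,
                 assignments = assignments, n = n),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %s, %d folds over %d rows (sizes: %s)\n",
              x$scheme, x$k, x$n,
              paste(lengths(x$folds), collapse = ", ")))
  invisible(x)
}
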