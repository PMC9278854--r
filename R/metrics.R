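#' Pairwise two-class AUC via the Mann-Whitney U statistic
#'
#' For scores of class-X rows and class-Y rows, counts over all (i, j) pairs
#' the cases where the X score exceeds the Y score, scoring ties 1/2, and
#' normalizes by the number of pairs. Equivalent to the rank-sum form with
#' midranks, which is how it is computed.
#'
#' @param scores_x numeric scores for the rows of class X.
#' @param scores_y numeric scores for the rows of class Y.
#' @return AUC in `[0, 1]`: the probability (with tie correction) that a
#'   random X row outranks a random Y row.
#' @export
pairwise_auc <- function(scores_x, scores_y) {
  n <- length(scores_x); m <- length(scores_y)
  assert_that(n >= 1 && m >= 1, "both score groups must be nonempty")
  r <- rank(c(scores_x, scores_y), ties.method = "average")
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u / (n * m)
}

#' Multiclass AUC (Hand-Till construction)
#'
#' For each unordered pair of classes (a, b) present in `labels`, computes the
#' two directed pairwise AUCs -- class-a rows vs class-b rows, both scored by
#' the class-a probability, and the reverse scored by the class-b probability
#' -- averages the two, then averages over all pairs. Classes absent from
#' `labels` are skipped. Chance level is 0.5 regardless of the number of
#' classes.
#'
#' @param P numeric `n x m` score matrix (probabilities or any monotone
#'   scores; column j scores class j).
#' @param labels integer class labels in `1..m`, length `n`.
#' @return AUC in `[0, 1]`.
#' @export
multiclass_auc <- function(P, labels) {
  P <- unclass(P)
  stopifnot(nrow(P) == length(labels))
  present <- sort(unique(labels))
  assert_that(length(present) >= 2, "need at least two classes present")
  pairs <- utils::combn(present, 2)
  vals <- apply(pairs, 2, function(ab) {
    a <- ab[1]; b <- ab[2]
    ia <- labels == a; ib <- labels == b
    a_given <- pairwise_auc(P[ia, a], P[ib, a])
    b_given <- pairwise_auc(P[ib, b], P[ia, b])
    (a_given + b_given) / 2
  })
  mean(vals)
}

#' Row-wise Kullback-Leibler divergence between prediction matrices
#'
#' Scores how far the brain-driven predictions `P_r` fall from the image-driven
#' reference `P_i`, row by row. The default direction is `KL(P_i || P_r)`
#' (divergence of the approximation from the reference); the opposite
#' direction is available via `direction`. Probabilities are clipped at
#' `clip` and renormalized before taking logs so one-hot rows cannot produce
#' infinities. Values are in nats and always nonnegative.
#'
#' @param P_r `n x m` approximation (e.g. interfaced) prediction matrix.
#' @param P_i `n x m` reference (image-driven) prediction matrix, same class
#'   order.
#' @param direction `"ref_vs_approx"` (default, `KL(P_i || P_r)`) or
#'   `"approx_vs_ref"` (`KL(P_r || P_i)`).
#' @param clip probability floor applied before renormalization.
#' @return Numeric vector of per-row divergences (nats), with the mean in
#'   attribute `"mean"`.
#' @export
kl_rows <- function(P_r, P_i, direction = c("ref_vs_approx", "approx_vs_ref"),
                    clip = 1e-9) {
  direction <- match.arg(direction)
  P_r <- unclass(P_r); P_i <- unclass(P_i)
  assert_that(all(dim(P_r) == dim(P_i)), "prediction matrices must have identical shape")
  pr <- clip_probs(P_r, clip)
  pi_ <- clip_probs(P_i, clip)
  kl <- if (direction == "ref_vs_approx") {
    rowSums(pi_ * (log(pi_) - log(pr)))
  } else {
    rowSums(pr * (log(pr) - log(pi_)))
  }
  kl <- pmax(kl, 0)
  attr(kl, "mean") <- mean(kl)
  kl
}
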