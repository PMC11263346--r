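#' Extract event boundaries from a latent-cause sequence
#'
#' A boundary is a switch point: `boundaries[t] = 1` iff the inferred cause at
#' `t` differs from the one at `t - 1`; the first entry is always 0.
#'
#' @param x A vector of per-step cause labels, or an [lcnet()] fit (whose
#'   inferred `map_lc` sequence is used).
#' @param ... Unused.
#' @return An integer 0/1 vector of the same length.
#' @examples
#' extract_boundaries(c(1, 1, 2, 2, 1))
#' @export
extract_boundaries <- function(x, ...) UseMethod("extract_boundaries")

#' @rdname extract_boundaries
#' @export
extract_boundaries.default <- function(x, ...) {
  if (length(x) < 1L) stop("`x` must contain at least one element")
  if (length(x) == 1L) return(0L)
  c(0L, as.integer(x[-1] != x[-length(x)]))
}

#' @rdname extract_boundaries
#' @export
extract_boundaries.lcnet <- function(x, ...)
  extract_boundaries(x$trace$map_lc)

#' Cluster purity of inferred latent causes against ground truth
#'
#' For each inferred cluster, take the size of its largest overlap with any
#' true class; purity is the sum of those overlaps divided by the number of
#' observations. A score of 1 means every inferred cluster is contained in a
#' single true class.
#'
#' @param assignments Inferred cluster labels.
#' @param truth True class labels of the same length.
#' @return A number in `[0, 1]`.
#' @examples
#' cluster_purity(c(1, 1, 1, 1), c(1, 1, 2, 2))  # 0.5
#' @export
cluster_purity <- function(assignments, truth) {
  if (length(assignments) != length(truth))
    stop("`assignments` and `truth` must have the same length")
  n <- length(truth)
  if (n < 1L) stop("empty labelings")
  tab <- table(assignments, truth)
  sum(apply(tab, 1L, max)) / n
}

entropy_nat <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Expected mutual information under fixed marginals
#'
#' The expectation of the mutual information between two labelings whose
#' contingency table is drawn from the hypergeometric model induced by random
#' permutation of one labeling (fixed row and column sums).
#'
#' @param a_counts,b_counts Marginal counts of the two labelings (must sum to
#'   the same total).
#' @return Expected MI in nats.
#' @export
expected_mutual_information <- function(a_counts, b_counts) {
  n <- sum(a_counts)
  if (sum(b_counts) != n) stop("marginals must sum to the same total")
  emi <- 0
  for (ai in a_counts) {
    for (bj in b_counts) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        logp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
          lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
          lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
          lgamma(n - ai - bj + nij + 1)
        emi <- emi + (nij / n) * log(n * nij / (ai * bj)) * exp(logp)
      }
    }
  }
  emi
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance agreement under the
#' fixed-marginals permutation model and normalized by the larger of the two
#' entropies: `AMI = (MI - E[MI]) / (max(H(a), H(b)) - E[MI])`. Identical
#' partitions score 1; independent labelings score approximately 0 in
#' expectation. When the denominator is 0 (both labelings constant) the value
#' is 1 if the partitions are identical as partitions and 0 otherwise.
#'
#' @param assignments,truth Label vectors of equal length.
#' @return A number `<= 1`.
#' @examples
#' adjusted_mutual_information(c(1, 1, 2, 2), c(5, 5, 7, 7))  # 1
#' @export
adjusted_mutual_information <- function(assignments, truth) {
  if (length(assignments) != length(truth))
    stop("`assignments` and `truth` must have the same length")
  n <- length(truth)
  tab <- table(assignments, truth)
  a_counts <- rowSums(tab); b_counts <- colSums(tab)
  ha <- entropy_nat(a_counts); hb <- entropy_nat(b_counts)
  p <- tab / n
  nz <- p > 0
  pa <- a_counts / n; pb <- b_counts / n
  outer_p <- outer(pa, pb)
  mi <- sum(p[nz] * log(p[nz] / outer_p[nz]))
  emi <- expected_mutual_information(a_counts, b_counts)
  denom <- max(ha, hb) - emi
  if (abs(denom) < 1e-12) {
    identical_partition <- all(apply(tab, 1, function(r) sum(r > 0) <= 1)) &&
      all(apply(tab, 2, function(r) sum(r > 0) <= 1))
    return(if (identical_partition) 1 else 0)
  }
  (mi - emi) / denom
}

#' Point-biserial correlation between model boundaries and a probability track
#'
#' `r_pb = ((M1 - M0) / s_n) * sqrt(n1 * n0 / n^2)`, where `M1`/`M0` are the
#' mean human boundary probabilities at frames with/without a model boundary,
#' `n1`/`n0` the respective counts, and `s_n` the (population) standard
#' deviation of the probability track. Numerically identical to the Pearson
#' correlation between the binary and the continuous vector.
#'
#' @param model_boundaries Binary 0/1 vector containing both values.
#' @param human_prob Continuous vector of the same length, not constant.
#' @return A number in `[-1, 1]`.
#' @export
point_biserial <- function(model_boundaries, human_prob) {
  n <- length(human_prob)
  if (length(model_boundaries) != n)
    stop("inputs must have the same length")
  if (!all(model_boundaries %in% c(0, 1)))
    stop("`model_boundaries` must be a 0/1 vector")
  n1 <- sum(model_boundaries == 1); n0 <- n - n1
  if (n1 == 0 || n0 == 0)
    stop("undefined correlation: boundary vector is single-valued")
  s_n <- sqrt(mean((human_prob - mean(human_prob))^2))
  if (s_n == 0)
    stop("undefined correlation: `human_prob` is constant")
  m1 <- mean(human_prob[model_boundaries == 1])
  m0 <- mean(human_prob[model_boundaries == 0])
  (m1 - m0) / s_n * sqrt(n1 * n0 / n^2)
}

#' Point-biserial correlation scaled by its achievable range
#'
#' The extreme values of the point-biserial correlation depend on how many
#' boundaries the model inferred. Holding that number `n1` fixed, the maximal
#' (minimal) achievable correlation places the `n1` boundary indicators at
#' the frames with the largest (smallest) probability values; the raw
#' correlation is min-max rescaled to `[0, 1]` within that range.
#'
#' @inheritParams point_biserial
#' @return A number in `[0, 1]`.
#' @export
scaled_point_biserial <- function(model_boundaries, human_prob) {
  r <- point_biserial(model_boundaries, human_prob)
  n <- length(human_prob)
  n1 <- sum(model_boundaries == 1)
  b_max <- b_min <- integer(n)
  b_max[order(human_prob, decreasing = TRUE)[seq_len(n1)]] <- 1L
  b_min[order(human_prob)[seq_len(n1)]] <- 1L
  r_max <- point_biserial(b_max, human_prob)
  r_min <- point_biserial(b_min, human_prob)
  if (r_max == r_min)
    stop("degenerate scaling: maximal and minimal achievable r coincide")
  (r - r_min) / (r_max - r_min)
}

#' Permutation p-value for a boundary statistic
#'
#' Permutes the positions of the first label/boundary vector uniformly
#' (preserving its composition), recomputes the statistic for each
#' permutation, and returns the add-one estimator
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`. Permutations on which
#' the statistic is undefined are redrawn.
#'
#' @param observed_stat The statistic computed on the unpermuted data.
#' @param model_boundaries Vector whose positions are permuted (binary
#'   boundaries or cause labels).
#' @param human_prob Second, fixed argument to `statistic_fn`.
#' @param statistic_fn Function of `(permuted_vector, human_prob)`.
#' @param n_perm Number of permutations (>= 1).
#' @param keep_null Attach the permuted statistics as attribute
#'   `"null_stats"`.
#' @return The p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed_stat, model_boundaries, human_prob,
                               statistic_fn = scaled_point_biserial,
                               n_perm = 1000, keep_null = FALSE) {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  null_stats <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    stat <- NA_real_
    tries <- 0L
    while (is.na(stat)) {
      tries <- tries + 1L
      if (tries > 100L)
        stop("statistic undefined on 100 consecutive permutations")
      perm <- sample(model_boundaries)
      stat <- tryCatch(statistic_fn(perm, human_prob),
                       error = function(e) NA_real_)
    }
    null_stats[i] <- stat
  }
  p <- (1 + sum(null_stats >= observed_stat)) / (1 + n_perm)
  if (keep_null) attr(p, "null_stats") <- null_stats
  p
}
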