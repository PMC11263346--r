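# Independent brute-force oracles used across the suite. These deliberately
# recompute quantities by the most literal route available so that they stay
# independent of the package's implementation.

# plain CRP probability vector from first principles
crp_oracle <- function(counts, alpha) {
  n <- sum(counts)
  c(counts, alpha) / (n + alpha)
}

# softmax of negative per-cause MSE, computed elementwise
softmax_neg_mse_oracle <- function(preds, x_curr, temperature) {
  losses <- vapply(preds, function(p) {
    s <- 0
    for (i in seq_along(p)) s <- s + (p[i] - x_curr[i])^2
    s / length(p)
  }, numeric(1))
  w <- exp(-(losses - min(losses)) / temperature)
  w / sum(w)
}

# Bayes rule by elementwise product then renormalization
bayes_oracle <- function(prior, likelihood) {
  u <- prior * likelihood
  u / sum(u)
}

# mutual information (nats) from a contingency table, double loop
mi_oracle <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (i in ua) for (j in ub) {
    nij <- sum(a == i & b == j)
    if (nij == 0) next
    mi <- mi + (nij / n) * log(n * nij / (sum(a == i) * sum(b == j)))
  }
  mi
}

# E[MI] under the permutation model by exhaustive enumeration of all
# permutations of one labeling (feasible for n <= 8)
emi_enumeration_oracle <- function(a, b) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  ps <- perms(seq_along(a))
  mean(vapply(ps, function(p) mi_oracle(a[p], b), numeric(1)))
}

# maximal/minimal point-biserial over all placements of n1 ones (n <= 12)
pb_extreme_oracle <- function(n, n1, human_prob) {
  sets <- utils::combn(n, n1)
  vals <- apply(sets, 2, function(idx) {
    b <- integer(n); b[idx] <- 1L
    point_biserial(b, human_prob)
  })
  c(max = max(vals), min = min(vals))
}

# elementwise feedforward pass with explicit loops
ff_oracle <- function(net, x, cv) {
  H <- net$hidden_dim
  pre <- numeric(H)
  for (i in seq_len(H)) {
    s <- net$b_h[i]
    for (j in seq_len(net$input_dim)) s <- s + net$W_in[i, j] * x[j]
    if (net$context_dim > 0)
      for (j in seq_len(net$context_dim)) s <- s + net$W_ctx[i, j] * cv[j]
    pre[i] <- s
  }
  h <- tanh(pre)
  out <- numeric(net$output_dim)
  for (k in seq_len(net$output_dim)) {
    s <- net$b_out[k]
    for (i in seq_len(H)) s <- s + net$W_out[k, i] * h[i]
    out[k] <- s
  }
  out
}

# elementwise GRU step following the four printed update equations
gru_oracle <- function(net, x, cv, h_prev) {
  sig <- function(v) 1 / (1 + exp(-v))
  a <- c(h_prev, x, cv)
  z <- sig(as.numeric(net$W_z %*% a) + net$b_z)
  r <- sig(as.numeric(net$W_r %*% a) + net$b_r)
  ar <- c(r * h_prev, x, cv)
  h_cand <- tanh(as.numeric(net$W_h %*% ar) + net$b_h)
  (1 - z) * h_prev + z * h_cand
}

# central finite-difference gradient of the one-step MSE loss with respect to
# a single named parameter entry
fd_grad <- function(loss_fn, net, name, i, j = NULL, eps = 1e-6) {
  bump <- function(net, d) {
    if (is.null(j)) net[[name]][i] <- net[[name]][i] + d
    else net[[name]][i, j] <- net[[name]][i, j] + d
    net
  }
  (loss_fn(bump(net, eps)) - loss_fn(bump(net, -eps))) / (2 * eps)
}

# every composition (ordered count vector) of total n into k positive parts
compositions <- function(n, k) {
  if (k == 1L) return(list(n))
  out <- list()
  for (first in seq_len(n - k + 1L))
    for (rest in compositions(n - first, k - 1L))
      out[[length(out) + 1L]] <- c(first, rest)
  out
}
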