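#' Sticky Chinese Restaurant Process parameters
#'
#' Bundles the hyperparameters of the latent-cause prior and likelihood. Under
#' the sticky CRP, an existing cause `k` receives unnormalized prior mass
#' `count_k + stickiness * I[prev == k]` and a new cause receives mass `alpha`.
#'
#' @param alpha Concentration parameter (>= 0). Larger values make opening a
#'   new latent cause more likely.
#' @param stickiness Bonus mass (>= 0) added to the cause that was active at
#'   the previous step, encoding temporal persistence of contexts.
#' @param temperature Softmax temperature (> 0) used when converting
#'   prediction losses into a likelihood over causes. Smaller values sharpen
#'   the likelihood.
#' @param context_dim Dimension of the Gaussian context vectors indexing each
#'   latent cause.
#' @return An object of class `"scrp_params"`.
#' @examples
#' scrp_params(alpha = 0.5, stickiness = 1)
#' @export
scrp_params <- function(alpha = 0.5, stickiness = 1, temperature = 1,
                        context_dim = 32) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("`alpha` must be a single non-negative number")
  if (!is.numeric(stickiness) || length(stickiness) != 1L || is.na(stickiness) ||
      stickiness < 0)
    stop("`stickiness` must be a single non-negative number")
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0)
    stop("`temperature` must be a single positive number")
  if (!is.numeric(context_dim) || length(context_dim) != 1L || context_dim < 1)
    stop("`context_dim` must be a positive integer")
  structure(list(alpha = alpha, stickiness = stickiness,
                 temperature = temperature,
                 context_dim = as.integer(context_dim)),
            class = "scrp_params")
}

#' @export
print.scrp_params <- function(x, ...) {
  cat("Sticky-CRP parameters: alpha =", x$alpha,
      ", stickiness =", x$stickiness,
      ", temperature =", x$temperature,
      ", context_dim =", x$context_dim, "\n")
  invisible(x)
}

#' Sample a random context vector
#'
#' Context vectors indexing latent causes are independent standard-normal
#' draws; in high dimension such vectors are approximately orthogonal, which
#' is what makes them usable as (nearly) non-interfering indices.
#'
#' @param dim Positive integer, the vector dimension.
#' @return A numeric vector of `dim` iid N(0, 1) draws (uses the global RNG).
#' @examples
#' set.seed(1); sample_context_vector(4)
#' @export
sample_context_vector <- function(dim) {
  if (!is.numeric(dim) || length(dim) != 1L || is.na(dim) || dim < 1)
    stop("`dim` must be a positive integer")
  stats::rnorm(as.integer(dim))
}

#' Create an empty latent-cause registry
#'
#' The registry holds the context vectors of all causes inferred so far, their
#' observation counts, the previously active cause, and one preallocated
#' candidate vector for the cause that has not yet been created. When a new
#' cause is spawned the candidate is adopted verbatim and a fresh candidate is
#' sampled, so the "new-cause" loss is always evaluated with the exact vector
#' that would be adopted.
#'
#' @param dim Context-vector dimension.
#' @return An object of class `"lc_registry"` with fields `vectors`
#'   (`dim x K` matrix), `counts`, `prev_lc` (NA before the first step),
#'   `candidate`, and `dim`.
#' @examples
#' set.seed(1); lc_registry(8)
#' @export
lc_registry <- function(dim) {
  if (!is.numeric(dim) || length(dim) != 1L || is.na(dim) || dim < 1)
    stop("`dim` must be a positive integer")
  dim <- as.integer(dim)
  structure(list(vectors = matrix(numeric(0), nrow = dim, ncol = 0),
                 counts = integer(0),
                 prev_lc = NA_integer_,
                 candidate = sample_context_vector(dim),
                 dim = dim),
            class = "lc_registry")
}

#' @export
print.lc_registry <- function(x, ...) {
  cat("Latent-cause registry:", n_causes(x), "cause(s), context dim", x$dim,
      "\n")
  if (n_causes(x) > 0L) {
    cat("  counts:", paste(x$counts, collapse = " "),
        " prev:", x$prev_lc, "\n")
  }
  invisible(x)
}

#' Number of latent causes in a registry
#' @param registry An `lc_registry`.
#' @return Integer count of causes created so far.
#' @export
n_causes <- function(registry) length(registry$counts)

#' Sticky-CRP prior over latent causes
#'
#' Returns the prior probability of assigning the next observation to each of
#' the `K` existing causes or to a new cause (entry `K + 1`). Existing cause
#' `k` gets mass proportional to `count_k + stickiness * I[prev_lc == k]`; the
#' new cause gets mass proportional to `alpha`. With `stickiness = 0` this is
#' the plain Chinese Restaurant Process.
#'
#' @param registry An `lc_registry`.
#' @param params An `scrp_params` object.
#' @return A probability vector of length `K + 1` summing to 1.
#' @examples
#' set.seed(1)
#' r <- lc_registry(4)
#' r <- update_registry(r, 1)  # spawn first cause
#' scrp_prior(r, scrp_params(alpha = 0.5, stickiness = 1))
#' @export
scrp_prior <- function(registry, params) {
  stopifnot(inherits(registry, "lc_registry"), inherits(params, "scrp_params"))
  w <- c(as.numeric(registry$counts), params$alpha)
  if (!is.na(registry$prev_lc))
    w[registry$prev_lc] <- w[registry$prev_lc] + params$stickiness
  tot <- sum(w)
  if (tot <= 0)
    stop("degenerate prior: no cause has positive mass (K = 0 and alpha = 0)")
  w / tot
}

#' Prediction-loss likelihood over latent causes
#'
#' Each cause is scored by how well the predictive model explains the current
#' observation when run with that cause's context vector:
#' `loss_k = MSE(predict_fn(x_prev, c_k), x_curr)`. The loss of the
#' not-yet-created cause is computed with the registry's preallocated
#' candidate vector. The likelihood is `softmax(-losses / temperature)`
#' (computed in log space), so the maximum-likelihood cause is the one with
#' the lowest loss.
#'
#' @param predict_fn Function of `(x_prev, context_vector)` returning a
#'   predicted observation.
#' @param registry An `lc_registry`.
#' @param x_prev Previous observation (passed through to `predict_fn`).
#' @param x_curr Current observation the causes must explain.
#' @param temperature Positive softmax temperature.
#' @return A list with `likelihood` (length `K + 1`, sums to 1) and `losses`.
#' @export
lc_likelihoods <- function(predict_fn, registry, x_prev, x_curr,
                           temperature = 1) {
  stopifnot(inherits(registry, "lc_registry"))
  if (temperature <= 0) stop("`temperature` must be positive")
  K <- n_causes(registry)
  if (K == 0L) {
    # only the candidate cause exists; its likelihood is trivially 1
    loss <- if (is.null(x_prev) || is.null(x_curr)) NA_real_ else
      mean((predict_fn(x_prev, registry$candidate) - x_curr)^2)
    return(list(likelihood = 1, losses = loss))
  }
  losses <- numeric(K + 1L)
  for (k in seq_len(K))
    losses[k] <- mean((predict_fn(x_prev, registry$vectors[, k]) - x_curr)^2)
  losses[K + 1L] <- mean((predict_fn(x_prev, registry$candidate) - x_curr)^2)
  if (any(!is.finite(losses)))
    stop("non-finite prediction loss while computing likelihoods")
  ll <- -losses / temperature
  ll <- ll - max(ll)
  lik <- exp(ll)
  list(likelihood = lik / sum(lik), losses = losses)
}

#' Local-MAP posterior over latent causes
#'
#' Combines a prior and a likelihood elementwise (in log space) and
#' renormalizes; the maximum a posteriori cause is selected, with ties broken
#' toward the lowest index (older causes win).
#'
#' @param prior Probability vector.
#' @param likelihood Probability vector of the same length.
#' @return A list with `posterior` and `map_lc`.
#' @examples
#' lc_posterior_map(c(0.5, 0.5), c(0.9, 0.1))
#' @export
lc_posterior_map <- function(prior, likelihood) {
  if (length(prior) != length(likelihood))
    stop("`prior` and `likelihood` must have the same length")
  if (abs(sum(prior) - 1) > 1e-6 || abs(sum(likelihood) - 1) > 1e-6)
    stop("`prior` and `likelihood` must each sum to 1")
  lp <- log(prior) + log(likelihood)
  m <- max(lp)
  if (!is.finite(m))
    stop("posterior underflow: prior and likelihood have disjoint support")
  post <- exp(lp - m)
  post <- post / sum(post)
  list(posterior = post, map_lc = which.max(post))
}

#' Record an assignment in the latent-cause registry
#'
#' If `map_lc` equals `K + 1` the preallocated candidate vector is adopted as
#' the new cause's context vector and a fresh candidate is sampled. The
#' selected cause's count is incremented and it becomes the previously active
#' cause. Context vectors of existing causes never change.
#'
#' @param registry An `lc_registry`.
#' @param map_lc Selected cause index in `1..K+1`.
#' @return The updated registry.
#' @export
update_registry <- function(registry, map_lc) {
  stopifnot(inherits(registry, "lc_registry"))
  K <- n_causes(registry)
  if (!is.numeric(map_lc) || length(map_lc) != 1L || is.na(map_lc) ||
      map_lc < 1 || map_lc > K + 1L)
    stop("`map_lc` must be an index in 1..K+1")
  map_lc <- as.integer(map_lc)
  if (map_lc == K + 1L) {
    registry$vectors <- cbind(registry$vectors, registry$candidate)
    registry$counts <- c(registry$counts, 0L)
    registry$candidate <- sample_context_vector(registry$dim)
  }
  registry$counts[map_lc] <- registry$counts[map_lc] + 1L
  registry$prev_lc <- map_lc
  registry
}

#' One step of latent-cause inference
#'
#' Composes the sticky-CRP prior, the prediction-loss likelihood, and the
#' local-MAP rule, then updates the registry. When `inference_enabled` is
#' `FALSE` (used at transitions known to be unpredictable) the previously
#' active cause is carried forward without computing a posterior; its count is
#' still incremented, since the observation is still explained by that cause.
#'
#' @inheritParams lc_likelihoods
#' @param params An `scrp_params` object.
#' @param inference_enabled Logical; carry the previous cause when `FALSE`.
#' @return A list with `trace` (fields `prior`, `likelihood`, `posterior`,
#'   `losses`, `map_lc`, `spawned_new`, `inference`) and the updated
#'   `registry`.
#' @export
infer_step <- function(predict_fn, registry, params, x_prev, x_curr,
                       inference_enabled = TRUE) {
  stopifnot(inherits(registry, "lc_registry"), inherits(params, "scrp_params"))
  K <- n_causes(registry)
  if (!inference_enabled) {
    if (is.na(registry$prev_lc))
      stop("inference-disabled step with no previously active cause")
    map_lc <- registry$prev_lc
    registry <- update_registry(registry, map_lc)
    return(list(trace = list(prior = NULL, likelihood = NULL, posterior = NULL,
                             losses = NULL, map_lc = map_lc,
                             spawned_new = FALSE, inference = FALSE),
                registry = registry))
  }
  prior <- scrp_prior(registry, params)
  lik <- lc_likelihoods(predict_fn, registry, x_prev, x_curr,
                        params$temperature)
  if (K == 0L) {
    posterior <- 1
    map_lc <- 1L
  } else {
    pm <- lc_posterior_map(prior, lik$likelihood)
    posterior <- pm$posterior
    map_lc <- pm$map_lc
  }
  spawned <- map_lc == K + 1L
  registry <- update_registry(registry, map_lc)
  list(trace = list(prior = prior, likelihood = lik$likelihood,
                    posterior = posterior, losses = lik$losses,
                    map_lc = map_lc, spawned_new = spawned, inference = TRUE),
       registry = registry)
}
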