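#' Feedforward predictive network with a context pathway
#'
#' A one-hidden-layer network whose hidden layer receives both the observation
#' and the context vector of the currently inferred latent cause:
#' `hidden = act(W_in x + W_ctx c + b_h)`, `output = W_out hidden + b_out`.
#' The context-to-hidden weights `W_ctx` are learnable; the context vectors
#' themselves are fixed random indices. With `context_dim = 0` the network is
#' context-blind (the baseline architecture, which instead receives any
#' context-indicative signal as part of its input).
#'
#' @param input_dim,context_dim,output_dim Layer dimensions (`context_dim`
#'   may be 0).
#' @param hidden_dim Hidden-layer width.
#' @param init_scale Weights are drawn uniformly from
#'   `[-init_scale, init_scale] / sqrt(fan_in)`.
#' @param activation `"tanh"` (default) or `"identity"`.
#' @return An object of class `"ff_net"`.
#' @examples
#' set.seed(1)
#' net <- ff_net(input_dim = 2, context_dim = 4, output_dim = 1)
#' ff_forward(net, c(0.1, -0.2), rnorm(4))
#' @export
ff_net <- function(input_dim, context_dim, output_dim, hidden_dim = 64,
                   init_scale = 1, activation = c("tanh", "identity")) {
  activation <- match.arg(activation)
  stopifnot(input_dim >= 1, context_dim >= 0, output_dim >= 1, hidden_dim >= 1,
            init_scale > 0)
  ru <- function(nr, nc, fan) {
    matrix(stats::runif(nr * nc, -init_scale, init_scale) / sqrt(fan), nr, nc)
  }
  fan <- input_dim + context_dim
  structure(list(
    W_in = ru(hidden_dim, input_dim, fan),
    W_ctx = if (context_dim > 0) ru(hidden_dim, context_dim, fan) else
      matrix(numeric(0), hidden_dim, 0),
    b_h = numeric(hidden_dim),
    W_out = ru(output_dim, hidden_dim, hidden_dim),
    b_out = numeric(output_dim),
    input_dim = as.integer(input_dim), context_dim = as.integer(context_dim),
    hidden_dim = as.integer(hidden_dim), output_dim = as.integer(output_dim),
    activation = activation
  ), class = "ff_net")
}

act_fun <- function(name) {
  switch(name, tanh = tanh, identity = identity,
         stop("unknown activation: ", name))
}

act_grad <- function(name, h) {
  switch(name, tanh = 1 - h^2, identity = rep(1, length(h)),
         stop("unknown activation: ", name))
}

#' Forward pass of the feedforward network
#'
#' @param net An `ff_net`.
#' @param x Observation vector of length `input_dim`.
#' @param c Context vector of length `context_dim` (may be `NULL` when
#'   `context_dim = 0`).
#' @param lesioned If `TRUE`, the context-to-hidden term is zeroed, removing
#'   the latent-cause pathway while leaving the rest of the network intact.
#' @param return_hidden Also return hidden activations.
#' @return The output vector, or a list `(output, hidden)` when
#'   `return_hidden = TRUE`.
#' @export
ff_forward <- function(net, x, c = NULL, lesioned = FALSE,
                       return_hidden = FALSE) {
  stopifnot(inherits(net, "ff_net"))
  if (length(x) != net$input_dim) stop("`x` has the wrong dimension")
  pre <- drop(net$W_in %*% x) + net$b_h
  if (net$context_dim > 0 && !lesioned) {
    if (is.null(c) || length(c) != net$context_dim)
      stop("`c` has the wrong dimension")
    pre <- pre + drop(net$W_ctx %*% c)
  }
  h <- act_fun(net$activation)(pre)
  y <- drop(net$W_out %*% h) + net$b_out
  if (return_hidden) list(output = y, hidden = h) else y
}

#' One online gradient step
#'
#' Generic single-observation stochastic gradient descent on the mean squared
#' error between the network's prediction and a target. Only network weights
#' are updated; context vectors are fixed indices and receive no gradient.
#'
#' @param net A network object (`ff_net` or `gru_net`).
#' @param ... Passed to methods.
#' @return A list with the updated `net` and the pre-update `loss` (methods
#'   may add fields, e.g. the new hidden state for recurrent networks).
#' @export
train_step <- function(net, ...) UseMethod("train_step")

#' @rdname train_step
#' @param x Input observation vector.
#' @param c Context vector (ignored when `context_dim = 0`).
#' @param target Target vector.
#' @param learning_rate Positive SGD step size.
#' @param clip Elementwise bound on the output-error gradient (gradient
#'   clipping); `Inf` disables it.
#' @export
train_step.ff_net <- function(net, x, c = NULL, target,
                              learning_rate = 0.01, clip = Inf, ...) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  fw <- ff_forward(net, x, c, return_hidden = TRUE)
  y <- fw$output; h <- fw$hidden
  err <- y - target
  loss <- mean(err^2)
  if (!is.finite(loss))
    stop("numerical divergence: non-finite loss in train_step (|y| max = ",
         max(abs(y)), ")")
  dy <- 2 * err / length(err)
  dy <- pmin(pmax(dy, -clip), clip)
  dW_out <- dy %o% h
  dh <- drop(crossprod(net$W_out, dy))
  dpre <- dh * act_grad(net$activation, h)
  net$W_out <- net$W_out - learning_rate * dW_out
  net$b_out <- net$b_out - learning_rate * dy
  net$W_in <- net$W_in - learning_rate * (dpre %o% x)
  net$b_h <- net$b_h - learning_rate * dpre
  if (net$context_dim > 0)
    net$W_ctx <- net$W_ctx - learning_rate * (dpre %o% c)
  list(net = net, loss = loss)
}

#' Gated recurrent unit network with context input
#'
#' A GRU whose input at every step is the observation concatenated with the
#' context vector of the currently inferred latent cause. Gate dynamics follow
#' the standard equations: with `a = [h_prev, x, c]`,
#' `update = sigmoid(W_z a + b_z)`, `reset = sigmoid(W_r a + b_r)`,
#' `h_cand = tanh(W_h [reset * h_prev, x, c] + b_h)`, and
#' `h = (1 - update) * h_prev + update * h_cand` (the forget gate is
#' `1 - update`, so writing and forgetting are synchronized). A linear readout
#' maps the hidden state to the predicted next observation. The gate symbol
#' usually written `z` is called `update` here to avoid a clash with the
#' latent-cause assignment.
#'
#' @inheritParams ff_net
#' @param hidden_dim Number of GRU units.
#' @return An object of class `"gru_net"`.
#' @export
gru_net <- function(input_dim, context_dim, output_dim, hidden_dim = 32,
                    init_scale = 1) {
  stopifnot(input_dim >= 1, context_dim >= 0, output_dim >= 1, hidden_dim >= 1,
            init_scale > 0)
  cat_dim <- hidden_dim + input_dim + context_dim
  ru <- function(nr, nc, fan) {
    matrix(stats::runif(nr * nc, -init_scale, init_scale) / sqrt(fan), nr, nc)
  }
  structure(list(
    W_z = ru(hidden_dim, cat_dim, cat_dim), b_z = numeric(hidden_dim),
    W_r = ru(hidden_dim, cat_dim, cat_dim), b_r = numeric(hidden_dim),
    W_h = ru(hidden_dim, cat_dim, cat_dim), b_h = numeric(hidden_dim),
    W_out = ru(output_dim, hidden_dim, hidden_dim), b_out = numeric(output_dim),
    input_dim = as.integer(input_dim), context_dim = as.integer(context_dim),
    hidden_dim = as.integer(hidden_dim), output_dim = as.integer(output_dim)
  ), class = "gru_net")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_cache <- function(net, x, c, h_prev) {
  xc <- c(x, if (net$context_dim > 0) c)
  a <- c(h_prev, xc)
  z <- sigmoid(drop(net$W_z %*% a) + net$b_z)
  r <- sigmoid(drop(net$W_r %*% a) + net$b_r)
  ar <- c(r * h_prev, xc)
  h_cand <- tanh(drop(net$W_h %*% ar) + net$b_h)
  h <- (1 - z) * h_prev + z * h_cand
  list(a = a, ar = ar, z = z, r = r, h_cand = h_cand, h = h)
}

#' One GRU time step
#'
#' @param net A `gru_net`.
#' @param x Input vector of length `input_dim`.
#' @param c Context vector of length `context_dim` (or `NULL` if 0).
#' @param h_prev Previous hidden state of length `hidden_dim`.
#' @return The new hidden state; each coordinate lies between the
#'   corresponding coordinates of `h_prev` and the candidate state.
#' @export
gru_step <- function(net, x, c = NULL, h_prev) {
  stopifnot(inherits(net, "gru_net"))
  if (length(x) != net$input_dim) stop("`x` has the wrong dimension")
  if (net$context_dim > 0 && (is.null(c) || length(c) != net$context_dim))
    stop("`c` has the wrong dimension")
  if (length(h_prev) != net$hidden_dim) stop("`h_prev` has the wrong dimension")
  gru_cache(net, x, c, h_prev)$h
}

#' Forward pass of the GRU network (hidden update plus readout)
#'
#' @inheritParams gru_step
#' @return A list with `output` (readout of the new hidden state) and `h`.
#' @export
gru_forward <- function(net, x, c = NULL, h_prev) {
  h <- gru_step(net, x, c, h_prev)
  list(output = drop(net$W_out %*% h) + net$b_out, h = h)
}

#' @rdname train_step
#' @param h_prev Previous hidden state (treated as a constant: gradients are
#'   truncated at one step, the standard online-learning simplification).
#' @param ctx_grad_mult Multiplier on the gradient of the context-input
#'   columns of the gate and candidate weights. Values above 1 make the
#'   context pathway the fast, cause-specific store while the shared backbone
#'   changes slowly — the single-network analogue of one-network-per-cause
#'   separation.
#' @export
train_step.gru_net <- function(net, x, c = NULL, target, learning_rate = 0.01,
                               clip = Inf, h_prev, ctx_grad_mult = 1, ...) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  stopifnot(length(h_prev) == net$hidden_dim)
  cc <- gru_cache(net, x, c, h_prev)
  y <- drop(net$W_out %*% cc$h) + net$b_out
  err <- y - target
  loss <- mean(err^2)
  if (!is.finite(loss))
    stop("numerical divergence: non-finite loss in train_step (|y| max = ",
         max(abs(y)), ")")
  H <- net$hidden_dim
  dy <- 2 * err / length(err)
  dy <- pmin(pmax(dy, -clip), clip)
  dW_out <- dy %o% cc$h
  dh <- drop(crossprod(net$W_out, dy))
  dz <- dh * (cc$h_cand - h_prev)
  dh_cand <- dh * cc$z
  dpre_h <- dh_cand * (1 - cc$h_cand^2)
  dar <- drop(crossprod(net$W_h, dpre_h))
  dr <- dar[seq_len(H)] * h_prev
  dpre_z <- dz * cc$z * (1 - cc$z)
  dpre_r <- dr * cc$r * (1 - cc$r)
  gmul <- rep(1, length(cc$a))
  if (ctx_grad_mult != 1 && net$context_dim > 0)
    gmul[H + net$input_dim + seq_len(net$context_dim)] <- ctx_grad_mult
  net$W_out <- net$W_out - learning_rate * dW_out
  net$b_out <- net$b_out - learning_rate * dy
  net$W_h <- net$W_h - learning_rate * (dpre_h %o% (cc$ar * gmul))
  net$b_h <- net$b_h - learning_rate * dpre_h
  net$W_z <- net$W_z - learning_rate * (dpre_z %o% (cc$a * gmul))
  net$b_z <- net$b_z - learning_rate * dpre_z
  net$W_r <- net$W_r - learning_rate * (dpre_r %o% (cc$a * gmul))
  net$b_r <- net$b_r - learning_rate * dpre_r
  list(net = net, loss = loss, h = cc$h)
}

#' One-network-per-cause expert ensemble
#'
#' The predecessor architecture to context-vector indexing: each latent cause
#' owns an independent, freshly initialized network, and only the network of
#' the currently inferred cause ever sees (or is trained on) an observation.
#' Experts never share weights, so there is no interference between causes and
#' no reuse of structure across them.
#'
#' @param factory Zero-argument function returning a freshly initialized
#'   expert network (drawing from the global RNG so experts are independent).
#' @return An object of class `"sem_ensemble"`.
#' @examples
#' set.seed(1)
#' ens <- sem_ensemble(function() ff_net(1, 0, 1, hidden_dim = 8))
#' sel <- sem_select_or_spawn(ens, 1)
#' length(sel$ensemble$experts)
#' @export
sem_ensemble <- function(factory) {
  stopifnot(is.function(factory))
  structure(list(experts = list(), factory = factory), class = "sem_ensemble")
}

#' Select an existing expert or spawn a new one
#'
#' @param ensemble A `sem_ensemble`.
#' @param map_lc Cause index; `length(experts) + 1` spawns a new expert.
#' @return A list with the (possibly grown) `ensemble`, the selected
#'   `expert`, and its `index`.
#' @export
sem_select_or_spawn <- function(ensemble, map_lc) {
  stopifnot(inherits(ensemble, "sem_ensemble"))
  n <- length(ensemble$experts)
  if (!is.numeric(map_lc) || length(map_lc) != 1L || is.na(map_lc) ||
      map_lc < 1 || map_lc > n + 1L)
    stop("`map_lc` must be an index in 1..K+1 (no gaps)")
  map_lc <- as.integer(map_lc)
  if (map_lc == n + 1L)
    ensemble$experts[[map_lc]] <- ensemble$factory()
  list(ensemble = ensemble, expert = ensemble$experts[[map_lc]],
       index = map_lc)
}

#' Store a trained expert back into the ensemble
#'
#' @param ensemble A `sem_ensemble`.
#' @param index Expert index.
#' @param expert The updated expert network.
#' @return The updated ensemble.
#' @export
sem_set_expert <- function(ensemble, index, expert) {
  stopifnot(inherits(ensemble, "sem_ensemble"),
            index >= 1, index <= length(ensemble$experts))
  ensemble$experts[[index]] <- expert
  ensemble
}
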