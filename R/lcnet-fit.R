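#' Fit a latent-cause network to an observation stream
#'
#' Runs online latent-cause inference and prediction learning over a stream of
#' observations. At each step `t >= 2` the model (i) scores every existing
#' latent cause, plus one candidate new cause, by how well a shared predictive
#' network explains the current observation when modulated by that cause's
#' context vector (`softmax(-MSE / temperature)` likelihood, using the
#' previous observation to predict the current one); (ii) combines the scores
#' with a sticky-CRP prior and commits to the maximum a posteriori cause; and
#' (iii) takes one stochastic-gradient step on the prediction error under the
#' chosen cause. Event boundaries are the time points at which the inferred
#' cause switches.
#'
#' @param x Numeric matrix, one observation per row (time runs down the rows).
#' @param targets Optional numeric matrix: `targets[t, ]` is the vector the
#'   model should predict from `x[t, ]`. Defaults to the next observation
#'   (`targets[t, ] = x[t + 1, ]`); rows that are all `NA` are skipped during
#'   training. The observation "explained" by the causes at step `t` is
#'   `targets[t - 1, ]`.
#' @param architecture `"feedforward"` or `"gru"`.
#' @param alpha,stickiness,temperature,context_dim Sticky-CRP and likelihood
#'   hyperparameters; see [scrp_params()].
#' @param hidden_dim Hidden width (default 64 feedforward, 32 GRU).
#' @param learning_rate SGD step size.
#' @param init_scale Weight-initialization scale.
#' @param ctx_init_gain Multiplier applied to the context-to-hidden (or, for
#'   the GRU, the context-input columns of the gate/candidate) weights at
#'   initialization. Values above 1 start the causes in well-separated hidden
#'   regions; 0 starts the context pathway silent, so separation is entirely
#'   learned and a candidate cause predicts like the plain backbone.
#' @param ctx_grad_mult GRU only: gradient multiplier for the context-input
#'   weight columns, making the context pathway the fast cause-specific store
#'   while the shared backbone changes slowly (see [train_step()]).
#' @param inference_mask Logical vector of length `nrow(x)`; `FALSE` marks
#'   steps at which Bayesian inference is turned off and the previous cause is
#'   carried forward (used for transitions known to be unpredictable).
#' @param learn If `FALSE` the network weights are frozen (inference still
#'   runs) — used for untrained control models.
#' @param net Optionally, a pre-built or previously trained network to
#'   continue from.
#' @param registry Optionally, a previously populated [lc_registry()].
#' @param h0 Initial hidden state for the GRU (default zeros).
#' @param seed Optional integer seed set before any random draw, making the
#'   whole trajectory reproducible.
#' @return An object of class `"lcnet"` with components `trace` (a data frame
#'   with one row per time step: `t`, `map_lc`, `spawned_new`, `inference`,
#'   `K`, `loss`), `posterior` (list of per-step posterior vectors),
#'   `predictions` (matrix; row `t` is the model's prediction of
#'   `targets[t - 1, ]` made at inference time), `registry`, `net`, `params`,
#'   `architecture`, and `call`.
#' @examples
#' set.seed(42)
#' x <- rbind(matrix(rnorm(60, 0), 20), matrix(rnorm(60, 3), 20))
#' fit <- lcnet(x, architecture = "feedforward", context_dim = 8,
#'              hidden_dim = 16, seed = 1)
#' print(fit)
#' @export
lcnet <- function(x, targets = NULL,
                  architecture = c("feedforward", "gru"),
                  alpha = 0.5, stickiness = 1, temperature = 1,
                  context_dim = 32, hidden_dim = NULL,
                  learning_rate = 0.01, init_scale = 1, ctx_init_gain = 1,
                  ctx_grad_mult = 1, inference_mask = NULL, learn = TRUE,
                  net = NULL, registry = NULL, h0 = NULL, seed = NULL) {
  architecture <- match.arg(architecture)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  TT <- nrow(x)
  if (TT < 1L) stop("`x` must contain at least one observation")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(targets)) {
    targets <- rbind(x[-1, , drop = FALSE], NA_real_)
  }
  if (!is.matrix(targets)) targets <- matrix(targets, ncol = 1)
  if (nrow(targets) != TT)
    stop("`targets` must have one row per observation")
  if (is.null(inference_mask)) inference_mask <- rep(TRUE, TT)
  if (length(inference_mask) != TT)
    stop("`inference_mask` must have one entry per observation")
  if (is.null(hidden_dim))
    hidden_dim <- if (architecture == "gru") 32L else 64L

  params <- scrp_params(alpha, stickiness, temperature, context_dim)
  if (is.null(registry)) registry <- lc_registry(context_dim)
  out_dim <- ncol(targets)
  if (is.null(net)) {
    if (architecture == "gru") {
      net <- gru_net(ncol(x), context_dim, out_dim, hidden_dim, init_scale)
      if (ctx_init_gain != 1 && context_dim > 0) {
        ctx_cols <- net$hidden_dim + ncol(x) + seq_len(context_dim)
        for (nm in c("W_z", "W_r", "W_h"))
          net[[nm]][, ctx_cols] <- net[[nm]][, ctx_cols] * ctx_init_gain
      }
    } else {
      net <- ff_net(ncol(x), context_dim, out_dim, hidden_dim, init_scale)
      net$W_ctx <- net$W_ctx * ctx_init_gain
    }
  }
  is_gru <- inherits(net, "gru_net")
  h_buf <- if (is_gru) {
    if (is.null(h0)) numeric(net$hidden_dim) else h0
  } else NULL

  map_lc <- integer(TT); spawned <- logical(TT); infl <- logical(TT)
  Ks <- integer(TT); losses <- rep(NA_real_, TT)
  posterior <- vector("list", TT)
  predictions <- matrix(NA_real_, TT, out_dim)

  predict_fn <- function(x_prev, cv) {
    if (is_gru) drop(net$W_out %*% gru_step(net, x_prev, cv, h_buf)) +
      net$b_out
    else ff_forward(net, x_prev, cv)
  }

  for (t in seq_len(TT)) {
    if (t == 1L) {
      # first observation: nothing to predict from. An empty registry spawns
      # the first cause; a continued registry carries the previous cause.
      res <- infer_step(predict_fn, registry, params, NULL, NULL,
                        inference_enabled = n_causes(registry) == 0L)
    } else {
      y_prev <- targets[t - 1L, ]
      x_prev <- x[t - 1L, ]
      obs <- if (all(is.na(y_prev))) NULL else y_prev
      if (is.null(obs)) {
        # no defined observation to explain: carry the previous cause
        res <- infer_step(predict_fn, registry, params, x_prev, obs, FALSE)
      } else {
        res <- infer_step(predict_fn, registry, params, x_prev, obs,
                          inference_enabled = inference_mask[t])
      }
    }
    registry <- res$registry
    z <- res$trace$map_lc
    map_lc[t] <- z; spawned[t] <- res$trace$spawned_new
    infl[t] <- res$trace$inference; Ks[t] <- n_causes(registry)
    posterior[[t]] <- res$trace$posterior
    cz <- registry$vectors[, z]
    if (t > 1L) {
      x_prev <- x[t - 1L, ]
      y_prev <- targets[t - 1L, ]
      have_target <- !all(is.na(y_prev))
      if (have_target) {
        if (is_gru) {
          if (learn) {
            st <- train_step(net, x_prev, cz, y_prev,
                             learning_rate = learning_rate, h_prev = h_buf,
                             ctx_grad_mult = ctx_grad_mult)
            losses[t] <- st$loss
            predictions[t, ] <- drop(net$W_out %*% st$h) + net$b_out
            net <- st$net
            h_buf <- st$h
          } else {
            fw <- gru_forward(net, x_prev, cz, h_buf)
            losses[t] <- mean((fw$output - y_prev)^2)
            predictions[t, ] <- fw$output
            h_buf <- fw$h
          }
        } else {
          pred <- ff_forward(net, x_prev, cz)
          losses[t] <- mean((pred - y_prev)^2)
          predictions[t, ] <- pred
          if (learn) {
            st <- train_step(net, x_prev, cz, y_prev,
                             learning_rate = learning_rate)
            net <- st$net
          }
        }
      } else if (is_gru) {
        h_buf <- gru_step(net, x_prev, cz, h_buf)
      }
    }
  }

  structure(list(
    trace = data.frame(t = seq_len(TT), map_lc = map_lc,
                       spawned_new = spawned, inference = infl, K = Ks,
                       loss = losses),
    posterior = posterior,
    predictions = predictions,
    registry = registry, net = net, params = params,
    architecture = architecture, h = h_buf, learn = learn,
    call = match.call()
  ), class = "lcnet")
}

#' @export
print.lcnet <- function(x, ...) {
  cat("Latent-cause network fit (", x$architecture, ")\n", sep = "")
  cat("  ", nrow(x$trace), " observations, ", n_causes(x$registry),
      " latent cause(s), ", sum(extract_boundaries(x)), " boundaries\n",
      sep = "")
  cat("  alpha = ", x$params$alpha, ", stickiness = ", x$params$stickiness,
      ", temperature = ", x$params$temperature, "\n", sep = "")
  invisible(x)
}

#' @export
summary.lcnet <- function(object, ...) {
  tr <- object$trace
  s <- list(
    architecture = object$architecture,
    n_obs = nrow(tr),
    n_causes = n_causes(object$registry),
    counts = object$registry$counts,
    n_boundaries = sum(extract_boundaries(object)),
    mean_loss = mean(tr$loss, na.rm = TRUE),
    final_loss = mean(utils::tail(stats::na.omit(tr$loss), 20)),
    params = object$params
  )
  class(s) <- "summary.lcnet"
  s
}

#' @export
print.summary.lcnet <- function(x, ...) {
  cat("Latent-cause network fit (", x$architecture, ")\n", sep = "")
  cat("Observations:", x$n_obs, "  Latent causes:", x$n_causes,
      "  Boundaries:", x$n_boundaries, "\n")
  cat("Cause usage counts:", paste(x$counts, collapse = " "), "\n")
  cat("Mean prediction MSE:", signif(x$mean_loss, 4),
      "  (last 20 steps:", paste0(signif(x$final_loss, 4), ")"), "\n")
  print(x$params)
  invisible(x)
}

#' @export
coef.lcnet <- function(object, ...) {
  n <- object$net
  n[grep("^(W|b)_", names(n))]
}

#' @export
residuals.lcnet <- function(object, ...) object$trace$loss

#' @export
fitted.lcnet <- function(object, ...) object$predictions

#' Predict from a fitted latent-cause network
#'
#' Runs the trained network forward over new inputs under a fixed latent
#' cause's context vector (no inference, no learning).
#'
#' @param object An `lcnet` fit.
#' @param newdata Matrix of inputs, one per row.
#' @param lc Latent-cause index whose context vector to use; defaults to the
#'   most recently active cause.
#' @param h0 Initial hidden state (GRU only).
#' @param lesioned Zero the context pathway (feedforward only).
#' @param ... Unused.
#' @return Matrix of predictions, one row per input row.
#' @export
predict.lcnet <- function(object, newdata, lc = NULL, h0 = NULL,
                          lesioned = FALSE, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, ncol = 1)
  if (is.null(lc)) lc <- object$registry$prev_lc
  if (is.na(lc) || lc < 1 || lc > n_causes(object$registry))
    stop("`lc` must index an existing latent cause")
  cv <- object$registry$vectors[, lc]
  net <- object$net
  out <- matrix(NA_real_, nrow(newdata), net$output_dim)
  if (inherits(net, "gru_net")) {
    h <- if (is.null(h0)) numeric(net$hidden_dim) else h0
    for (i in seq_len(nrow(newdata))) {
      fw <- gru_forward(net, newdata[i, ], cv, h)
      out[i, ] <- fw$output
      h <- fw$h
    }
  } else {
    for (i in seq_len(nrow(newdata)))
      out[i, ] <- ff_forward(net, newdata[i, ], cv, lesioned = lesioned)
  }
  out
}

#' Plot the inferred latent-cause trajectory
#'
#' Draws the inferred cause index over time (step function) with event
#' boundaries marked, and the per-step prediction loss underneath.
#'
#' @param x An `lcnet` fit.
#' @param truth Optional vector of ground-truth labels to overlay.
#' @param ... Passed to `plot`.
#' @export
plot.lcnet <- function(x, truth = NULL, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(tr$t, tr$map_lc, type = "s", xlab = "", ylab = "inferred LC",
       main = "Latent-cause trajectory", ...)
  if (!is.null(truth))
    graphics::lines(tr$t, as.integer(factor(truth)), type = "s", col = 2,
                    lty = 2)
  b <- which(extract_boundaries(x) == 1)
  if (length(b)) graphics::abline(v = tr$t[b], col = "grey80")
  plot(tr$t, tr$loss, type = "l", xlab = "time", ylab = "prediction MSE")
  invisible(x)
}

#' Write a posterior trace to CSV
#'
#' One row per time step with columns `t`, `map_lc`, `spawned_new`,
#' `inference`, `K`, `loss`, and the per-cause posterior serialized as a JSON
#' string (empty for inference-disabled steps).
#'
#' @param fit An `lcnet` fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  stopifnot(inherits(fit, "lcnet"))
  tr <- fit$trace
  tr$posterior <- vapply(fit$posterior, function(p) {
    if (is.null(p)) "" else
      as.character(jsonlite::toJSON(as.numeric(p), digits = NA))
  }, character(1))
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
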