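#' Sample a polynomial function-learning task set
#'
#' Each of `n_tasks` regression tasks is the sum of one shared polynomial and
#' a task-specific idiosyncratic polynomial, so the environment has structure
#' that is common across contexts and structure that is not. Every task also
#' carries a context-indicative signal (CIS): a random 128-bit binary vector,
#' observed with bit-flip noise.
#'
#' @param n_tasks Number of tasks (>= 1).
#' @param degree Polynomial degree (>= 1).
#' @param coeff_scale Idiosyncratic coefficients are uniform on
#'   `[-coeff_scale, coeff_scale]`.
#' @param shared_scale Scale of the shared-term coefficients (defaults to
#'   `coeff_scale`; the shared structure can be made more or less prominent
#'   than the task-specific structure).
#' @param x_range Closed interval inputs are drawn from.
#' @param cis_dim CIS length in bits.
#' @param cis_noise_rate Per-bit flip probability in `[0, 0.5)`.
#' @return An object of class `"polynomial_taskset"` with `shared_coeffs`,
#'   `idio_coeffs` (one row per task), `cis_vectors` (one row per task), and
#'   the generator settings.
#' @examples
#' set.seed(1)
#' ts <- sample_polynomial_taskset(4)
#' all.equal(poly_task(ts, 2, 0.3), poly_shared(ts, 0.3) + poly_idio(ts, 2, 0.3))
#' @export
sample_polynomial_taskset <- function(n_tasks = 4, degree = 3, coeff_scale = 1,
                                      x_range = c(-1, 1), cis_dim = 128,
                                      cis_noise_rate = 0.1,
                                      shared_scale = coeff_scale) {
  if (n_tasks < 1) stop("`n_tasks` must be >= 1")
  if (degree < 1) stop("`degree` must be >= 1")
  if (length(x_range) != 2 || x_range[2] <= x_range[1])
    stop("`x_range` must be a non-empty interval")
  if (cis_noise_rate < 0 || cis_noise_rate >= 0.5)
    stop("`cis_noise_rate` must be in [0, 0.5)")
  p <- degree + 1L
  structure(list(
    shared_coeffs = stats::runif(p, -shared_scale, shared_scale),
    idio_coeffs = matrix(stats::runif(n_tasks * p, -coeff_scale, coeff_scale),
                         n_tasks, p),
    cis_vectors = matrix(stats::rbinom(n_tasks * cis_dim, 1, 0.5),
                         n_tasks, cis_dim),
    n_tasks = as.integer(n_tasks), degree = as.integer(degree),
    x_range = x_range, cis_noise_rate = cis_noise_rate
  ), class = "polynomial_taskset")
}

poly_eval <- function(coeffs, x) {
  y <- 0
  for (j in seq_along(coeffs)) y <- y + coeffs[j] * x^(j - 1L)
  y
}

#' Evaluate the shared, idiosyncratic, or full polynomial of a task set
#'
#' By construction `poly_task(ts, i, x) == poly_shared(ts, x) +
#' poly_idio(ts, i, x)` exactly.
#'
#' @param taskset A `polynomial_taskset`.
#' @param x Numeric input(s).
#' @return Numeric value(s) of the polynomial at `x`.
#' @export
poly_shared <- function(taskset, x) poly_eval(taskset$shared_coeffs, x)

#' @rdname poly_shared
#' @param task Task index.
#' @export
poly_idio <- function(taskset, task, x)
  poly_eval(taskset$idio_coeffs[task, ], x)

#' @rdname poly_shared
#' @export
poly_task <- function(taskset, task, x)
  poly_shared(taskset, x) + poly_idio(taskset, task, x)

#' Apply bit-flip noise to a context-indicative signal
#'
#' @param cis Binary (0/1) vector.
#' @param noise_rate Independent per-bit flip probability in `[0, 0.5)`.
#' @return A binary vector of the same length.
#' @examples
#' set.seed(1); make_noisy_cis(c(1, 0, 1, 1), 0.25)
#' @export
make_noisy_cis <- function(cis, noise_rate) {
  if (!all(cis %in% c(0, 1))) stop("`cis` must be a 0/1 vector")
  if (noise_rate < 0 || noise_rate >= 0.5)
    stop("`noise_rate` must be in [0, 0.5)")
  flip <- stats::runif(length(cis)) < noise_rate
  ifelse(flip, 1 - cis, cis)
}

schema_successors <- list(
  `1` = c(`1` = 4, `2` = 3, `3` = 6, `4` = 5),  # cafe: 1-4-5 and 2-3-6
  `2` = c(`1` = 3, `2` = 4, `3` = 5, `4` = 6)   # bar:  1-3-5 and 2-4-6
)

#' Paths allowed by one context of the schema graph
#'
#' @param context 1 (cafe) or 2 (bar).
#' @return A list of the two length-3 state paths of that context.
#' @export
schema_paths <- function(context) {
  if (!context %in% 1:2) stop("`context` must be 1 or 2")
  succ <- schema_successors[[context]]
  lapply(1:2, function(s0) {
    s1 <- unname(succ[as.character(s0)])
    c(s0, s1, unname(succ[as.character(s1)]))
  })
}

#' Create a two-context schema task
#'
#' Six narrative states plus two context-indicative opening states (cafe and
#' bar) are each assigned a fixed random vector; state vectors are identical
#' across contexts (the states are aliased), and only the transition structure
#' differs: in the cafe context the sequences 1-4-5 and 2-3-6 can occur, in
#' the bar context 1-3-5 and 2-4-6. Inputs presented to a model are smoothed:
#' `input = w * current state + (1 - w) * previous state`, giving the model a
#' recency-weighted trace of the recent past.
#'
#' @param state_dim State-vector dimension.
#' @param smoothing_weight `w` in `(0, 1]`.
#' @return An object of class `"schema_task"`; `state_vectors` has 8 rows
#'   (states 1-6, then the cafe and bar opening states).
#' @export
schema_task <- function(state_dim = 32, smoothing_weight = 0.7) {
  if (smoothing_weight <= 0 || smoothing_weight > 1)
    stop("`smoothing_weight` must be in (0, 1]")
  structure(list(
    state_vectors = matrix(stats::rnorm(8 * state_dim), 8, state_dim),
    smoothing_weight = smoothing_weight,
    state_dim = as.integer(state_dim)
  ), class = "schema_task")
}

#' Sample one trial from the schema task
#'
#' A trial is the context's opening (CIS) state followed by one of its two
#' paths, chosen uniformly. For each observation the trial also carries: the
#' smoothed input vector, the prediction target (the next raw state vector),
#' a two-alternative foil (the state that would follow under the *other*
#' context, defined at the predictable transitions), a predictability flag,
#' and an inference mask that disables Bayesian inference at the inherently
#' unpredictable CIS-to-first-state transition.
#'
#' @param task A `schema_task`.
#' @param context 1 (cafe) or 2 (bar).
#' @param prev_state Optional raw state vector preceding the trial (the last
#'   state of the previous trial), used to smooth the first input.
#' @return A list with `raw` (state ids, length 4), `inputs` (4 x dim),
#'   `targets` (4 x dim, last row `NA`), `foils` (4 x dim, `NA` where no
#'   predictable foil exists), `predictable` (logical, per prediction made
#'   *from* each observation), `inference_mask` (logical, per observation),
#'   `context`, and `path`.
#' @export
sample_schema_trial <- function(task, context, prev_state = NULL) {
  stopifnot(inherits(task, "schema_task"))
  if (!context %in% 1:2) stop("`context` must be 1 or 2")
  w <- task$smoothing_weight
  path <- schema_paths(context)[[sample.int(2, 1)]]
  raw <- c(6L + context, path)
  V <- task$state_vectors[raw, , drop = FALSE]
  inputs <- V
  for (t in 2:4) inputs[t, ] <- w * V[t, ] + (1 - w) * V[t - 1L, ]
  if (!is.null(prev_state)) inputs[1, ] <- w * V[1, ] + (1 - w) * prev_state
  targets <- rbind(V[-1, , drop = FALSE], NA_real_)
  foils <- matrix(NA_real_, 4, task$state_dim)
  # foil for the unpredictable opening transition: the other start state
  foils[1, ] <- task$state_vectors[c(2L, 1L)[path[1]], ]
  other <- schema_successors[[3L - context]]
  foils[2, ] <- task$state_vectors[unname(other[as.character(raw[2])]), ]
  foils[3, ] <- task$state_vectors[unname(other[as.character(raw[3])]), ]
  list(raw = raw, inputs = inputs, targets = targets, foils = foils,
       predictable = c(FALSE, TRUE, TRUE, FALSE),
       inference_mask = c(TRUE, FALSE, TRUE, TRUE),
       context = as.integer(context), path = path)
}

#' Build a blocked or interleaved curriculum
#'
#' Training trials either present context 1 for the first half and context 2
#' for the second half (blocked) or strictly alternate contexts from trial to
#' trial (interleaved). Test trials draw their context uniformly at random.
#'
#' @param condition `"blocked"` or `"interleaved"`.
#' @param n_train Even number of training trials.
#' @param n_test Number of test trials.
#' @return A data frame with columns `trial`, `phase` (`"train"`/`"test"`),
#'   and `context`, with the condition stored as an attribute.
#' @examples
#' set.seed(1); make_curriculum("blocked", 4, 2)
#' @export
make_curriculum <- function(condition = c("blocked", "interleaved"),
                            n_train, n_test) {
  condition <- match.arg(condition)
  if (n_train < 2 || n_train %% 2 != 0)
    stop("`n_train` must be a positive even number")
  train_ctx <- if (condition == "blocked")
    rep(1:2, each = n_train / 2) else rep_len(1:2, n_train)
  test_ctx <- sample.int(2, n_test, replace = TRUE)
  out <- data.frame(
    trial = seq_len(n_train + n_test),
    phase = rep(c("train", "test"), c(n_train, n_test)),
    context = c(train_ctx, test_ctx)
  )
  attr(out, "condition") <- condition
  out
}

#' Generate a synthetic naturalistic event-stream corpus
#'
#' A stand-in for a corpus of everyday-activity videos compressed to
#' low-dimensional frame vectors. Each event class owns a fixed linear
#' dynamical generator: a scaled random rotation about a class-specific
#' center, excited by process noise, so that classes differ primarily in how
#' the scene *moves* rather than in a static signature — the class (like the
#' context of a naturalistic activity) is not trivially readable from a
#' single frame, only from its dynamics. The active class evolves as a
#' sticky Markov chain (stay probability `persistence`, switches uniform over
#' the other classes), frames are the latent state plus Gaussian observation
#' noise, and a pool of simulated annotators produces a per-frame
#' boundary-probability track by pressing (with some reliability and temporal
#' jitter) near each true class change.
#'
#' @param n_videos Number of independent streams.
#' @param n_classes Number of event classes (>= 2).
#' @param frames_per_video Frames per stream.
#' @param frame_dim Frame-vector dimension (30 mirrors compressed video
#'   features).
#' @param persistence Per-frame stay probability in `(0, 1)`; mean event
#'   length is `1 / (1 - persistence)` frames.
#' @param obs_noise Observation-noise standard deviation.
#' @param process_noise Standard deviation of the latent process noise that
#'   keeps each class's orbit excited (motion never dies out).
#' @param n_subjects Number of simulated annotators.
#' @param jitter_sd SD (frames) of each annotator's press-time jitter.
#' @param press_prob Probability an annotator presses at all for a boundary.
#' @param spectral_radius Modulus of the class rotation dynamics in `(0, 1)`;
#'   close to 1 gives slowly decaying, persistent motion.
#' @param class_scale Scale of the class orbit centers (controls how far
#'   apart classes sit in frame space).
#' @return An object of class `"event_corpus"`: lists `frames` (T x dim
#'   matrices), `labels`, `boundaries`, `subject_prob` (all per video), plus
#'   the generator parameters.
#' @export
generate_event_corpus <- function(n_videos = 4, n_classes = 12,
                                  frames_per_video = 500, frame_dim = 30,
                                  persistence = 0.99, obs_noise = 0.1,
                                  process_noise = 0.3, n_subjects = 20,
                                  jitter_sd = 1, press_prob = 0.9,
                                  spectral_radius = 0.95, class_scale = 2) {
  if (n_classes < 2) stop("`n_classes` must be >= 2")
  if (persistence <= 0 || persistence >= 1)
    stop("`persistence` must be in (0, 1)")
  if (spectral_radius <= 0 || spectral_radius >= 1)
    stop("`spectral_radius` must be in (0, 1)")
  A <- vector("list", n_classes); mu <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    # scaled random rotation: class identity lives in the motion pattern
    Q <- qr.Q(qr(matrix(stats::rnorm(frame_dim^2), frame_dim, frame_dim)))
    A[[k]] <- spectral_radius * Q
    mu[[k]] <- stats::rnorm(frame_dim) * class_scale
  }
  frames <- labels <- bounds <- probs <- vector("list", n_videos)
  for (v in seq_len(n_videos)) {
    TT <- frames_per_video
    z <- integer(TT)
    z[1] <- sample.int(n_classes, 1)
    for (t in 2:TT) {
      z[t] <- if (stats::runif(1) < persistence) z[t - 1L] else
        sample(setdiff(seq_len(n_classes), z[t - 1L]), 1)
    }
    s <- matrix(0, TT, frame_dim)
    s[1, ] <- mu[[z[1]]] + stats::rnorm(frame_dim, sd = process_noise)
    for (t in 2:TT) {
      k <- z[t]
      s[t, ] <- mu[[k]] + drop(A[[k]] %*% (s[t - 1L, ] - mu[[k]])) +
        stats::rnorm(frame_dim, sd = process_noise)
    }
    X <- s + matrix(stats::rnorm(TT * frame_dim, sd = obs_noise), TT)
    b <- c(0L, as.integer(z[-1] != z[-TT]))
    press <- matrix(0L, n_subjects, TT)
    for (tb in which(b == 1L)) {
      for (sj in seq_len(n_subjects)) {
        if (stats::runif(1) < press_prob) {
          tt <- tb + as.integer(round(stats::rnorm(1, 0, jitter_sd)))
          tt <- min(max(tt, 1L), TT)
          press[sj, tt] <- 1L
        }
      }
    }
    frames[[v]] <- X; labels[[v]] <- z; bounds[[v]] <- b
    probs[[v]] <- colMeans(press)
  }
  structure(list(frames = frames, labels = labels, boundaries = bounds,
                 subject_prob = probs,
                 class_dynamics = A, class_means = mu,
                 params = list(n_videos = n_videos, n_classes = n_classes,
                               frames_per_video = frames_per_video,
                               frame_dim = frame_dim,
                               persistence = persistence,
                               obs_noise = obs_noise,
                               process_noise = process_noise,
                               n_subjects = n_subjects, jitter_sd = jitter_sd,
                               press_prob = press_prob,
                               spectral_radius = spectral_radius,
                               class_scale = class_scale)),
            class = "event_corpus")
}

#' @export
print.event_corpus <- function(x, ...) {
  p <- x$params
  cat("Synthetic event corpus:", p$n_videos, "stream(s) x",
      p$frames_per_video, "frames,", p$n_classes, "event classes,",
      "frame dim", p$frame_dim, "\n")
  invisible(x)
}

#' Write a synthetic event corpus to plain-text files
#'
#' Writes one `frames_<v>.csv` per video, a combined `annotations.csv`
#' (columns `video_id`, `t`, `label`, `boundary`, `subject_prob`), and a
#' `manifest.json` recording all generator parameters.
#'
#' @param corpus An `event_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_event_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "event_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- list()
  for (v in seq_along(corpus$frames)) {
    utils::write.csv(as.data.frame(corpus$frames[[v]]),
                     file.path(dir, sprintf("frames_%d.csv", v)),
                     row.names = FALSE)
    ann[[v]] <- data.frame(video_id = v, t = seq_along(corpus$labels[[v]]),
                           label = corpus$labels[[v]],
                           boundary = corpus$boundaries[[v]],
                           subject_prob = corpus$subject_prob[[v]])
  }
  utils::write.csv(do.call(rbind, ann), file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(corpus$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
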