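#' Default configuration for a simulation
#'
#' Returns the full set of tunable parameters for one of the three simulation
#' studies, as a flat named list suitable for [write_experiment_config()].
#' Every runner records the configuration it was given, and the same
#' configuration plus seed reproduces a run exactly.
#'
#' @param simulation 1 (polynomial function learning), 2 (schema curricula),
#'   or 3 (event segmentation on the synthetic corpus).
#' @return A named list.
#' @export
default_config <- function(simulation) {
  base <- list(simulation = as.integer(simulation), seed = 0L,
               alpha = 0.5, stickiness = 1, init_scale = 1)
  extra <- switch(as.character(simulation),
    "1" = list(n_runs = 10L, n_tasks = 4L, degree = 3L, coeff_scale = 1,
               shared_scale = 2, x_range = c(-1, 1), cis_dim = 128L,
               cis_noise_rate = 0.1,
               obs_per_epoch = 1500L, hidden_dim = 64L, learning_rate = 0.004,
               rf_input_gain = 6, rf_bias_gain = 4, ctx_init_scale = 1.2,
               ctx_dropout = 0.1, dropout_lr = 6e-4, grad_clip = 2,
               temperature = 0.005, context_dim = 32L, cis_lr = 0.003,
               test_grid_n = 50L, criterion_mse = 0.05,
               criterion_window = 10L),
    "2" = list(n_runs = 10L, n_train = 100L, n_test = 40L, state_dim = 32L,
               smoothing_weight = 0.7, hidden_dim = 128L, learning_rate = 0.1,
               temperature = 0.05, context_dim = 32L, ctx_init_gain = 0,
               conditions = c("blocked", "interleaved"),
               stickiness_values = NULL),
    "3" = list(n_models = 6L, n_videos = 4L, n_classes = 12L,
               frames_per_video = 500L, frame_dim = 30L, persistence = 0.99,
               obs_noise = 0.1, process_noise = 0.3, n_subjects = 20L,
               jitter_sd = 1, press_prob = 0.9, spectral_radius = 0.95,
               class_scale = 2,
               hidden_dim = 32L, learning_rate = 0.03, temperature = 0.1,
               context_dim = 16L, ctx_init_gain = 0, ctx_grad_mult = 10,
               n_perm = 1000L, include_frozen = TRUE,
               n_checkpoints = 10L),
    stop("`simulation` must be 1, 2, or 3"))
  c(base, extra)
}

# --- Simulation 1 internals -------------------------------------------------

# Online linear predictor mapping a context vector to the expected CIS;
# serves as predict_fn for infer_step so that LC inference is driven by the
# context-indicative signal. The offset is fixed at 0.5 (the marginal bit
# mean) and only the context-dependent weights are trained, so an untrained
# (candidate) cause keeps a loss ~ 0.25 against any CIS — between a learned
# match (~ the flip-noise level) and a mismatched cause (~ 0.45).
new_cis_channel <- function(cis_dim, context_dim, lr) {
  list(W = matrix(0, cis_dim, context_dim), b = rep(0.5, cis_dim), lr = lr)
}

cis_predict <- function(ch, cv) drop(ch$W %*% cv) + ch$b

cis_channel_step <- function(ch, registry, params, cis) {
  res <- infer_step(function(xp, cv) cis_predict(ch, cv),
                    registry, params, NULL, cis, TRUE)
  z <- res$trace$map_lc
  cv <- res$registry$vectors[, z]
  err <- cis_predict(ch, cv) - cis
  ch$W <- ch$W - ch$lr * (err %o% cv)
  list(channel = ch, registry = res$registry, map_lc = z)
}

# Test-time inference: MAP over *existing* causes given a CIS, with no
# stickiness carry-over and no registry update.
cis_channel_probe <- function(ch, registry, params, cis) {
  K <- n_causes(registry)
  if (K == 0L) stop("cannot probe an empty registry")
  frozen <- registry
  frozen$prev_lc <- NA_integer_
  prior <- scrp_prior(frozen, params)
  lik <- lc_likelihoods(function(xp, cv) cis_predict(ch, cv),
                        frozen, NULL, cis, params$temperature)
  post <- prior * lik$likelihood
  which.max(post[seq_len(K)])
}

#' Observations to criterion on a learning curve
#'
#' First observation index at which the running mean of the last `window`
#' losses drops below `threshold`; curves that never reach criterion are
#' censored at `length(losses) + 1`.
#'
#' @param losses Per-observation training losses.
#' @param threshold Criterion MSE.
#' @param window Running-mean window length.
#' @return An integer index (possibly the censoring value).
#' @export
obs_to_criterion <- function(losses, threshold, window = 20) {
  n <- length(losses)
  if (n < window) return(n + 1L)
  cm <- cumsum(losses)
  run_mean <- (cm[window:n] - c(0, cm[seq_len(n - window)])) / window
  hit <- which(run_mean < threshold)
  if (length(hit) == 0L) n + 1L else hit[1] + window - 1L
}

#' Run Simulation 1: shared structure and catastrophic interference
#'
#' Trains three models on a sequence of polynomial regression tasks presented
#' in fully blocked epochs (epoch `i` contains only task `i`): a context-blind
#' baseline network that receives the noisy context-indicative signal (CIS)
#' as input, a context-vector-indexed network (latent causes inferred from
#' the CIS), and a one-network-per-cause expert ensemble. After every epoch
#' all models are tested on all tasks; within-epoch learning curves and a
#' post-training lesion analysis (context pathway zeroed, output compared to
#' the generating shared term) are recorded.
#'
#' @param config List from [default_config()] (simulation 1), possibly
#'   modified.
#' @return A tidy data frame with columns `run`, `model`, `epoch`, `index`,
#'   `measure`, `value`. Measures: `test_mse` (index = tested task),
#'   `train_loss` (index = observation), `obs_to_criterion`, `lesion_cor`.
#' @export
run_sim1 <- function(config = default_config(1)) {
  stopifnot(config$simulation == 1)
  out <- list()
  grid <- seq(config$x_range[1], config$x_range[2],
              length.out = config$test_grid_n)
  for (run in seq_len(config$n_runs)) {
    set.seed(config$seed + run - 1L)
    ts <- sample_polynomial_taskset(config$n_tasks, config$degree,
                                    config$coeff_scale, config$x_range,
                                    config$cis_dim, config$cis_noise_rate,
                                    shared_scale = config$shared_scale)
    params <- scrp_params(config$alpha, config$stickiness,
                          config$temperature, config$context_dim)
    baseline <- ff_net(1L + config$cis_dim, 0L, 1L, config$hidden_dim,
                       config$init_scale)
    lcn <- ff_net(1L, config$context_dim, 1L, config$hidden_dim,
                  config$init_scale)
    # Random-feature regime: wide-spread input weights and biases give the
    # hidden layer kinks across the trained x range even at a zero context,
    # and a strong context scale puts different causes in well-separated
    # hidden regions from the outset.
    H <- config$hidden_dim
    lcn$W_in <- matrix(stats::runif(H, -config$rf_input_gain,
                                    config$rf_input_gain), H, 1)
    lcn$b_h <- stats::runif(H, -config$rf_bias_gain, config$rf_bias_gain)
    lcn$W_ctx <- matrix(stats::runif(H * config$context_dim,
                                     -config$ctx_init_scale,
                                     config$ctx_init_scale),
                        H, config$context_dim)
    lcn_ch <- new_cis_channel(config$cis_dim, config$context_dim,
                              config$cis_lr)
    lcn_reg <- lc_registry(config$context_dim)
    sem <- sem_ensemble(local({
      hd <- config$hidden_dim; sc <- config$init_scale
      function() ff_net(1L, 0L, 1L, hd, sc)
    }))
    sem_ch <- new_cis_channel(config$cis_dim, config$context_dim,
                              config$cis_lr)
    sem_reg <- lc_registry(config$context_dim)

    for (epoch in seq_len(config$n_tasks)) {
      tl <- matrix(NA_real_, config$obs_per_epoch, 3,
                   dimnames = list(NULL, c("baseline", "lcnet", "sem")))
      for (i in seq_len(config$obs_per_epoch)) {
        x <- stats::runif(1, config$x_range[1], config$x_range[2])
        y <- poly_task(ts, epoch, x)
        cis <- make_noisy_cis(ts$cis_vectors[epoch, ], config$cis_noise_rate)
        st <- train_step(baseline, c(x, cis), NULL, y,
                         config$learning_rate, clip = config$grad_clip)
        baseline <- st$net; tl[i, "baseline"] <- st$loss
        cs <- cis_channel_step(lcn_ch, lcn_reg, params, cis)
        lcn_ch <- cs$channel; lcn_reg <- cs$registry
        if (stats::runif(1) < config$ctx_dropout) {
          # context dropout: an occasional slow step with the context pathway
          # silenced regularizes the backbone toward task-general structure
          st <- train_step(lcn, x, numeric(config$context_dim), y,
                           config$dropout_lr, clip = config$grad_clip)
          lcn <- st$net
          st <- list(loss = st$loss)
          tl[i, "lcnet"] <- st$loss
        } else {
          st <- train_step(lcn, x, lcn_reg$vectors[, cs$map_lc], y,
                           config$learning_rate, clip = config$grad_clip)
          lcn <- st$net; tl[i, "lcnet"] <- st$loss
        }
        cs <- cis_channel_step(sem_ch, sem_reg, params, cis)
        sem_ch <- cs$channel; sem_reg <- cs$registry
        sel <- sem_select_or_spawn(sem, cs$map_lc)
        st <- train_step(sel$expert, x, NULL, y, config$learning_rate,
                         clip = config$grad_clip)
        sem <- sem_set_expert(sel$ensemble, sel$index, st$net)
        tl[i, "sem"] <- st$loss
      }
      for (m in colnames(tl)) {
        out[[length(out) + 1L]] <- data.frame(
          run = run, model = m, epoch = epoch,
          index = seq_len(config$obs_per_epoch), measure = "train_loss",
          value = tl[, m])
        out[[length(out) + 1L]] <- data.frame(
          run = run, model = m, epoch = epoch, index = NA_integer_,
          measure = "obs_to_criterion",
          value = obs_to_criterion(tl[, m], config$criterion_mse,
                                   config$criterion_window))
      }
      # end-of-epoch test on all tasks
      for (task in seq_len(config$n_tasks)) {
        truth <- poly_task(ts, task, grid)
        pb <- pl <- ps <- numeric(length(grid))
        z_l <- cis_channel_probe(lcn_ch, lcn_reg, params,
                                 make_noisy_cis(ts$cis_vectors[task, ],
                                                config$cis_noise_rate))
        z_s <- cis_channel_probe(sem_ch, sem_reg, params,
                                 make_noisy_cis(ts$cis_vectors[task, ],
                                                config$cis_noise_rate))
        for (g in seq_along(grid)) {
          cis <- make_noisy_cis(ts$cis_vectors[task, ], config$cis_noise_rate)
          pb[g] <- ff_forward(baseline, c(grid[g], cis))
          pl[g] <- ff_forward(lcn, grid[g], lcn_reg$vectors[, z_l])
          ps[g] <- ff_forward(sem$experts[[min(z_s, length(sem$experts))]],
                              grid[g])
        }
        vals <- c(baseline = mean((pb - truth)^2),
                  lcnet = mean((pl - truth)^2),
                  sem = mean((ps - truth)^2))
        out[[length(out) + 1L]] <- data.frame(
          run = run, model = names(vals), epoch = epoch, index = task,
          measure = "test_mse", value = unname(vals))
        out[[length(out) + 1L]] <- data.frame(
          run = run, model = c("lcnet", "sem"), epoch = epoch, index = task,
          measure = "probe_lc", value = c(z_l, z_s))
      }
    }
    # lesion analysis: context pathway zeroed, compare to the shared term
    lesioned <- vapply(grid, function(g) ff_forward(lcn, g, NULL,
                                                    lesioned = TRUE),
                       numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      run = run, model = "lcnet", epoch = NA_integer_, index = NA_integer_,
      measure = "lesion_cor",
      value = stats::cor(lesioned, poly_shared(ts, grid)))
  }
  do.call(rbind, out)
}

# --- Simulation 2 internals -------------------------------------------------

run_sim2_once <- function(config, condition, lambda, run) {
  set.seed(config$seed + run - 1L)
  task <- schema_task(config$state_dim, config$smoothing_weight)
  cur <- make_curriculum(condition, config$n_train, config$n_test)
  n_trials <- nrow(cur)
  inputs <- targets <- foils <- NULL
  mask <- predictable <- logical(0)
  prev_state <- NULL
  obs_phase <- character(0); obs_trial <- integer(0); obs_ctx <- integer(0)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tr <- sample_schema_trial(task, cur$context[i], prev_state)
    trials[[i]] <- tr
    inputs <- rbind(inputs, tr$inputs)
    targets <- rbind(targets, tr$targets)
    foils <- rbind(foils, tr$foils)
    mask <- c(mask, tr$inference_mask)
    predictable <- c(predictable, tr$predictable)
    obs_phase <- c(obs_phase, rep(cur$phase[i], 4))
    obs_trial <- c(obs_trial, rep(i, 4))
    obs_ctx <- c(obs_ctx, rep(cur$context[i], 4))
    prev_state <- task$state_vectors[tr$raw[4], ]
  }
  # across trials, the target of a trial's last state is the next trial's
  # opening (CIS) state: the transition whose likelihood signals the context
  TT <- nrow(inputs)
  last_steps <- which(seq_len(TT) %% 4 == 0)
  for (t in last_steps[-length(last_steps)])
    targets[t, ] <- task$state_vectors[trials[[t / 4 + 1L]]$raw[1], ]
  fit <- lcnet(inputs, targets = targets, architecture = "feedforward",
               alpha = config$alpha, stickiness = lambda,
               temperature = config$temperature,
               context_dim = config$context_dim,
               hidden_dim = config$hidden_dim,
               learning_rate = config$learning_rate,
               init_scale = config$init_scale,
               ctx_init_gain = config$ctx_init_gain,
               inference_mask = mask)
  correct <- rep(NA, TT)
  for (t in which(predictable)) {
    pred <- fit$predictions[t + 1L, ]
    if (any(is.na(pred))) next
    correct[t] <- sum((pred - targets[t, ])^2) < sum((pred - foils[t, ])^2)
  }
  acc <- tapply(correct, obs_trial, function(v) mean(v, na.rm = TRUE))
  rows <- data.frame(run = run, condition = condition, lambda = lambda,
                     phase = cur$phase, trial = cur$trial,
                     measure = "acc_2afc", value = as.numeric(acc))
  test_idx <- obs_phase == "test"
  train_idx <- obs_phase == "train"
  # trial-level latent-cause assignment: the trial's majority cause (the
  # trial is the unit at which the context is defined; ties go to the later
  # cause, i.e. where inference settled)
  trial_lc <- vapply(split(fit$trace$map_lc, obs_trial), function(z) {
    tab <- table(z)
    cand <- as.integer(names(tab)[tab == max(tab)])
    cand[length(cand)]
  }, integer(1))
  extra <- data.frame(
    run = run, condition = condition, lambda = lambda,
    phase = c("test", "train", "test", "test"), trial = NA_integer_,
    measure = c("purity", "purity", "purity_obs", "n_lcs"),
    value = c(cluster_purity(trial_lc[cur$phase == "test"],
                             cur$context[cur$phase == "test"]),
              cluster_purity(trial_lc[cur$phase == "train"],
                             cur$context[cur$phase == "train"]),
              cluster_purity(fit$trace$map_lc[test_idx], obs_ctx[test_idx]),
              n_causes(fit$registry)))
  rbind(rows, extra)
}

#' Run Simulation 2: curriculum effects on schema learning
#'
#' Trains the feedforward latent-cause network on the two-context schema
#' graph under blocked and interleaved curricula, then tests on randomly
#' ordered contexts. Records per-trial two-alternative forced-choice accuracy
#' (the prediction must be strictly closer to the true next state than to the
#' other context's continuation; ties count as errors), latent-cause purity,
#' and, when `config$stickiness_values` is set, a sweep over the stickiness
#' parameter.
#'
#' @param config List from [default_config()] (simulation 2).
#' @return A tidy data frame with columns `run`, `condition`, `lambda`,
#'   `phase`, `trial`, `measure`, `value`.
#' @export
run_sim2 <- function(config = default_config(2)) {
  stopifnot(config$simulation == 2)
  lambdas <- config$stickiness_values
  if (is.null(lambdas)) lambdas <- config$stickiness
  out <- list()
  for (lambda in lambdas)
    for (condition in config$conditions)
      for (run in seq_len(config$n_runs))
        out[[length(out) + 1L]] <- run_sim2_once(config, condition, lambda,
                                                 run)
  do.call(rbind, out)
}

# --- Simulation 3 internals -------------------------------------------------

# Permutation null for adjusted mutual information. The expected-MI
# correction and the entropy normalizer depend only on the marginals, which
# permutation preserves, so they are computed once.
ami_permutation_null <- function(assignments, truth, n_perm) {
  n <- length(truth)
  tab <- table(assignments, truth)
  a_counts <- rowSums(tab); b_counts <- colSums(tab)
  emi <- expected_mutual_information(a_counts, b_counts)
  denom <- max(entropy_nat(a_counts), entropy_nat(b_counts)) - emi
  mi_of <- function(a) {
    p <- table(a, truth) / n
    nz <- p > 0
    po <- outer(rowSums(p), colSums(p))
    sum(p[nz] * log(p[nz] / po[nz]))
  }
  if (abs(denom) < 1e-12) return(rep(0, n_perm))
  vapply(seq_len(n_perm),
         function(i) (mi_of(sample(assignments)) - emi) / denom,
         numeric(1))
}

run_sim3_model <- function(config, corpus, model_id, learn, model_seed) {
  set.seed(model_seed)
  net <- NULL; registry <- NULL
  lc_seq <- integer(0); bound <- integer(0); Ks <- integer(0)
  for (v in seq_along(corpus$frames)) {
    fit <- lcnet(corpus$frames[[v]], architecture = "gru",
                 alpha = config$alpha, stickiness = config$stickiness,
                 temperature = config$temperature,
                 context_dim = config$context_dim,
                 hidden_dim = config$hidden_dim,
                 learning_rate = config$learning_rate,
                 init_scale = config$init_scale,
                 ctx_init_gain = config$ctx_init_gain,
                 ctx_grad_mult = config$ctx_grad_mult,
                 learn = learn, net = net, registry = registry)
    net <- fit$net; registry <- fit$registry
    lc_seq <- c(lc_seq, fit$trace$map_lc)
    bound <- c(bound, extract_boundaries(fit))
    Ks <- c(Ks, fit$trace$K)
  }
  labels <- unlist(corpus$labels)
  probs <- unlist(corpus$subject_prob)
  n <- length(labels)
  ami <- adjusted_mutual_information(lc_seq, labels)
  null_ami <- ami_permutation_null(lc_seq, labels, config$n_perm)
  ami_p <- (1 + sum(null_ami >= ami)) / (1 + config$n_perm)
  ami_q975 <- stats::quantile(null_ami, 0.975, names = FALSE)
  pur <- cluster_purity(lc_seq, labels)
  if (sum(bound) > 0 && sum(bound) < n) {
    spb <- scaled_point_biserial(bound, probs)
    spb_p <- permutation_pvalue(spb, bound, probs,
                                statistic_fn = scaled_point_biserial,
                                n_perm = config$n_perm)
  } else {
    spb <- NA_real_; spb_p <- NA_real_
  }
  ck <- unique(round(seq(n / config$n_checkpoints, n,
                         length.out = config$n_checkpoints)))
  cum_ami <- vapply(ck, function(m)
    adjusted_mutual_information(lc_seq[seq_len(m)], labels[seq_len(m)]),
    numeric(1))
  rbind(
    data.frame(model = model_id, index = NA_integer_,
               measure = c("ami", "ami_p", "ami_null_q975", "purity", "spb",
                           "spb_p", "n_lcs", "n_boundaries"),
               value = c(ami, ami_p, ami_q975, pur, spb, spb_p,
                         n_causes(registry), sum(bound))),
    data.frame(model = model_id, index = ck, measure = "ami_cum",
               value = cum_ami),
    data.frame(model = model_id, index = ck, measure = "n_lcs_over_time",
               value = Ks[ck])
  )
}

#' Run Simulation 3: event segmentation of a synthetic naturalistic corpus
#'
#' Generates one synthetic event-stream corpus, then trains several
#' independently initialized recurrent (GRU) latent-cause networks on
#' next-frame prediction, with no feedback on the inference itself. For each
#' model it extracts event boundaries (switch points of the inferred cause)
#' and scores them: cluster purity and adjusted mutual information against
#' ground-truth event labels (with a label-permutation null), and the scaled
#' point-biserial correlation against the simulated annotators' boundary
#' probabilities (with a position-permutation null). A frozen-at-
#' initialization control model is included when `config$include_frozen`.
#'
#' @param config List from [default_config()] (simulation 3).
#' @return A tidy data frame with columns `model` (integer id or `"frozen"`),
#'   `index`, `measure`, `value`.
#' @export
run_sim3 <- function(config = default_config(3)) {
  stopifnot(config$simulation == 3)
  set.seed(config$seed)
  corpus <- generate_event_corpus(
    n_videos = config$n_videos, n_classes = config$n_classes,
    frames_per_video = config$frames_per_video,
    frame_dim = config$frame_dim, persistence = config$persistence,
    obs_noise = config$obs_noise, process_noise = config$process_noise,
    n_subjects = config$n_subjects,
    jitter_sd = config$jitter_sd, press_prob = config$press_prob,
    spectral_radius = config$spectral_radius,
    class_scale = config$class_scale)
  out <- list()
  for (m in seq_len(config$n_models))
    out[[length(out) + 1L]] <-
      run_sim3_model(config, corpus, as.character(m), TRUE,
                     config$seed + m)
  if (isTRUE(config$include_frozen))
    out[[length(out) + 1L]] <-
      run_sim3_model(config, corpus, "frozen", FALSE,
                     config$seed + config$n_models + 1L)
  do.call(rbind, out)
}

#' Aggregate results tables across runs
#'
#' Stacks tidy results tables and reports, for every design cell (every
#' combination of the non-`run`, non-`value` columns), the mean, standard
#' error, and number of contributing runs. The output is sorted by the design
#' columns, so it is invariant to the input order.
#'
#' @param tables A list of results data frames with identical columns (a
#'   single data frame is also accepted).
#' @return A data frame with the design columns plus `mean`, `se`, `n`.
#' @export
aggregate_runs <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  cols <- lapply(tables, function(d) sort(names(d)))
  if (length(unique(vapply(cols, paste, character(1), collapse = ","))) != 1L)
    stop("heterogeneous designs: tables have different columns")
  df <- do.call(rbind, tables)
  unit <- if ("run" %in% names(df)) "run" else if ("model" %in% names(df))
    "model" else stop("no replicate column (`run` or `model`) found")
  grp_cols <- setdiff(names(df), c(unit, "value"))
  key <- df[grp_cols]
  key[] <- lapply(key, function(v) ifelse(is.na(v), "<NA>", as.character(v)))
  id <- do.call(paste, c(key, sep = "\r"))
  o <- order(id)
  df <- df[o, ]; id <- id[o]
  sp <- split(df$value, factor(id, levels = unique(id)))
  first <- df[!duplicated(id), grp_cols, drop = FALSE]
  stats_ <- t(vapply(sp, function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    c(mean = if (n) mean(v) else NA_real_,
      se = if (n > 1) stats::sd(v) / sqrt(n) else 0,
      n = n)
  }, numeric(3)))
  res <- cbind(first, as.data.frame(stats_))
  rownames(res) <- NULL
  res
}

#' Save a run's outputs in the standard layout
#'
#' Writes `results.csv`, `summary.json` (the aggregated table), and
#' `config.yaml` into `dir`.
#'
#' @param results Tidy results data frame from a `run_sim*` function.
#' @param config The configuration that produced it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run <- function(results, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results, file.path(dir, "results.csv"), row.names = FALSE)
  jsonlite::write_json(aggregate_runs(results),
                       file.path(dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  write_experiment_config(config, file.path(dir, "config.yaml"))
  invisible(dir)
}
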