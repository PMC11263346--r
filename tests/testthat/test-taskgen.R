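test_that("polynomial tasks decompose exactly into shared plus idiosyncratic
           terms", {
  set.seed(31)
  ts <- sample_polynomial_taskset(n_tasks = 4, degree = 3)
  x <- runif(1000, -1, 1)
  for (i in 1:4) {
    expect_identical(poly_task(ts, i, x),
                     poly_shared(ts, x) + poly_idio(ts, i, x))
  }
  # four distinct idiosyncratic coefficient vectors
  expect_equal(nrow(unique(ts$idio_coeffs)), 4)

  set.seed(0); a <- sample_polynomial_taskset(4)
  set.seed(1); b <- sample_polynomial_taskset(4)
  expect_false(identical(a$shared_coeffs, b$shared_coeffs))

  set.seed(31)
  ts2 <- sample_polynomial_taskset(4, shared_scale = 2)
  expect_lte(max(abs(ts2$idio_coeffs)), 1)
  expect_error(sample_polynomial_taskset(4, x_range = c(1, 1)), "interval")
})

test_that("CIS noise flips bits at the requested rate", {
  set.seed(32)
  cis <- rbinom(128, 1, 0.5)
  expect_identical(make_noisy_cis(cis, 0), cis)
  expect_error(make_noisy_cis(c(0, 2, 1), 0.1), "0/1")
  expect_error(make_noisy_cis(cis, 0.5), "0.5")

  flips <- replicate(10000, sum(make_noisy_cis(cis, 0.1) != cis))
  # binomial mean 12.8, sd 3.394; the mean of 10^4 draws is very tight
  expect_lt(abs(mean(flips) - 12.8), 3 * sqrt(128 * 0.1 * 0.9) / sqrt(10000))
  expect_false(identical(make_noisy_cis(cis, 0.1), make_noisy_cis(cis, 0.1)))
})

test_that("schema graph paths match the two context structures", {
  expect_setequal(lapply(schema_paths(1), paste, collapse = "-"),
                  list("1-4-5", "2-3-6"))
  expect_setequal(lapply(schema_paths(2), paste, collapse = "-"),
                  list("1-3-5", "2-4-6"))
  expect_error(schema_paths(3), "1 or 2")
})

test_that("schema trials are walks on the declared graph with correct
           smoothing, foils, and inference mask", {
  set.seed(33)
  task <- schema_task(state_dim = 16, smoothing_weight = 0.7)
  for (rep in 1:50) {
    ctx <- sample(1:2, 1)
    tr <- sample_schema_trial(task, ctx)
    allowed <- vapply(schema_paths(ctx), paste, character(1), collapse = "-")
    expect_true(paste(tr$raw[-1], collapse = "-") %in% allowed)
    expect_equal(tr$raw[1], 6L + ctx)
    # smoothing identity
    V <- task$state_vectors[tr$raw, ]
    for (t in 2:4)
      expect_equal(tr$inputs[t, ], 0.7 * V[t, ] + 0.3 * V[t - 1, ])
    # targets are the next raw state vectors
    for (t in 1:3) expect_equal(tr$targets[t, ], V[t + 1, ])
    # the foil at each predictable step is the other context's successor
    other <- schema_paths(3 - ctx)
    succ_other <- function(s) {
      for (p in other) {
        i <- match(s, p)
        if (!is.na(i) && i < 3) return(p[i + 1])
      }
      NA_integer_
    }
    expect_equal(tr$foils[2, ],
                 task$state_vectors[succ_other(tr$raw[2]), ])
    # inference is disabled exactly at the opening-to-first-state transition
    expect_identical(tr$inference_mask, c(TRUE, FALSE, TRUE, TRUE))
    expect_identical(tr$predictable, c(FALSE, TRUE, TRUE, FALSE))
  }

  # degenerate smoothing: inputs equal the raw state vectors
  task1 <- schema_task(state_dim = 8, smoothing_weight = 1)
  tr <- sample_schema_trial(task1, 1)
  expect_equal(tr$inputs, task1$state_vectors[tr$raw, ],
               ignore_attr = TRUE)
  expect_error(sample_schema_trial(task, 3), "1 or 2")
})

test_that("curricula satisfy their definitions", {
  set.seed(34)
  cur <- make_curriculum("blocked", 8, 2)
  expect_equal(cur$context[cur$phase == "train"], c(1, 1, 1, 1, 2, 2, 2, 2))
  cur <- make_curriculum("interleaved", 8, 2)
  expect_equal(cur$context[cur$phase == "train"], c(1, 2, 1, 2, 1, 2, 1, 2))
  expect_error(make_curriculum("blocked", 7, 2), "even")

  for (n_train in c(2, 10, 100, 1000)) {
    b <- make_curriculum("blocked", n_train, 0)
    expect_true(all(diff(b$context) >= 0))
    expect_equal(sum(b$context == 1), n_train / 2)
    i <- make_curriculum("interleaved", n_train, 0)
    expect_true(all(abs(diff(i$context)) == 1))
  }

  frac <- mean(replicate(200, {
    mean(make_curriculum("blocked", 2, 100)$context[-(1:2)] == 1)
  }))
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(200 * 100))
})

test_that("the synthetic event corpus has persistent labels, geometric event
           lengths, and consistent boundaries", {
  set.seed(35)
  corp <- generate_event_corpus(n_videos = 20, n_classes = 4,
                                frames_per_video = 400, frame_dim = 6,
                                persistence = 0.95, n_subjects = 5)
  stay <- unlist(lapply(corp$labels, function(z) z[-1] == z[-length(z)]))
  p_hat <- mean(stay)
  expect_lt(abs(p_hat - 0.95), 3 * sqrt(0.95 * 0.05 / length(stay)))

  lens <- unlist(lapply(corp$labels, function(z) rle(z)$lengths))
  # censored geometric with mean 1/(1-p) = 20; generous band
  expect_lt(abs(mean(lens) - 20), 3 * 20 / sqrt(length(lens)) + 3)

  for (v in seq_along(corp$labels)) {
    z <- corp$labels[[v]]
    expect_identical(corp$boundaries[[v]],
                     c(0L, as.integer(z[-1] != z[-length(z)])))
    expect_true(all(corp$subject_prob[[v]] >= 0 &
                    corp$subject_prob[[v]] <= 1))
  }
  expect_error(generate_event_corpus(persistence = 1), "persistence")
})

test_that("with no observation noise and distant class centers a nearest
           centroid classifier recovers the labels", {
  set.seed(36)
  corp <- generate_event_corpus(n_videos = 2, n_classes = 2,
                                frames_per_video = 300, frame_dim = 10,
                                persistence = 0.98, obs_noise = 0,
                                process_noise = 0.1, class_scale = 8,
                                spectral_radius = 0.3)
  mu <- do.call(rbind, corp$class_means)
  for (v in 1:2) {
    d <- as.matrix(corp$frames[[v]])
    pred <- apply(d, 1, function(f)
      which.min(colSums((t(mu) - f)^2)))
    expect_equal(as.integer(pred), corp$labels[[v]])
  }
})

test_that("perfectly reliable annotators with zero jitter reproduce the true
           boundary indicator", {
  set.seed(37)
  corp <- generate_event_corpus(n_videos = 2, n_classes = 3,
                                frames_per_video = 200, frame_dim = 4,
                                persistence = 0.95, n_subjects = 20,
                                jitter_sd = 0, press_prob = 1)
  for (v in 1:2)
    expect_equal(corp$subject_prob[[v]], as.numeric(corp$boundaries[[v]]))
})

test_that("a corpus serializes to plain-text files with a manifest", {
  set.seed(38)
  corp <- generate_event_corpus(n_videos = 2, n_classes = 2,
                                frames_per_video = 20, frame_dim = 3,
                                persistence = 0.9, n_subjects = 3)
  dir <- tempfile()
  write_event_corpus(corp, dir)
  expect_true(file.exists(file.path(dir, "frames_1.csv")))
  ann <- read.csv(file.path(dir, "annotations.csv"))
  expect_equal(nrow(ann), 40)
  expect_setequal(names(ann),
                  c("video_id", "t", "label", "boundary", "subject_prob"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_videos, 2)
  unlink(dir, recursive = TRUE)
})
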