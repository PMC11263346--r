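test_that("context vectors are reproducible standard-normal draws", {
  set.seed(11)
  v1 <- sample_context_vector(3)
  set.seed(11)
  v2 <- sample_context_vector(3)
  expect_identical(v1, v2)
  expect_length(v1, 3)
  expect_error(sample_context_vector(0), "positive")

  set.seed(12)
  draws <- matrix(rnorm(0), 0, 0)
  x <- replicate(2000, sample_context_vector(16))
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(stats::var(as.numeric(x)) - 1), 0.05)
})

test_that("high-dimensional context vectors are near-orthogonal", {
  set.seed(13)
  cosines <- replicate(50, {
    a <- sample_context_vector(256)
    b <- sample_context_vector(256)
    abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  })
  expect_lt(max(cosines), 0.25)
  expect_lt(mean(cosines), 0.1)
})

test_that("sticky-CRP prior matches hand-computed probabilities", {
  set.seed(1)
  r <- lc_registry(4)
  p <- scrp_params(alpha = 0.7, stickiness = 1)
  # empty registry: all mass on the new cause
  expect_equal(scrp_prior(r, p), 1)

  r <- update_registry(r, 1)  # counts = 1, prev = 1
  r <- update_registry(r, 1)  # counts = 2
  pr <- scrp_prior(r, scrp_params(alpha = 0.5, stickiness = 1))
  expect_equal(pr, c((2 + 1) / 3.5, 0.5 / 3.5))

  # two causes, no previous cause, no stickiness: plain CRP thirds
  r2 <- lc_registry(4)
  r2 <- update_registry(r2, 1)
  r2 <- update_registry(r2, 2)
  r2$prev_lc <- NA_integer_
  expect_equal(scrp_prior(r2, scrp_params(alpha = 1, stickiness = 0)),
               rep(1 / 3, 3))

  expect_error(scrp_prior(lc_registry(4), scrp_params(alpha = 0)),
               "degenerate")
})

test_that("with zero stickiness the prior reduces to the plain CRP for all
           count configurations with total <= 5 and K <= 3", {
  set.seed(2)
  for (K in 1:3) {
    for (total in K:5) {
      for (counts in compositions(total, K)) {
        for (prev in c(NA_integer_, seq_len(K))) {
          r <- lc_registry(2)
          r$vectors <- matrix(rnorm(2 * K), 2, K)
          r$counts <- as.integer(counts)
          r$prev_lc <- prev
          for (alpha in c(0.3, 1, 2.5)) {
            expect_equal(scrp_prior(r, scrp_params(alpha, stickiness = 0)),
                         crp_oracle(counts, alpha), tolerance = 1e-12)
          }
        }
      }
    }
  }
})

test_that("increasing stickiness never decreases the previous cause's prior", {
  set.seed(3)
  for (rep in 1:20) {
    K <- sample(1:4, 1)
    r <- lc_registry(2)
    r$vectors <- matrix(rnorm(2 * K), 2, K)
    r$counts <- sample.int(6, K, replace = TRUE)
    r$prev_lc <- sample.int(K, 1)
    lams <- sort(runif(5, 0, 4))
    pr_prev <- vapply(lams, function(l)
      scrp_prior(r, scrp_params(0.5, l))[r$prev_lc], numeric(1))
    expect_true(all(diff(pr_prev) >= -1e-12))
  }
})

test_that("likelihood is softmax of negative scaled loss", {
  set.seed(4)
  r <- lc_registry(3)
  r <- update_registry(r, 1)
  r <- update_registry(r, 2)
  # constant predictor: all causes equally wrong, uniform likelihood
  res <- lc_likelihoods(function(xp, cv) c(0, 0), r, c(0, 0), c(1, 1), 1)
  expect_equal(res$likelihood, rep(1 / 3, 3))

  # losses 0 and 100 at temperature 1
  dummy <- lc_registry(1)
  dummy <- update_registry(dummy, 1)
  dummy$vectors <- matrix(0, 1, 1)
  dummy$candidate <- 10   # forces candidate loss 100 for the predictor below
  res <- lc_likelihoods(function(xp, cv) cv, dummy, 0, 0, 1)
  expect_equal(res$losses, c(0, 100))
  expect_equal(res$likelihood[1], 1, tolerance = 1e-10)
  expect_equal(res$likelihood[2], exp(-100), tolerance = 1e-12)

  # random two-cause setting against the brute-force softmax(-MSE) oracle
  for (rep in 1:20) {
    r <- lc_registry(5)
    r <- update_registry(r, 1)
    r <- update_registry(r, 2)
    x_prev <- rnorm(4); x_curr <- rnorm(4)
    W <- matrix(rnorm(20), 4, 5)
    pf <- function(xp, cv) drop(W %*% cv) + xp
    temp <- runif(1, 0.2, 2)
    res <- lc_likelihoods(pf, r, x_prev, x_curr, temp)
    preds <- list(pf(x_prev, r$vectors[, 1]), pf(x_prev, r$vectors[, 2]),
                  pf(x_prev, r$candidate))
    expect_equal(res$likelihood,
                 softmax_neg_mse_oracle(preds, x_curr, temp),
                 tolerance = 1e-12)
  }
})

test_that("posterior is renormalized prior times likelihood with low-index
           tie-breaking", {
  pm <- lc_posterior_map(c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(pm$posterior, c(0.9, 0.1))
  expect_equal(pm$map_lc, 1L)

  pm <- lc_posterior_map(c(1, 0), c(0.6, 0.4))
  expect_equal(pm$map_lc, 1L)

  # exact tie goes to the older (lower-index) cause
  pm <- lc_posterior_map(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(pm$map_lc, 1L)

  set.seed(5)
  for (rep in 1:25) {
    pr <- runif(4); pr <- pr / sum(pr)
    li <- runif(4); li <- li / sum(li)
    pm <- lc_posterior_map(pr, li)
    expect_equal(pm$posterior, bayes_oracle(pr, li), tolerance = 1e-12)
    expect_equal(pm$map_lc, which.max(bayes_oracle(pr, li)))
  }

  expect_error(lc_posterior_map(c(1, 0), c(0, 1)), "underflow")
  expect_error(lc_posterior_map(c(0.5, 0.5), c(0.5, 0.5, 0)), "length")
})

test_that("registry bookkeeping conserves counts and never rewrites vectors", {
  set.seed(6)
  r <- lc_registry(3)
  cand0 <- r$candidate
  r <- update_registry(r, 1)          # spawn first cause
  expect_equal(n_causes(r), 1L)
  expect_equal(r$counts, 1L)
  expect_equal(r$prev_lc, 1L)
  expect_identical(r$vectors[, 1], cand0)  # candidate adopted verbatim
  expect_false(identical(r$candidate, cand0))

  r <- update_registry(r, 2)          # spawn second
  r <- update_registry(r, 2)
  r <- update_registry(r, 1)
  expect_equal(r$counts, c(2L, 2L))
  expect_equal(r$prev_lc, 1L)
  expect_error(update_registry(r, 4), "1..K\\+1")

  v_before <- r$vectors
  for (i in 1:100) r <- update_registry(r, sample.int(n_causes(r) + 1L, 1))
  expect_equal(sum(r$counts), 104L)
  expect_identical(r$vectors[, 1:2], v_before)
})

test_that("infer_step spawns on an empty registry, carries when disabled, and
           errors on a disabled step with no history", {
  set.seed(7)
  p <- scrp_params(alpha = 0.5, stickiness = 1, temperature = 1,
                   context_dim = 3)
  r <- lc_registry(3)
  pf <- function(xp, cv) cv
  res <- infer_step(pf, r, p, NULL, NULL, TRUE)
  expect_true(res$trace$spawned_new)
  expect_equal(res$trace$map_lc, 1L)

  r <- res$registry
  r <- update_registry(r, 2)   # second cause active
  res <- infer_step(pf, r, p, rnorm(3), rnorm(3), inference_enabled = FALSE)
  expect_equal(res$trace$map_lc, 2L)
  expect_false(res$trace$inference)
  expect_equal(res$registry$counts[2], 2L)  # carried cause still counted

  expect_error(infer_step(pf, lc_registry(3), p, NULL, NULL,
                          inference_enabled = FALSE),
               "no previously active cause")
})

test_that("a three-segment stream with distinct contexts is segmented with
           perfect purity at a verified operating point", {
  set.seed(1)
  mus <- list(rep(0, 6), rep(4, 6), rep(-4, 6))
  x <- do.call(rbind, lapply(mus, function(m)
    matrix(rnorm(40 * 6, mean = rep(m, each = 40), sd = 0.02), 40)))
  fit <- lcnet(x, architecture = "feedforward", context_dim = 8,
               hidden_dim = 16, alpha = 8, stickiness = 1,
               temperature = 0.5, learning_rate = 0.1, seed = 1001)
  expect_equal(cluster_purity(fit$trace$map_lc, rep(1:3, each = 40)), 1.0)
})
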