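test_that("feedforward pass matches an elementwise oracle and the lesion
           removes exactly the context term", {
  set.seed(21)
  for (rep in 1:10) {
    net <- ff_net(input_dim = 3, context_dim = 5, output_dim = 2,
                  hidden_dim = 7)
    x <- rnorm(3); cv <- rnorm(5)
    expect_equal(ff_forward(net, x, cv), ff_oracle(net, x, cv),
                 tolerance = 1e-6)
    # zero context weights: lesioned and unlesioned coincide
    net0 <- net
    net0$W_ctx[] <- 0
    expect_identical(ff_forward(net0, x, cv),
                     ff_forward(net0, x, cv, lesioned = TRUE))
    # zero context vector contributes nothing
    expect_equal(ff_forward(net, x, rep(0, 5)),
                 ff_forward(net, x, cv, lesioned = TRUE))
  }
  net <- ff_net(2, 2, 1)
  expect_error(ff_forward(net, c(1, 2, 3), c(0, 0)), "dimension")
  expect_error(ff_forward(net, c(1, 2), c(0, 0, 0)), "dimension")
})

test_that("feedforward training step follows the analytic gradient", {
  set.seed(22)
  net <- ff_net(input_dim = 2, context_dim = 3, output_dim = 2,
                hidden_dim = 2)
  x <- rnorm(2); cv <- rnorm(3); target <- rnorm(2)
  loss_fn <- function(n) mean((ff_forward(n, x, cv) - target)^2)
  lr <- 0.37
  st <- train_step(net, x, cv, target, learning_rate = lr)
  expect_equal(st$loss, loss_fn(net))
  for (nm in c("W_in", "W_ctx", "W_out")) {
    for (i in seq_len(nrow(net[[nm]]))) {
      for (j in seq_len(ncol(net[[nm]]))) {
        g <- (net[[nm]][i, j] - st$net[[nm]][i, j]) / lr
        expect_equal(g, fd_grad(loss_fn, net, nm, i, j), tolerance = 1e-5)
      }
    }
  }
  for (nm in c("b_h", "b_out")) {
    for (i in seq_along(net[[nm]])) {
      g <- (net[[nm]][i] - st$net[[nm]][i]) / lr
      expect_equal(g, fd_grad(loss_fn, net, nm, i), tolerance = 1e-5)
    }
  }
})

test_that("training is a fixed point at zero error and converges on one
           example", {
  set.seed(23)
  net <- ff_net(1, 2, 1, hidden_dim = 8)
  x <- 0.3; cv <- rnorm(2)
  y0 <- ff_forward(net, x, cv)
  st <- train_step(net, x, cv, y0, learning_rate = 0.1)
  expect_equal(st$loss, 0)
  expect_identical(st$net$W_in, net$W_in)
  expect_identical(st$net$W_out, net$W_out)

  target <- 1.7
  losses <- numeric(200)
  for (i in 1:200) {
    st <- train_step(net, x, cv, target, learning_rate = 0.1)
    net <- st$net
    losses[i] <- st$loss
  }
  expect_lt(losses[200], 1e-4)
  expect_true(all(diff(losses) <= 1e-8))
})

test_that("GRU step obeys the gate equations", {
  set.seed(24)
  for (rep in 1:10) {
    net <- gru_net(input_dim = 3, context_dim = 2, output_dim = 3,
                   hidden_dim = 4)
    x <- rnorm(3); cv <- rnorm(2); h0 <- rnorm(4) * 0.5
    expect_equal(gru_step(net, x, cv, h0), gru_oracle(net, x, cv, h0),
                 tolerance = 1e-6)
    # interpolation bound: h between h_prev and the candidate state
    sig <- function(v) 1 / (1 + exp(-v))
    a <- c(h0, x, cv)
    r <- sig(drop(net$W_r %*% a) + net$b_r)
    h_cand <- tanh(drop(net$W_h %*% c(r * h0, x, cv)) + net$b_h)
    h <- gru_step(net, x, cv, h0)
    expect_true(all(h >= pmin(h0, h_cand) - 1e-12))
    expect_true(all(h <= pmax(h0, h_cand) + 1e-12))
  }

  # saturated update gate: full retention vs complete overwrite
  net <- gru_net(2, 0, 2, hidden_dim = 3)
  x <- rnorm(2); h0 <- rnorm(3) * 0.3
  net$b_z <- rep(-50, 3)
  expect_equal(gru_step(net, x, NULL, h0), h0, tolerance = 1e-12)
  net$b_z <- rep(50, 3)
  sig <- function(v) 1 / (1 + exp(-v))
  r <- sig(drop(net$W_r %*% c(h0, x)) + net$b_r)
  h_cand <- tanh(drop(net$W_h %*% c(r * h0, x)) + net$b_h)
  expect_equal(gru_step(net, x, NULL, h0), h_cand, tolerance = 1e-12)

  expect_error(gru_step(net, c(1, 2, 3), NULL, h0), "dimension")
})

test_that("GRU training step follows the truncated analytic gradient", {
  set.seed(25)
  net <- gru_net(input_dim = 2, context_dim = 2, output_dim = 2,
                 hidden_dim = 3)
  x <- rnorm(2); cv <- rnorm(2); h0 <- rnorm(3) * 0.4; target <- rnorm(2)
  loss_fn <- function(n) {
    fw <- gru_forward(n, x, cv, h0)
    mean((fw$output - target)^2)
  }
  lr <- 0.21
  st <- train_step(net, x, cv, target, learning_rate = lr, h_prev = h0)
  expect_equal(st$loss, loss_fn(net))
  expect_equal(st$h, gru_step(net, x, cv, h0))
  for (nm in c("W_z", "W_r", "W_h", "W_out")) {
    nr <- nrow(net[[nm]]); nc <- ncol(net[[nm]])
    idx <- rbind(c(1, 1), c(nr, nc), c(1, nc), c(nr, 1))
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      g <- (net[[nm]][i, j] - st$net[[nm]][i, j]) / lr
      expect_equal(g, fd_grad(loss_fn, net, nm, i, j), tolerance = 1e-5)
    }
  }
  for (nm in c("b_z", "b_r", "b_h", "b_out")) {
    for (i in seq_along(net[[nm]])) {
      g <- (net[[nm]][i] - st$net[[nm]][i]) / lr
      expect_equal(g, fd_grad(loss_fn, net, nm, i), tolerance = 1e-5)
    }
  }
})

test_that("the context-gradient multiplier scales exactly the context
           columns", {
  set.seed(26)
  net <- gru_net(2, 3, 2, hidden_dim = 3)
  x <- rnorm(2); cv <- rnorm(3); h0 <- rnorm(3) * 0.3; target <- rnorm(2)
  s1 <- train_step(net, x, cv, target, learning_rate = 0.1, h_prev = h0)
  s5 <- train_step(net, x, cv, target, learning_rate = 0.1, h_prev = h0,
                   ctx_grad_mult = 5)
  ctx_cols <- 3 + 2 + 1:3
  other <- seq_len(ncol(net$W_z))[-ctx_cols]
  expect_equal(s5$net$W_z[, other], s1$net$W_z[, other])
  d1 <- net$W_z[, ctx_cols] - s1$net$W_z[, ctx_cols]
  d5 <- net$W_z[, ctx_cols] - s5$net$W_z[, ctx_cols]
  expect_equal(d5, 5 * d1, tolerance = 1e-12)
})

test_that("expert ensembles spawn, reuse, and isolate gradients", {
  set.seed(27)
  ens <- sem_ensemble(function() ff_net(1, 0, 1, hidden_dim = 6))
  sel <- sem_select_or_spawn(ens, 1)
  expect_length(sel$ensemble$experts, 1)
  ens <- sel$ensemble
  sel <- sem_select_or_spawn(ens, 2)
  sel$ensemble <- sem_set_expert(sel$ensemble, 2, sel$expert)
  ens <- sel$ensemble
  expect_length(ens$experts, 2)

  sel <- sem_select_or_spawn(ens, 2)
  expect_length(sel$ensemble$experts, 2)

  expect_error(sem_select_or_spawn(ens, 4), "no gaps")

  # training expert 1 leaves expert 2 bit-identical
  e2_before <- ens$experts[[2]]
  sel <- sem_select_or_spawn(ens, 1)
  for (i in 1:50) {
    st <- train_step(sel$expert, runif(1), NULL, 1, learning_rate = 0.05)
    sel$expert <- st$net
  }
  ens <- sem_set_expert(sel$ensemble, 1, sel$expert)
  expect_identical(ens$experts[[2]], e2_before)
  expect_false(identical(ens$experts[[1]], e2_before))
})

test_that("network checkpoints round-trip exactly through JSON", {
  set.seed(28)
  for (net in list(ff_net(3, 4, 2, hidden_dim = 5),
                   gru_net(3, 2, 3, hidden_dim = 4))) {
    path <- tempfile(fileext = ".json")
    write_network(net, path)
    back <- read_network(path)
    expect_identical(class(back), class(net))
    for (nm in names(net)) expect_equal(back[[nm]], net[[nm]],
                                        tolerance = 0, label = nm)
    unlink(path)
  }
})

test_that("same seed and data give bit-identical networks", {
  run_once <- function() {
    set.seed(29)
    net <- gru_net(2, 2, 2, hidden_dim = 3)
    h <- numeric(3)
    for (i in 1:30) {
      st <- train_step(net, rnorm(2), rnorm(2), rnorm(2),
                       learning_rate = 0.05, h_prev = h)
      net <- st$net; h <- st$h
    }
    net
  }
  expect_identical(run_once(), run_once())
})
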