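test_that("the Euler step is consistent with the continuous rectified RHS", {
  w <- cell_weights(n = 3, m = 3, n_classes = 2, dt = 1e-4, tau = 4, seed = 5,
                    dynamic_gains = FALSE, learn_tau = FALSE)
  w$W_zx <- diag(3)
  st <- list(y = c(0.3, -0.2, 0.1), a = c(0.4, 0.1, 0.2),
             b = w$b_init, b0 = w$b0_init)
  x <- c(1, 0.5, -0.3)
  nxt <- cell_step(st, x, w)
  p <- organics_params(n = 3, tau_y = 4, tau_a = 4, b = w$b_init,
                       b0 = w$b0_init, sigma = w$sigma, W_r = w$W_r, W = w$W)
  d <- rhs_rectified(organics_state(st$y, st$a), p, x)
  expect_equal((nxt$y - st$y) / 1e-4, d$dy, tolerance = 1e-8)
  expect_equal((nxt$a - st$a) / 1e-4, d$da, tolerance = 1e-8)
})

test_that("with zero gain weights the gains relax geometrically to f(0)", {
  w <- cell_weights(n = 2, m = 1, n_classes = 2, dt = 1, tau = 6, seed = 8)
  for (nm in c("W_bx", "W_by", "W_ba", "W_b0x", "W_b0y", "W_b0a")) {
    w[[nm]][] <- 0
  }
  w$W_zx[] <- 0
  st <- list(y = c(0, 0), a = c(0, 0), b = c(0.9, 0.2), b0 = w$b0_init)
  s1 <- cell_step(st, 0, w)
  kb <- (s1$b - st$b) / (0.5 - st$b) # infer dt/tau_b from the first step
  b_expect <- s1$b
  st <- s1
  for (t in 1:6) {
    st <- cell_step(st, 0, w)
    b_expect <- b_expect + kb * (0.5 - b_expect)
    expect_equal(st$b, b_expect, tolerance = 1e-12)
  }
})

test_that("a frozen-gain rollout reproduces the continuous rectified model", {
  w <- cell_weights(n = 3, m = 3, n_classes = 2, dt = 0.05, tau = 4, seed = 3,
                    dynamic_gains = FALSE, learn_tau = FALSE)
  w$W_zx <- diag(3)
  x <- c(0.5, -0.2, 0.8)
  p <- organics_params(n = 3, tau_y = 4, tau_a = 4, b = w$b_init,
                       b0 = w$b0_init, sigma = w$sigma, W_r = w$W_r, W = w$W)
  init <- list(y = c(0.1, 0.02, 0.05), a = c(0.1, 0.08, 0.02),
               b = w$b_init, b0 = w$b0_init)
  tr <- simulate_circuit(p, x, organics_state(init$y, init$a), dt = 0.05,
                         t_end = 20, method = "euler", variant = "rectified",
                         record_every = 400)
  st <- init
  for (k in 1:400) st <- cell_step(st, x, w)
  fs <- final_state(tr)
  expect_equal(st$y, fs$y, tolerance = 1e-12)
  expect_equal(st$a, fs$a, tolerance = 1e-12)

  # ... and the rollout endpoint approaches the rectified steady state
  fps <- fixed_point_iteration(p, x, tol = 1e-10)
  if (all(fps$y_s >= 0)) {
    expect_lt(max(abs(st$y - fps$y_s)), 1e-3)
  }
})

test_that("sequence runs are thin wrappers with deterministic readout", {
  w <- cell_weights(n = 4, m = 2, n_classes = 3, seed = 21)
  x1 <- matrix(c(0.5, -0.5), 2, 1)

  # a length-1 sequence is one step plus readout
  init <- cell_init_state(w, 1, "zero")
  out <- run_sequence(x1, w, init = lapply(init, drop))
  manual <- cell_step(lapply(init, drop), x1[, 1], w)
  expect_equal(out$state$y, manual$y)
  expect_equal(out$logits, drop(w$W_out %*% manual$y + w$b_out))

  # zero readout means zero logits
  w0 <- w
  w0$W_out[] <- 0
  w0$b_out[] <- 0
  xs <- matrix(rnorm(2 * 6), 2, 6)
  expect_equal(run_sequence(xs, w0, init = "uniform", seed = 4)$logits,
               c(0, 0, 0))

  # seeded uniform initialization is bitwise reproducible
  o1 <- run_sequence(xs, w, init = "uniform", seed = 7)
  o2 <- run_sequence(xs, w, init = "uniform", seed = 7)
  expect_identical(o1$logits, o2$logits)
})

test_that("reverse-mode gradients match central finite differences", {
  w <- cell_weights(n = 4, m = 3, n_classes = 3, dt = 1, tau = 5, seed = 7)
  set.seed(42)
  X <- matrix(rnorm(3 * 6), 3, 6) # 6 steps so every path reaches the loss
  labels <- 2L
  init <- withr::with_seed(9, cell_init_state(w, 1, "uniform"))
  g <- cell_gradients(w, X, labels, init = init)
  loss_of <- function(w) cell_gradients(w, X, labels, init = init)$loss
  h <- 1e-6
  for (nm in names(g$grads)) {
    w_dim <- if (is.matrix(w[[nm]])) dim(w[[nm]]) else c(length(w[[nm]]), 1)
    i <- min(2, w_dim[1])
    j <- min(2, w_dim[2])
    wp <- w
    wm <- w
    if (is.matrix(w[[nm]])) {
      wp[[nm]][i, j] <- wp[[nm]][i, j] + h
      wm[[nm]][i, j] <- wm[[nm]][i, j] - h
      ga <- g$grads[[nm]][i, j]
    } else {
      wp[[nm]][i] <- wp[[nm]][i] + h
      wm[[nm]][i] <- wm[[nm]][i] - h
      ga <- g$grads[[nm]][i]
    }
    fd <- (loss_of(wp) - loss_of(wm)) / (2 * h)
    expect_lt(abs(ga - fd) / max(abs(fd), 1e-6), 1e-4, label = nm)
  }
})

test_that("gradient norms stay bounded over a 64-step rollout", {
  w <- cell_weights(n = 16, m = 5, n_classes = 4, seed = 12)
  set.seed(12)
  X <- lapply(1:64, function(t) matrix(rnorm(5 * 8, sd = 0.5), 5, 8))
  labels <- sample.int(4, 8, replace = TRUE)
  init <- withr::with_seed(13, cell_init_state(w, 8, "uniform"))
  g <- cell_gradients(w, X, labels, init = init)
  expect_gt(g$grad_norm, 1e-8)
  expect_lt(g$grad_norm, 1e4)
})

test_that("a zero learning rate leaves the loss constant", {
  tt <- train_toy("sequence-sum-sign", steps = 5, lr = 0, seed = 1,
                  n = 6, seq_len = 8, n_examples = 64, batch_size = 64)
  expect_equal(tt$initial_loss, tt$final_loss)
})

test_that("updates are the raw scaled gradients - no clipping in the path", {
  seen <- list()
  hook <- function(step, grads, updates) {
    seen[[length(seen) + 1]] <<- vapply(names(grads), function(nm) {
      max(abs(updates[[nm]] + 0.1 * grads[[nm]]))
    }, numeric(1))
  }
  train_toy("sequence-sum-sign", steps = 3, lr = 0.1, seed = 2,
            n = 6, seq_len = 8, n_examples = 64, batch_size = 16,
            update_hook = hook)
  expect_length(seen, 3)
  expect_true(all(unlist(seen) == 0))
})

test_that("toy datasets are reproducible and balanced enough to learn", {
  d1 <- make_toy_task("delayed-recall", n_examples = 50, seq_len = 16, seed = 3)
  d2 <- make_toy_task("delayed-recall", n_examples = 50, seq_len = 16, seed = 3)
  expect_identical(d1, d2)
  expect_equal(dim(d1$X), c(5, 16, 50))
  expect_true(all(sort(unique(d1$labels)) %in% 1:4))
  ds <- make_toy_task("sequence-sum-sign", n_examples = 200, seq_len = 16, seed = 3)
  expect_gt(mean(ds$labels == 1), 0.3)
  expect_lt(mean(ds$labels == 1), 0.7)
})
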