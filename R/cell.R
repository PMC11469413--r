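sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# time constants are reparameterized as tau = dt + softplus(theta), so a
# learned tau can never drop below the integration step
tau_from_theta <- function(theta, dt) dt + softplus(theta)
theta_from_tau <- function(tau, dt) {
  x <- tau - dt
  stopifnot(all(x > 0))
  ifelse(x > 30, x, log(expm1(x)))
}

#' Initialize weights for the discrete-time circuit cell
#'
#' The cell is an explicit-Euler discretization of the rectified-variant
#' circuit in which the input gains `b` and `b0` are themselves dynamic
#' states, relaxing with their own time constants toward a logistic
#' function of learned projections of the input and the circuit state.
#' The logistic keeps the gains positive and bounded in `(0, 1)`,
#' matching the `1 - max(a,0)` recurrent-gain convention.
#'
#' Learnable tensors: input encoder `W_zx`, recurrent weights `W_r`
#' (initialized at the identity, the regime with a proven stability
#' certificate), the six gain projections, the class readout, and —
#' when `learn_tau = TRUE` — the four time-constant vectors through a
#' softplus reparameterization bounded below by `dt`. The normalization
#' pool `W` (uniform, `1/n`) and semisaturation `sigma` are fixed
#' buffers, which keeps `W >= 0` without constrained optimization.
#'
#' @param n Number of principal/modulator neurons.
#' @param m Input dimension per time step.
#' @param n_classes Readout classes.
#' @param dt Integration step (ms).
#' @param tau Initial value for all four time constants (ms), `> dt`.
#' @param sigma Fixed semisaturation constant.
#' @param learn_tau Make the time constants learnable.
#' @param dynamic_gains When `FALSE`, `b` and `b0` are frozen at their
#'   initial value and the cell is a pure Euler discretization of the
#'   rectified continuous model.
#' @param seed Seed for the weight initialization.
#' @return An `organics_cell` weight list.
#' @export
cell_weights <- function(n, m, n_classes, dt = 1, tau = 8, sigma = 0.5,
                         learn_tau = TRUE, dynamic_gains = TRUE, seed = 1) {
  stopifnot(tau > dt)
  withr::with_seed(seed, {
    rmat <- function(r, c, scale) matrix(stats::rnorm(r * c) * scale, r, c)
    w <- list(
      n = n, m = m, n_classes = n_classes, dt = dt,
      sigma = rep(sigma, n),
      W = matrix(1 / n, n, n),
      b_init = rep(0.5, n), b0_init = rep(0.5, n),
      learn_tau = learn_tau, dynamic_gains = dynamic_gains,
      theta_tau_y = theta_from_tau(rep(tau, n), dt),
      theta_tau_a = theta_from_tau(rep(tau, n), dt),
      theta_tau_b = theta_from_tau(rep(tau, n), dt),
      theta_tau_b0 = theta_from_tau(rep(tau, n), dt),
      W_zx = rmat(n, m, 1 / sqrt(m)),
      W_r = diag(n),
      W_bx = rmat(n, m, 0.1 / sqrt(m)),
      W_by = rmat(n, n, 0.1 / sqrt(n)),
      W_ba = rmat(n, n, 0.1 / sqrt(n)),
      W_b0x = rmat(n, m, 0.1 / sqrt(m)),
      W_b0y = rmat(n, n, 0.1 / sqrt(n)),
      W_b0a = rmat(n, n, 0.1 / sqrt(n)),
      W_out = rmat(n_classes, n, 1 / sqrt(n)),
      b_out = rep(0, n_classes)
    )
    class(w) <- "organics_cell"
    w
  })
}

learnable_names <- function(w) {
  nm <- c("W_zx", "W_r", "W_bx", "W_by", "W_ba", "W_b0x", "W_b0y", "W_b0a",
          "W_out", "b_out")
  if (w$learn_tau) {
    nm <- c(nm, "theta_tau_y", "theta_tau_a", "theta_tau_b", "theta_tau_b0")
  }
  nm
}

cell_taus <- function(w) {
  list(
    tau_y = tau_from_theta(w$theta_tau_y, w$dt),
    tau_a = tau_from_theta(w$theta_tau_a, w$dt),
    tau_b = tau_from_theta(w$theta_tau_b, w$dt),
    tau_b0 = tau_from_theta(w$theta_tau_b0, w$dt)
  )
}

# One Euler step for a batch. States are n x B matrices; x is m x B.
# Returns the new state plus the cache needed for the backward pass.
cell_step_batch <- function(st, x, w, keep_cache = FALSE) {
  tau <- cell_taus(w)
  ky <- w$dt / tau$tau_y
  ka <- w$dt / tau$tau_a
  Y <- st$y; A <- st$a; B <- st$b; B0 <- st$b0
  Z <- w$W_zx %*% x
  Yr <- pmax(Y, 0)
  Ar <- pmax(A, 0)
  Ry <- w$W_r %*% Yr
  Uy <- -Y + B * Z + (1 - Ar) * Ry
  Garg <- B0^2 * w$sigma^2 + w$W %*% (Y^2 * Ar^2)
  S <- sqrt(Garg)
  Ua <- -A + S
  Ynew <- Y + ky * Uy
  Anew <- A + ka * Ua
  if (w$dynamic_gains) {
    kb <- w$dt / tau$tau_b
    kb0 <- w$dt / tau$tau_b0
    Hb <- w$W_bx %*% x + w$W_by %*% Y + w$W_ba %*% A
    Hb0 <- w$W_b0x %*% x + w$W_b0y %*% Y + w$W_b0a %*% A
    Fb <- sigmoid(Hb)
    Fb0 <- sigmoid(Hb0)
    Ub <- -B + Fb
    Ub0 <- -B0 + Fb0
    Bnew <- B + kb * Ub
    B0new <- B0 + kb0 * Ub0
  } else {
    Fb <- Fb0 <- Ub <- Ub0 <- NULL
    Bnew <- B
    B0new <- B0
  }
  if (!all(is.finite(Ynew), is.finite(Anew), is.finite(Bnew), is.finite(B0new))) {
    stop("non-finite state in cell step")
  }
  out <- list(state = list(y = Ynew, a = Anew, b = Bnew, b0 = B0new))
  if (keep_cache) {
    out$cache <- list(Y = Y, A = A, B = B, B0 = B0, x = x, Z = Z, Yr = Yr,
                      Ar = Ar, Ry = Ry, S = S, Fb = Fb, Fb0 = Fb0,
                      Uy = Uy, Ua = Ua, Ub = Ub, Ub0 = Ub0)
  }
  out
}

#' One discrete update of the circuit cell
#'
#' Applies the explicit-Euler update to a single (unbatched) cell state.
#' All four state variables are updated simultaneously from the state at
#' the current step; rectifications use subgradient 0 at the corner, so
#' every operation in the step is differentiable in the sense used by the
#' backward pass.
#'
#' @param state A list with numeric vectors `y`, `a`, `b`, `b0` (length
#'   `n`).
#' @param x_t Input vector at this step (length `m`).
#' @param weights An `organics_cell` from [cell_weights()].
#' @return The updated state list.
#' @export
cell_step <- function(state, x_t, weights) {
  st <- lapply(state[c("y", "a", "b", "b0")], function(v) matrix(v, ncol = 1))
  out <- cell_step_batch(st, matrix(x_t, ncol = 1), weights)$state
  lapply(out, drop)
}

#' Initial cell state
#'
#' Hidden potentials `y` and `a` start uniform on `[0, 0.1]`
#' (`policy = "uniform"`) or at zero; the gain states start at their
#' fixed initial value (0.5, the logistic midpoint).
#'
#' @param weights An `organics_cell`.
#' @param batch Number of columns (sequences) in the state matrices.
#' @param policy `"uniform"` or `"zero"`.
#' @return A list of `n x batch` matrices `y`, `a`, `b`, `b0`.
#' @export
cell_init_state <- function(weights, batch = 1, policy = c("uniform", "zero")) {
  policy <- match.arg(policy)
  n <- weights$n
  init <- function() {
    if (policy == "uniform") matrix(stats::runif(n * batch, 0, 0.1), n, batch)
    else matrix(0, n, batch)
  }
  list(y = init(), a = init(),
       b = matrix(weights$b_init, n, batch),
       b0 = matrix(weights$b0_init, n, batch))
}

#' Run the cell over an input sequence
#'
#' Iterates [cell_step()] over the columns of `x_seq` and reads out class
#' logits from the final principal state.
#'
#' @param x_seq `m x T` input matrix (one column per time step).
#' @param weights An `organics_cell`.
#' @param init Initial state as returned by [cell_init_state()] (vectors
#'   or single-column matrices), or a policy name passed on to it.
#' @param seed Optional seed making a `"uniform"` initialization
#'   reproducible.
#' @return A list with the final `state` and the `logits` vector.
#' @export
run_sequence <- function(x_seq, weights, init = "zero", seed = NULL) {
  x_seq <- as.matrix(x_seq)
  stopifnot(ncol(x_seq) >= 1, nrow(x_seq) == weights$m)
  if (is.character(init)) {
    init <- if (is.null(seed)) {
      cell_init_state(weights, 1, init)
    } else {
      withr::with_seed(seed, cell_init_state(weights, 1, init))
    }
  } else {
    init <- lapply(init[c("y", "a", "b", "b0")], function(v) matrix(v, ncol = 1))
  }
  st <- init
  for (t in seq_len(ncol(x_seq))) {
    st <- cell_step_batch(st, x_seq[, t, drop = FALSE], weights)$state
  }
  logits <- drop(weights$W_out %*% st$y + weights$b_out)
  list(state = lapply(st, drop), logits = logits)
}

# Forward + (optionally) reverse-mode gradients through the unrolled cell.
# X: list of T matrices (m x B); labels: integer vector length B.
cell_forward_backward <- function(w, X, labels, init, compute_grads = TRUE) {
  Tn <- length(X)
  B <- ncol(X[[1]])
  st <- init
  caches <- if (compute_grads) vector("list", Tn)
  for (t in seq_len(Tn)) {
    out <- cell_step_batch(st, X[[t]], w, keep_cache = compute_grads)
    if (compute_grads) caches[[t]] <- out$cache
    st <- out$state
  }
  logits <- w$W_out %*% st$y + w$b_out
  lm <- apply(logits, 2, max)
  P <- exp(sweep(logits, 2, lm))
  P <- sweep(P, 2, colSums(P), "/")
  loss <- -mean(log(pmax(P[cbind(labels, seq_len(B))], 1e-300)))
  acc <- mean(apply(logits, 2, which.max) == labels)
  res <- list(loss = loss, accuracy = acc, final_state = st)
  if (!compute_grads) return(res)

  onehot <- matrix(0, w$n_classes, B)
  onehot[cbind(labels, seq_len(B))] <- 1
  dlogits <- (P - onehot) / B
  g <- list(
    W_out = dlogits %*% t(st$y), b_out = rowSums(dlogits),
    W_zx = matrix(0, w$n, w$m), W_r = matrix(0, w$n, w$n),
    W_bx = matrix(0, w$n, w$m), W_by = matrix(0, w$n, w$n),
    W_ba = matrix(0, w$n, w$n),
    W_b0x = matrix(0, w$n, w$m), W_b0y = matrix(0, w$n, w$n),
    W_b0a = matrix(0, w$n, w$n),
    theta_tau_y = rep(0, w$n), theta_tau_a = rep(0, w$n),
    theta_tau_b = rep(0, w$n), theta_tau_b0 = rep(0, w$n)
  )
  tau <- cell_taus(w)
  ky <- w$dt / tau$tau_y
  ka <- w$dt / tau$tau_a
  kb <- w$dt / tau$tau_b
  kb0 <- w$dt / tau$tau_b0
  # d(dt/tau)/d(theta) for the softplus reparameterization
  dk_dth <- function(k, theta, tau_v) -(k / tau_v) * sigmoid(theta)

  GY <- t(w$W_out) %*% dlogits
  GA <- matrix(0, w$n, B)
  GB <- matrix(0, w$n, B)
  GB0 <- matrix(0, w$n, B)
  for (t in rev(seq_len(Tn))) {
    cc <- caches[[t]]
    GUy <- ky * GY
    GUa <- ka * GA
    GGarg <- GUa * (0.5 / cc$S)
    P2 <- t(w$W) %*% GGarg
    indY <- (cc$Y > 0)
    indA <- (cc$A > 0)
    nGY <- GY - GUy +
      indY * (t(w$W_r) %*% ((1 - cc$Ar) * GUy)) +
      2 * cc$Y * cc$Ar^2 * P2
    nGA <- GA - GUa +
      indA * (2 * cc$Ar * cc$Y^2 * P2) -
      indA * cc$Ry * GUy
    decay_b <- if (w$dynamic_gains) (1 - kb) else 1
    decay_b0 <- if (w$dynamic_gains) (1 - kb0) else 1
    nGB <- GB * decay_b + cc$Z * GUy
    nGB0 <- GB0 * decay_b0 + 2 * cc$B0 * w$sigma^2 * GGarg
    g$W_r <- g$W_r + ((1 - cc$Ar) * GUy) %*% t(cc$Yr)
    g$W_zx <- g$W_zx + (cc$B * GUy) %*% t(cc$x)
    if (w$learn_tau) {
      g$theta_tau_y <- g$theta_tau_y +
        rowSums(GY * cc$Uy) * dk_dth(ky, w$theta_tau_y, tau$tau_y)
      g$theta_tau_a <- g$theta_tau_a +
        rowSums(GA * cc$Ua) * dk_dth(ka, w$theta_tau_a, tau$tau_a)
    }
    if (w$dynamic_gains) {
      GHb <- (kb * GB) * cc$Fb * (1 - cc$Fb)
      GHb0 <- (kb0 * GB0) * cc$Fb0 * (1 - cc$Fb0)
      nGY <- nGY + t(w$W_by) %*% GHb + t(w$W_b0y) %*% GHb0
      nGA <- nGA + t(w$W_ba) %*% GHb + t(w$W_b0a) %*% GHb0
      g$W_bx <- g$W_bx + GHb %*% t(cc$x)
      g$W_by <- g$W_by + GHb %*% t(cc$Y)
      g$W_ba <- g$W_ba + GHb %*% t(cc$A)
      g$W_b0x <- g$W_b0x + GHb0 %*% t(cc$x)
      g$W_b0y <- g$W_b0y + GHb0 %*% t(cc$Y)
      g$W_b0a <- g$W_b0a + GHb0 %*% t(cc$A)
      if (w$learn_tau) {
        g$theta_tau_b <- g$theta_tau_b +
          rowSums(GB * cc$Ub) * dk_dth(kb, w$theta_tau_b, tau$tau_b)
        g$theta_tau_b0 <- g$theta_tau_b0 +
          rowSums(GB0 * cc$Ub0) * dk_dth(kb0, w$theta_tau_b0, tau$tau_b0)
      }
    }
    GY <- nGY
    GA <- nGA
    GB <- nGB
    GB0 <- nGB0
  }
  res$grads <- g[learnable_names(w)]
  res$grad_norm <- sqrt(sum(vapply(res$grads, function(m) sum(m^2), numeric(1))))
  res
}

#' Loss and gradients for a batch of sequences
#'
#' Exposes the cell's reverse-mode gradient computation directly, mainly
#' for validation against finite differences.
#'
#' @param weights An `organics_cell`.
#' @param X A list of `m x B` input matrices, one per time step (a single
#'   `m x T` matrix is treated as one sequence, `B = 1`).
#' @param labels Integer class labels, length `B`.
#' @param init Initial state matrices (see [cell_init_state()]); zero
#'   state by default.
#' @return A list with `loss`, `accuracy`, `grads` (named by learnable
#'   tensor) and `grad_norm`.
#' @export
cell_gradients <- function(weights, X, labels, init = NULL) {
  if (is.matrix(X)) {
    X <- lapply(seq_len(ncol(X)), function(t) X[, t, drop = FALSE])
  }
  if (is.null(init)) init <- cell_init_state(weights, ncol(X[[1]]), "zero")
  cell_forward_backward(weights, X, labels, init, compute_grads = TRUE)
}

#' Synthetic sequence-classification tasks
#'
#' Generates small fully synthetic datasets for exercising the trainer:
#'
#' * `"delayed-recall"` — one of 4 symbols is presented (one-hot, held
#'   for the first 3 steps) on dedicated channels, followed by Gaussian
#'   distractor noise on a separate channel; the class is the symbol, so
#'   the cell must retain the cue across the delay.
#' * `"sequence-sum-sign"` — a scalar Gaussian sequence; the class is the
#'   sign of its sum, requiring integration over the whole sequence.
#'
#' @param task Task name.
#' @param n_examples Number of sequences.
#' @param seq_len Sequence length (time steps).
#' @param seed Seed for generation.
#' @return A list: `X` (array `m x seq_len x n_examples`), `labels`,
#'   `m`, `n_classes`, `task`.
#' @export
make_toy_task <- function(task = c("delayed-recall", "sequence-sum-sign"),
                          n_examples = 2000, seq_len = 32, seed = 0) {
  task <- match.arg(task)
  withr::with_seed(seed, {
    if (task == "delayed-recall") {
      k <- 4
      m <- k + 1
      X <- array(0, c(m, seq_len, n_examples))
      labels <- sample.int(k, n_examples, replace = TRUE)
      for (i in seq_len(n_examples)) {
        X[labels[i], 1:3, i] <- 1
        X[m, , i] <- stats::rnorm(seq_len, sd = 0.3)
      }
      list(X = X, labels = labels, m = m, n_classes = k, task = task)
    } else {
      X <- array(stats::rnorm(seq_len * n_examples) / sqrt(seq_len),
                 c(1, seq_len, n_examples))
      labels <- ifelse(apply(X[1, , , drop = TRUE], 2, sum) > 0, 1L, 2L)
      list(X = X, labels = labels, m = 1L, n_classes = 2L, task = task)
    }
  })
}

#' Train the circuit cell on a synthetic task with naive BPTT
#'
#' Plain stochastic gradient descent on the unrolled cell: the update is
#' exactly `weight - lr * gradient`, with no gradient clipping, scaling,
#' or adaptive preconditioning anywhere in the path — training stability
#' is carried by the circuit's own normalization dynamics. Gradients are
#' checked finite at every step; a non-finite loss or gradient aborts
#' with a diagnostic error.
#'
#' @param task Passed to [make_toy_task()].
#' @param steps Number of gradient steps.
#' @param lr Learning rate.
#' @param seed Master seed (task generation, weights, batching, state
#'   initialization).
#' @param n Hidden size (number of principal neurons).
#' @param seq_len,n_examples Task shape.
#' @param batch_size Minibatch size.
#' @param learn_tau Learn the time constants.
#' @param update_hook Optional function `(step, grads, updates)` called
#'   after each parameter update, e.g. to audit that updates are the raw
#'   scaled gradients.
#' @return An `organics_training` object: `history` tibble (`step`,
#'   `loss`, `grad_norm`, `accuracy`), `initial_loss`, `final_loss`,
#'   `final_accuracy` (on a held-out evaluation subset), and the trained
#'   `weights`. `tidy()` returns the history; `autoplot()` draws the
#'   loss curve.
#' @export
train_toy <- function(task = c("delayed-recall", "sequence-sum-sign"),
                      steps = 2000, lr = 0.05, seed = 0,
                      n = 16, seq_len = 32, n_examples = 2000,
                      batch_size = 32, learn_tau = TRUE,
                      update_hook = NULL) {
  task <- match.arg(task)
  data <- make_toy_task(task, n_examples, seq_len, seed = seed)
  w <- cell_weights(n, data$m, data$n_classes, seed = seed + 1,
                    learn_tau = learn_tau)
  n_eval <- min(512L, n_examples)
  eval_idx <- seq_len(n_eval)
  eval_X <- lapply(seq_len(seq_len), function(t) {
    matrix(data$X[, t, eval_idx], nrow = data$m)
  })
  eval_init <- withr::with_seed(seed + 2, cell_init_state(w, n_eval, "uniform"))
  evaluate <- function(w) {
    cell_forward_backward(w, eval_X, data$labels[eval_idx], eval_init,
                          compute_grads = FALSE)
  }
  ev0 <- evaluate(w)
  history <- vector("list", steps)
  withr::with_seed(seed + 3, {
    for (s in seq_len(steps)) {
      idx <- sample.int(n_examples, batch_size)
      X <- lapply(seq_len(seq_len), function(t) {
        matrix(data$X[, t, idx], nrow = data$m)
      })
      init <- cell_init_state(w, batch_size, "uniform")
      fb <- cell_forward_backward(w, X, data$labels[idx], init)
      bad <- !is.finite(fb$loss) ||
        any(!vapply(fb$grads, function(g) all(is.finite(g)), logical(1)))
      if (bad) {
        stop(sprintf("non-finite loss or gradient at step %d; training aborted", s))
      }
      updates <- lapply(fb$grads, function(g) -lr * g)
      for (nm in names(updates)) w[[nm]] <- w[[nm]] + updates[[nm]]
      if (!is.null(update_hook)) update_hook(s, fb$grads, updates)
      history[[s]] <- tibble::tibble(step = s, loss = fb$loss,
                                     grad_norm = fb$grad_norm,
                                     accuracy = fb$accuracy)
    }
  })
  ev1 <- evaluate(w)
  structure(
    list(
      history = dplyr::bind_rows(history),
      initial_loss = ev0$loss, final_loss = ev1$loss,
      initial_accuracy = ev0$accuracy, final_accuracy = ev1$accuracy,
      weights = w, task = task, lr = lr, steps = steps, seed = seed
    ),
    class = "organics_training"
  )
}

#' @export
print.organics_training <- function(x, ...) {
  cat(sprintf(
    "<organics_training> task = %s: loss %.4f -> %.4f, accuracy %.3f -> %.3f (%d steps)\n",
    x$task, x$initial_loss, x$final_loss,
    x$initial_accuracy, x$final_accuracy, x$steps
  ))
  invisible(x)
}

#' @export
tidy.organics_training <- function(x, ...) x$history

#' @export
glance.organics_training <- function(x, ...) {
  tibble::tibble(
    task = x$task, steps = x$steps, lr = x$lr,
    initial_loss = x$initial_loss, final_loss = x$final_loss,
    loss_ratio = x$final_loss / x$initial_loss,
    final_accuracy = x$final_accuracy,
    max_grad_norm = max(x$history$grad_norm),
    min_grad_norm = min(x$history$grad_norm)
  )
}

#' @export
autoplot.organics_training <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x,
                         span = 0.2, colour = "black") +
    ggplot2::labs(x = "gradient step", y = "minibatch loss") +
    ggplot2::theme_minimal()
}
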