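#' Integrate the circuit dynamics
#'
#' Fixed-step explicit integration (forward Euler or classical
#' Runge-Kutta) of any of the three dynamical variants. The input drive
#' may be a constant vector or a function of time. Steps that leave the
#' state non-finite or with norm above `1e12` truncate the trajectory
#' with a divergence flag — never silently.
#'
#' @inheritParams circuit_rhs
#' @param z Constant drive vector, or a function `z(t)` returning one.
#' @param init An [organics_state()] starting condition.
#' @param dt Time step (ms); a warning is issued when `dt >= min(tau)/2`,
#'   where explicit stepping becomes stiffness-limited.
#' @param t_end End time (ms).
#' @param method `"rk4"` (default) or `"euler"`.
#' @param record_every Store every k-th step (thinning for long runs).
#' @return An `organics_trajectory`: a long tibble with columns `t`,
#'   `neuron`, `population` (`"y"`/`"a"`) and `value`, carrying the raw
#'   state history and integration metadata as attributes (`t`, `y`, `a`,
#'   `method`, `dt`, `diverged`, `variant`).
#' @export
#' @examples
#' p <- organics_params(n = 1, b = 0.5, b0 = 0.5, sigma = 0.1)
#' tr <- simulate_circuit(p, z = 1, organics_state(0, 0.05), dt = 0.05, t_end = 40)
#' attr(tr, "diverged")
simulate_circuit <- function(params, z, init, dt, t_end,
                             method = c("rk4", "euler"),
                             variant = c("identity", "general", "rectified"),
                             record_every = 1L) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  z_fun <- if (is.function(z)) z else {
    zc <- recycle_z(z, params$n)
    function(t) zc
  }
  if (dt >= min(c(params$tau_y, params$tau_a)) / 2) {
    warning("dt >= min(tau)/2: explicit integration may be unstable")
  }
  stopifnot(dt > 0, t_end > 0)
  n_steps <- ceiling(t_end / dt)
  keep <- unique(c(seq(0, n_steps, by = record_every), n_steps))
  y <- init$y
  a <- init$a
  y_hist <- matrix(NA_real_, length(keep), params$n)
  a_hist <- matrix(NA_real_, length(keep), params$n)
  t_kept <- numeric(length(keep))
  ki <- 1L
  store <- function(step, yv, av) {
    y_hist[ki, ] <<- yv
    a_hist[ki, ] <<- av
    t_kept[ki] <<- step * dt
    ki <<- ki + 1L
  }
  deriv <- function(t, yv, av) {
    circuit_rhs(organics_state(yv, av), params, z_fun(t), variant)
  }
  diverged <- FALSE
  store(0L, y, a)
  for (step in seq_len(n_steps)) {
    t0 <- (step - 1) * dt
    if (method == "euler") {
      d1 <- deriv(t0, y, a)
      y_new <- y + dt * d1$dy
      a_new <- a + dt * d1$da
    } else {
      d1 <- deriv(t0, y, a)
      d2 <- deriv(t0 + dt / 2, y + dt / 2 * d1$dy, a + dt / 2 * d1$da)
      d3 <- deriv(t0 + dt / 2, y + dt / 2 * d2$dy, a + dt / 2 * d2$da)
      d4 <- deriv(t0 + dt, y + dt * d3$dy, a + dt * d3$da)
      y_new <- y + dt / 6 * (d1$dy + 2 * d2$dy + 2 * d3$dy + d4$dy)
      a_new <- a + dt / 6 * (d1$da + 2 * d2$da + 2 * d3$da + d4$da)
    }
    if (!all(is.finite(c(y_new, a_new))) ||
        sqrt(sum(y_new^2) + sum(a_new^2)) > 1e12) {
      diverged <- TRUE
      break
    }
    y <- y_new
    a <- a_new
    if (step %in% keep) store(step, y, a)
  }
  used <- seq_len(ki - 1L)
  y_hist <- y_hist[used, , drop = FALSE]
  a_hist <- a_hist[used, , drop = FALSE]
  t_kept <- t_kept[used]
  tb <- dplyr::bind_rows(
    tidyr::pivot_longer(
      tibble::as_tibble(`colnames<-`(y_hist, seq_len(params$n))) |>
        dplyr::mutate(t = t_kept),
      -"t", names_to = "neuron", values_to = "value"
    ) |> dplyr::mutate(population = "y"),
    tidyr::pivot_longer(
      tibble::as_tibble(`colnames<-`(a_hist, seq_len(params$n))) |>
        dplyr::mutate(t = t_kept),
      -"t", names_to = "neuron", values_to = "value"
    ) |> dplyr::mutate(population = "a")
  ) |>
    dplyr::mutate(neuron = as.integer(.data$neuron)) |>
    dplyr::select("t", "population", "neuron", "value")
  structure(
    tb,
    t = t_kept, y = y_hist, a = a_hist,
    method = method, dt = dt, diverged = diverged, variant = variant,
    class = c("organics_trajectory", class(tb))
  )
}

#' Final state of a trajectory
#'
#' @param traj An `organics_trajectory`.
#' @return An [organics_state()] at the last recorded time.
#' @export
final_state <- function(traj) {
  y <- attr(traj, "y")
  a <- attr(traj, "a")
  organics_state(y[nrow(y), ], a[nrow(a), ])
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.organics_trajectory <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$t, y = .data$value,
                 colour = factor(.data$neuron), group = .data$neuron)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~population, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential",
                  colour = "neuron") +
    ggplot2::theme_minimal()
}

#' Phase portrait of the two-dimensional circuit
#'
#' Samples the vector field `(dy/dt, da/dt)` on a grid, traces the two
#' nullclines by zero-level contouring, and overlays the fixed points
#' found by [find_fixed_points_2d()] with their stability labels.
#'
#' @param params An [organics_params()] with `n = 1`.
#' @param z Scalar input drive.
#' @param y_range,a_range Length-2 plotting ranges; sensible defaults are
#'   derived from the admissible steady-state interval and the fixed
#'   points.
#' @param grid_n Grid resolution per axis for the sampled field (the
#'   nullclines use a finer internal grid).
#' @param variant `"general"` or `"rectified"`.
#' @return An `organics_phase` list of tibbles: `field` (`y`, `a`, `dy`,
#'   `da`), `nullclines` (`y`, `a`, `which`, `piece`) and `fixed_points`;
#'   plot with [autoplot()].
#' @export
phase_portrait_2d <- function(params, z, y_range = NULL, a_range = NULL,
                              grid_n = 21,
                              variant = c("general", "rectified")) {
  variant <- match.arg(variant)
  stopifnot(params$n == 1)
  fps <- find_fixed_points_2d(params, z, variant = variant)
  w <- params$W[1, 1]
  if (is.null(y_range)) {
    hi <- if (w > 0) 0.95 / sqrt(w) else max(abs(fps$y_s), 1) * 1.5
    y_range <- range(c(-hi, hi, fps$y_s * 1.2))
  }
  if (is.null(a_range)) {
    a_range <- c(0, max(c(2 * fps$a_s, 1)))
  }
  fld <- function(res) {
    grid <- tidyr::expand_grid(
      y = seq(y_range[1], y_range[2], length.out = res),
      a = seq(a_range[1], a_range[2], length.out = res)
    )
    d <- purrr::map2(grid$y, grid$a, function(yy, aa) {
      circuit_rhs(organics_state(yy, aa), params, z, variant)
    })
    grid$dy <- purrr::map_dbl(d, "dy")
    grid$da <- purrr::map_dbl(d, "da")
    grid
  }
  field <- fld(grid_n)
  fine <- fld(101)
  contour_zero <- function(value, which) {
    yy <- sort(unique(fine$y))
    aa <- sort(unique(fine$a))
    zmat <- matrix(value, nrow = length(yy), byrow = TRUE)
    cl <- grDevices::contourLines(yy, aa, zmat, levels = 0)
    purrr::imap_dfr(cl, function(piece, i) {
      tibble::tibble(y = piece$x, a = piece$y, which = which,
                     piece = paste0(which, "_", i))
    })
  }
  nullclines <- dplyr::bind_rows(
    contour_zero(fine$dy, "y-nullcline"),
    contour_zero(fine$da, "a-nullcline")
  )
  structure(
    list(field = field, nullclines = nullclines, fixed_points = fps,
         y_range = y_range, a_range = a_range, variant = variant),
    class = "organics_phase"
  )
}

#' @export
autoplot.organics_phase <- function(object, arrow_scale = 0.4, ...) {
  f <- object$field
  step <- min(diff(sort(unique(f$y))))
  norm <- sqrt(f$dy^2 + f$da^2)
  len <- arrow_scale * step / pmax(norm, 1e-12)
  f$yend <- f$y + f$dy * len
  f$aend <- f$a + f$da * len
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = f,
      ggplot2::aes(x = .data$y, y = .data$a,
                   xend = .data$yend, yend = .data$aend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm")),
      colour = "grey55", linewidth = 0.3
    ) +
    ggplot2::geom_path(
      data = object$nullclines,
      ggplot2::aes(x = .data$y, y = .data$a,
                   colour = .data$which, group = .data$piece)
    ) +
    ggplot2::geom_point(
      data = object$fixed_points,
      ggplot2::aes(x = .data$y_s, y = .data$a_s, shape = .data$classification),
      size = 3, colour = "black", fill = "red", stroke = 1.1
    ) +
    ggplot2::scale_shape_manual(
      values = c(stable = 23, unstable = 21, marginal = 22)
    ) +
    ggplot2::labs(x = "y (principal potential)", y = "a (modulator potential)",
                  colour = NULL, shape = "fixed point") +
    ggplot2::theme_minimal()
}

#' Sample a random circuit under the stability-sweep constraints
#'
#' Draws one parameter set and input drive from broad, positive,
#' scale-controlled distributions: time constants log-uniform on
#' `[1, 100]` ms; gains and semisaturation log-uniform on `[0.1, 2]`;
#' normalization weights `|N(0,1)|/n`; recurrent weights `N(0,1)/sqrt(n)`
#' rescaled so the maximum singular value equals `smax` exactly; input
#' drive uniform in direction with radius uniform on `[0, 1]`, so
#' `||z|| <= 1` by construction.
#'
#' @param n Circuit size.
#' @param smax Imposed maximum singular value of the recurrent matrix.
#' @param seed Optional integer; the draw is a pure function of
#'   `(n, smax, seed)` when supplied.
#' @return A list with elements `params` ([organics_params()]) and `z`.
#' @export
sample_random_circuit <- function(n, smax = 1, seed = NULL) {
  draw <- function() {
    lu <- function(k, lo, hi) exp(stats::runif(k, log(lo), log(hi)))
    W_r <- matrix(stats::rnorm(n * n), n, n) / sqrt(n)
    W_r <- W_r * (smax / max(svd(W_r)$d))
    g <- stats::rnorm(n)
    z <- g / sqrt(sum(g^2)) * stats::runif(1)
    list(
      params = organics_params(
        n = n,
        tau_y = lu(n, 1, 100), tau_a = lu(n, 1, 100),
        b = lu(n, 0.1, 2), b0 = lu(n, 0.1, 2), sigma = lu(n, 0.1, 2),
        W_r = W_r,
        W = abs(matrix(stats::rnorm(n * n), n, n)) / n
      ),
      z = z
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Continuation of the normalization fixed point from identity recurrence
# (t = 0, closed form) to the target W_r (t = 1), Newton-tracking the
# branch with adaptive steps. Returns NULL when the branch cannot be
# continued to t = 1 (e.g. it disappears in a saddle-node).
homotopy_fixed_point <- function(params, z, tol = 1e-8, max_newton_calls = 30) {
  pI <- params
  pI$W_r <- diag(params$n)
  fp <- analytic_fixed_point(pI, z)
  t <- 0
  dt <- 0.2
  calls <- 0
  while (t < 1 - 1e-12) {
    if (calls >= max_newton_calls || dt < 1e-3) return(NULL)
    t_next <- min(1, t + dt)
    pt <- params
    pt$W_r <- t_next * params$W_r + (1 - t_next) * diag(params$n)
    np <- newton_fixed_point(pt, z, organics_state(fp$y_s, fp$a_s),
                             tol = tol, max_iter = 60)
    calls <- calls + 1
    if (isTRUE(np$converged)) {
      fp <- np
      t <- t_next
      dt <- min(dt * 1.5, 0.25)
    } else {
      dt <- dt / 2
    }
  }
  fp
}

#' Randomized stability sweep
#'
#' Repeats: sample a circuit with [sample_random_circuit()], locate a
#' fixed point (alternating iteration, with a long-integration fallback
#' when the iteration stalls), and evaluate the Jacobian spectrum there.
#' A trial counts as stable only when a fixed point was located to
#' tolerance *and* the maximum real eigenvalue is below `-1e-9`; trials
#' that diverge or fail to converge are counted unstable, never dropped —
#' the accounting is conservative, biased against the stability claim.
#'
#' With `identity_recurrence = TRUE` the sampled recurrent matrix is
#' replaced by the identity (the regime with a proven unconditional
#' stability certificate) and the closed-form fixed point is used.
#'
#' @param n Circuit size per trial.
#' @param n_trials Number of trials.
#' @param smax Maximum singular value imposed on the recurrent matrix.
#' @param seed Master seed; per-trial seeds are derived deterministically.
#' @param identity_recurrence Use identity recurrent weights instead of
#'   the sampled ones.
#' @param tol Fixed-point residual tolerance.
#' @return An `organics_sweep` tibble with one row per trial (`trial`,
#'   `seed`, `converged`, `used_fallback`, `residual`, `max_re`,
#'   `stable`) and attributes `n`, `smax`, `n_trials`, `fraction_stable`;
#'   `glance()` gives the one-row summary.
#' @export
#' @examples
#' sw <- stability_sweep(n = 5, n_trials = 20, smax = 1, seed = 1)
#' glance(sw)
stability_sweep <- function(n = 20, n_trials = 1000, smax = 1, seed = 1,
                            identity_recurrence = FALSE, tol = 1e-8) {
  records <- purrr::map_dfr(seq_len(n_trials), function(i) {
    trial_seed <- (seed + 104729 * i) %% .Machine$integer.max
    s <- sample_random_circuit(n, smax = smax, seed = trial_seed)
    params <- s$params
    if (identity_recurrence) params$W_r <- diag(n)
    variant <- if (identity_recurrence) "identity" else "general"
    fp <- if (identity_recurrence) {
      analytic_fixed_point(params, s$z)
    } else {
      fixed_point_iteration(params, s$z, tol = tol, max_iter = 100)
    }
    max_re_at <- function(fp) {
      J <- suppressWarnings(circuit_jacobian(params, s$z, fp, variant))
      max(Re(eigen(J, only.values = TRUE)$values))
    }
    max_re <- if (isTRUE(fp$converged)) max_re_at(fp) else NA_real_
    stable <- isTRUE(fp$converged) && is.finite(max_re) && max_re < -1e-9
    used_fallback <- FALSE
    if (!stable) {
      # The iteration either stalled or landed on an unstable branch.
      # A stable fixed point, if one exists, attracts trajectories:
      # integrate in chunks from a couple of starting points, polishing
      # each endpoint by damped Newton, and stop at the first stable
      # fixed point located to tolerance.
      used_fallback <- TRUE
      tau_min <- min(c(params$tau_y, params$tau_a))
      tau_max <- max(c(params$tau_y, params$tau_a))
      inits <- list(
        organics_state(rep(0, n), params$b0 * params$sigma),
        withr::with_seed(trial_seed + 1, organics_state(
          stats::rnorm(n, sd = 0.1), abs(stats::rnorm(n, sd = 0.1))
        ))
      )
      for (init in inits) {
        state <- init
        for (chunk in 1:3) {
          tr <- suppressWarnings(simulate_circuit(
            params, s$z, state, dt = tau_min / 3, t_end = 15 * tau_max,
            method = "rk4", variant = variant, record_every = 1e6
          ))
          if (attr(tr, "diverged")) break
          state <- final_state(tr)
          np <- newton_fixed_point(params, s$z, state, tol = tol)
          if (isTRUE(np$converged)) {
            mre <- max_re_at(np)
            if (is.finite(mre) && mre < -1e-9) {
              fp <- np
              max_re <- mre
              stable <- TRUE
              break
            }
          }
        }
        if (stable) break
      }
      if (!stable) {
        # last resort: continue the known identity-recurrence fixed point
        # along W_r(t) = t W_r + (1-t) I. If the stable branch survives to
        # t = 1 this locates it; if it dies at a fold, no stable fixed
        # point continues from the normalization branch.
        hp <- homotopy_fixed_point(params, s$z, tol = tol)
        if (!is.null(hp)) {
          mre <- max_re_at(hp)
          if (is.finite(mre) && mre < -1e-9) {
            fp <- hp
            max_re <- mre
            stable <- TRUE
          }
        }
      }
    }
    tibble::tibble(
      trial = i, seed = trial_seed,
      converged = isTRUE(fp$converged), used_fallback = used_fallback,
      residual = fp$residual, max_re = max_re,
      stable = stable
    )
  })
  structure(
    records,
    n = n, smax = smax, n_trials = n_trials,
    fraction_stable = mean(records$stable),
    class = c("organics_sweep", class(records))
  )
}

#' @export
glance.organics_sweep <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"),
    smax = attr(x, "smax"),
    n_trials = attr(x, "n_trials"),
    n_stable = sum(x$stable),
    fraction_stable = attr(x, "fraction_stable")
  )
}

#' @export
autoplot.organics_sweep <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, is.finite(.data$max_re)),
    ggplot2::aes(x = .data$max_re, fill = .data$stable)
  ) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "max Re(eigenvalue) at fixed point", y = "trials",
                  fill = "stable") +
    ggplot2::theme_minimal()
}
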