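new_fixed_point <- function(y_s, a_s, method, n_iter, residual,
                            converged = TRUE, stable = NA) {
  structure(
    list(
      y_s = y_s, a_s = a_s,
      y_s_plus = relu(y_s)^2, y_s_minus = relu(-y_s)^2, a_s_plus = relu(a_s),
      method = method, n_iter = n_iter, residual = residual,
      converged = converged, stable = stable
    ),
    class = "organics_fp"
  )
}

#' @export
print.organics_fp <- function(x, ...) {
  cat(sprintf(
    "<organics_fp> method = %s, n_iter = %d, residual = %.3g, converged = %s\n",
    x$method, x$n_iter, x$residual, x$converged
  ))
  if (length(x$y_s) <= 8) {
    cat("  y_s:", signif(x$y_s, 6), "\n  a_s:", signif(x$a_s, 6), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.organics_fp <- function(x, ...) {
  tibble::tibble(
    neuron = seq_along(x$y_s),
    y_s = x$y_s, a_s = x$a_s,
    y_s_plus = x$y_s_plus, y_s_minus = x$y_s_minus, a_s_plus = x$a_s_plus
  )
}

#' @export
glance.organics_fp <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_iter = x$n_iter, residual = x$residual,
    converged = x$converged, stable = x$stable
  )
}

#' Closed-form normalization fixed point (identity recurrence)
#'
#' With identity recurrent weights the circuit has a unique fixed point,
#' known in closed form:
#' `a_s = sqrt(b0^2 sigma^2 + W (b^2 z^2))` and `y_s = b z / a_s`.
#' At this point the steady firing rates implement divisive normalization:
#' each principal response is divided by pooled activity plus the
#' semisaturation floor.
#'
#' @param params An [organics_params()] with `W_r` equal to the identity.
#' @param z Input drive vector (length `n`, scalars recycled).
#' @return An `organics_fp` object; see [tidy()] / [glance()] methods.
#' @export
#' @examples
#' p <- organics_params(n = 1, b = 0.5, b0 = 0.5, sigma = 0.1)
#' analytic_fixed_point(p, z = 1)
analytic_fixed_point <- function(params, z) {
  if (!has_identity_recurrence(params, tol = 1e-8)) {
    stop("analytic fixed point requires identity recurrent weights `W_r`")
  }
  z <- recycle_z(z, params$n)
  bz <- params$b * z
  a_s <- sqrt(params$b0^2 * params$sigma^2 + drop(params$W %*% bz^2))
  y_s <- bz / a_s
  res <- rhs_residual(y_s, a_s, params, z, "identity")
  new_fixed_point(y_s, a_s, method = "analytic", n_iter = 0L, residual = res)
}

#' Steady-state normalization equation
#'
#' When the input gains are uniform and matched (`b = b0 = constant`), the
#' steady firing rates of the principal on/off pair follow the divisive
#' normalization equation exactly:
#' `y_s_plus = max(z,0)^2 / (sigma^2 + W (max(z,0)^2 + max(-z,0)^2))` and
#' symmetrically for `y_s_minus`. The two rectified channels together
#' contribute the contrast energy `z^2` to the normalization pool.
#'
#' @inheritParams analytic_fixed_point
#' @return A tibble with columns `neuron`, `y_s_plus`, `y_s_minus`.
#' @export
normalization_response <- function(params, z) {
  b <- params$b; b0 <- params$b0
  if (max(abs(b - b[1])) > 1e-12 || max(abs(b0 - b[1])) > 1e-12) {
    stop("normalization equation requires b = b0 = constant")
  }
  z <- recycle_z(z, params$n)
  pool <- params$sigma^2 + drop(params$W %*% (relu(z)^2 + relu(-z)^2))
  tibble::tibble(
    neuron = seq_len(params$n),
    y_s_plus = relu(z)^2 / pool,
    y_s_minus = relu(-z)^2 / pool
  )
}

recycle_z <- function(z, n) {
  z <- as.numeric(z)
  if (length(z) == 1 && n > 1) z <- rep(z, n)
  stopifnot(length(z) == n)
  z
}

# Inner solve of the modulator steady state given fixed y. At a steady
# state a > 0, so a = sqrt(v + W(y^2 * a^2)) is linear in q = a^2:
# (I - W diag(y^2)) q = v with v = b0^2 sigma^2 > 0. A valid steady state
# has q > 0, which forces rho(W diag(y^2)) < 1; when the current y admits
# no positive solution the half-step is reported as failed (NULL).
solve_a_given_y <- function(y, params) {
  v <- params$b0^2 * params$sigma^2
  M <- diag(params$n) - params$W %*% diag(y^2, params$n)
  q <- tryCatch(drop(solve(M, v)), error = function(e) NULL)
  if (is.null(q) || !all(is.finite(q)) || any(q <= 0)) return(NULL)
  sqrt(q)
}

#' Fixed point by alternating iteration (arbitrary recurrence)
#'
#' For a general recurrent weight matrix the steady state has no closed
#' form. This solver alternates two exact half-steps:
#'
#' 1. given the modulator state `a`, solve the linear system
#'    `(I - diag(1 - max(a,0)) W_r) y = b * z` for the principal state;
#' 2. given `y`, solve the modulator steady-state equation
#'    `a = sqrt(b0^2 sigma^2 + W(y^2 a^2))` by inner iteration.
#'
#' Convergence is measured by the max-norm of the full state derivative.
#' When the recurrent weights have maximum singular value at most 1 and
#' the input drive norm is at most 1, the scheme converges to high
#' accuracy in a handful of outer steps.
#'
#' @inheritParams analytic_fixed_point
#' @param params An [organics_params()]; any `W_r` accepted.
#' @param tol Convergence tolerance on the max-norm residual of the
#'   general-recurrence state derivative.
#' @param max_iter Maximum number of outer iterations.
#' @param init Optional [organics_state()] starting point; the default is
#'   the identity-recurrence normalization fixed point, a good warm start
#'   whenever the recurrent weights are scale-controlled.
#' @return An `organics_fp`; `converged = FALSE` flags the best iterate
#'   when the tolerance was not reached.
#' @export
fixed_point_iteration <- function(params, z, tol = 1e-8, max_iter = 50,
                                  init = NULL) {
  z <- recycle_z(z, params$n)
  bz <- params$b * z
  if (is.null(init)) {
    a <- sqrt(params$b0^2 * params$sigma^2 + drop(params$W %*% bz^2))
    y <- bz / a
  } else {
    y <- init$y
    a <- init$a
  }
  best <- list(y = y, a = a, res = rhs_residual(y, a, params, z, "general"), it = 0L)
  for (it in seq_len(max_iter)) {
    A <- diag(params$n) - diag(1 - relu(a), params$n) %*% params$W_r
    y <- tryCatch(drop(solve(A, bz)), error = function(e) {
      warning("singular linear solve in fixed-point iteration: ", conditionMessage(e))
      NULL
    })
    a_new <- if (is.null(y)) NULL else solve_a_given_y(y, params)
    if (is.null(a_new)) {
      return(new_fixed_point(best$y, best$a, "iteration", it, best$res,
                             converged = FALSE))
    }
    a <- a_new
    res <- rhs_residual(y, a, params, z, "general")
    if (res < best$res) best <- list(y = y, a = a, res = res, it = it)
    if (res < tol) {
      return(new_fixed_point(y, a, "iteration", it, res))
    }
    if (!all(is.finite(c(y, a)))) break
  }
  new_fixed_point(best$y, best$a, "iteration", max_iter, best$res,
                  converged = FALSE)
}

#' Polish a fixed point by damped Newton iteration
#'
#' Newton root-finding on the full 2n-dimensional steady-state system of
#' the general-recurrence dynamics, with backtracking line search on the
#' residual max-norm. Used to finish off starting points where the
#' alternating scheme stalls (e.g. strongly expansive recurrence).
#'
#' @inheritParams fixed_point_iteration
#' @param init An [organics_state()] starting point (required).
#' @return An `organics_fp` with `method = "root_find"`.
#' @export
newton_fixed_point <- function(params, z, init, tol = 1e-8, max_iter = 50) {
  z <- recycle_z(z, params$n)
  y <- init$y
  a <- init$a
  Fv <- function(y, a) {
    d <- circuit_rhs(organics_state(y, a), params, z, "general")
    c(d$dy, d$da)
  }
  f <- Fv(y, a)
  res <- max(abs(f))
  for (it in seq_len(max_iter)) {
    if (res < tol) {
      return(new_fixed_point(y, a, "root_find", it - 1L, res))
    }
    J <- suppressWarnings(
      circuit_jacobian(params, z, list(y_s = y, a_s = a), "general")
    )
    step <- tryCatch(drop(solve(J, -f)), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    lam <- 1
    improved <- FALSE
    for (k in 1:25) {
      y_t <- y + lam * step[seq_len(params$n)]
      a_t <- a + lam * step[params$n + seq_len(params$n)]
      f_t <- Fv(y_t, a_t)
      if (all(is.finite(f_t)) && max(abs(f_t)) < res) {
        y <- y_t; a <- a_t; f <- f_t; res <- max(abs(f_t))
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  new_fixed_point(y, a, "root_find", max_iter, res, converged = res < tol)
}

# modulator steady state as a function of y for the 2D circuit:
# a > 0 always holds at steady state, and a = b0*sigma / sqrt(1 - w y^2)
# requires w y^2 < 1 (no fixed point exists outside that interval).
steady_a_2d <- function(y, params) {
  w <- params$W[1, 1]
  v <- params$b0[1] * params$sigma[1]
  d <- 1 - w * y^2
  ifelse(d > 0, v / sqrt(d), NA_real_)
}

#' Enumerate the fixed points of the two-dimensional circuit
#'
#' For one principal and one modulator neuron all steady states can be
#' enumerated. At steady state the modulator potential is always positive
#' and satisfies `a = b0 sigma / sqrt(1 - w y^2)`, defined on
#' `|y| < 1/sqrt(w)`; substituting into the principal steady-state
#' equation leaves a scalar root-finding problem in `y`, solved by a dense
#' sign-change scan over the admissible interval followed by bisection
#' polishing. Each root is classified by the eigenvalues of the 2x2
#' Jacobian of the chosen variant.
#'
#' For the main (`"general"`) variant with positive drive there is always
#' exactly one fixed point with `y_s > 0`, and the total count is 1 or 3.
#'
#' @param params An [organics_params()] with `n = 1`.
#' @param z Scalar input drive.
#' @param variant `"general"` (the main model) or `"rectified"`.
#' @param n_scan Number of scan points across the admissible interval.
#' @return A tibble with one row per fixed point: `y_s`, `a_s`,
#'   `y_s_plus`, `y_s_minus`, `a_s_plus`, `residual`, `max_re`,
#'   `classification` (`"stable"`, `"unstable"` or `"marginal"`) and
#'   `stable`.
#' @export
#' @examples
#' p <- organics_params(n = 1, b = 0.5, b0 = 0.5, sigma = 0.1, W_r = 0.5)
#' find_fixed_points_2d(p, z = 1)
find_fixed_points_2d <- function(params, z,
                                 variant = c("general", "rectified"),
                                 n_scan = 2001) {
  variant <- match.arg(variant)
  stopifnot(params$n == 1)
  z <- as.numeric(z)[1]
  w <- params$W[1, 1]
  wr <- params$W_r[1, 1]
  bz <- params$b[1] * z
  # principal steady-state residual as a scalar function of y
  g <- function(y) {
    a <- steady_a_2d(y, params)
    yr <- if (variant == "rectified") relu(y) else y
    -y + bz + (1 - a) * wr * yr
  }
  if (w > 0) {
    ymax <- 1 / sqrt(w)
    lo <- -ymax * (1 - 1e-9)
    hi <- ymax * (1 - 1e-9)
  } else {
    half <- 10 * max(abs(bz), 1) * max(1, 1 / max(abs(1 - wr * (1 - params$b0[1] * params$sigma[1])), 1e-3))
    lo <- -half
    hi <- half
  }
  ys <- seq(lo, hi, length.out = n_scan)
  gs <- vapply(ys, g, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(n_scan - 1)) {
    g1 <- gs[i]; g2 <- gs[i + 1]
    if (!is.finite(g1) || !is.finite(g2)) next
    if (g1 == 0) roots <- c(roots, ys[i])
    if (g1 * g2 < 0) {
      r <- stats::uniroot(g, c(ys[i], ys[i + 1]), tol = 1e-14)$root
      roots <- c(roots, r)
    }
  }
  if (is.finite(gs[n_scan]) && gs[n_scan] == 0) roots <- c(roots, ys[n_scan])
  if (w <= 0 && length(roots) &&
      (min(roots) <= lo + (hi - lo) / n_scan || max(roots) >= hi - (hi - lo) / n_scan)) {
    warning("scan bracket reached; fixed points may lie outside the scanned range")
  }
  roots <- sort(unique(round(roots, 12)))
  purrr::map_dfr(roots, function(y_s) {
    a_s <- steady_a_2d(y_s, params)
    res <- rhs_residual(y_s, a_s, params, z, variant)
    fp <- new_fixed_point(y_s, a_s, "root_find", 0L, res)
    J <- circuit_jacobian(params, z, fp, variant)
    ev <- eigen(J, only.values = TRUE)$values
    mre <- max(Re(ev))
    cls <- if (mre < -1e-9) "stable" else if (mre > 1e-9) "unstable" else "marginal"
    tibble::tibble(
      y_s = y_s, a_s = a_s,
      y_s_plus = relu(y_s)^2, y_s_minus = relu(-y_s)^2, a_s_plus = relu(a_s),
      residual = res, max_re = mre,
      classification = cls, stable = cls == "stable"
    )
  })
}
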