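#' Analytic Jacobian of the circuit at a fixed point
#'
#' Block 2n x 2n Jacobian of the chosen dynamical variant, evaluated at a
#' steady state. Ordering is `(y, a)`. Derivatives of the rectifications
#' use the one-sided convention: slope 0 exactly at the corner. A warning
#' is emitted when any modulator sits at the rectification corner, where
#' the linearization is only one-sided.
#'
#' @param params An [organics_params()].
#' @param z Input drive (used only through the fixed point; accepted for a
#'   uniform interface).
#' @param fp An `organics_fp` (or any list with `y_s`, `a_s`).
#' @param variant Dynamical variant, as in [circuit_rhs()].
#' @return A `2n x 2n` numeric matrix.
#' @export
circuit_jacobian <- function(params, z, fp,
                             variant = c("identity", "general", "rectified")) {
  variant <- match.arg(variant)
  n <- params$n
  y <- fp$y_s; a <- fp$a_s
  if (any(abs(a) < 1e-10)) {
    warning("modulator state at the rectification corner; Jacobian is one-sided")
  }
  ap <- relu(a)
  ind_a <- as.numeric(a > 0)
  g <- params$b0^2 * params$sigma^2 + drop(params$W %*% (y^2 * ap^2))
  s <- sqrt(g)
  Dty <- 1 / params$tau_y
  Dta <- 1 / params$tau_a
  J_yy <- switch(variant,
    identity = diag(-ap * Dty, n),
    general = diag(Dty, n) %*% (-diag(n) + diag(1 - ap, n) %*% params$W_r),
    rectified = diag(Dty, n) %*%
      (-diag(n) + diag(1 - ap, n) %*% params$W_r %*% diag(as.numeric(y > 0), n))
  )
  rec_in <- switch(variant,
    identity = y,
    general = drop(params$W_r %*% y),
    rectified = drop(params$W_r %*% relu(y))
  )
  J_ya <- diag(-ind_a * rec_in * Dty, n)
  J_ay <- diag(Dta / s, n) %*% params$W %*% diag(y * ap^2, n)
  J_aa <- diag(Dta, n) %*%
    (-diag(n) + diag(1 / s, n) %*% params$W %*% diag(y^2 * ap * ind_a, n))
  rbind(cbind(J_yy, J_ya), cbind(J_ay, J_aa))
}

#' Quadratic-eigenvalue-problem matrices for identity recurrence
#'
#' Around the closed-form normalization fixed point, the linearized
#' identity-recurrence circuit is equivalent to a damped mechanical
#' system `x'' + B x' + K x = 0`: the stiffness `K` is positive diagonal
#' and the damping splits as `B = B1 + B2 - B3` with
#' `K = diag(a_s / (tau_y tau_a))`, `B1 = diag(1/tau_a)`,
#' `B2 = diag(a_s/tau_y)` and `B3 = diag(1/tau_a) W diag(y_s^2)`.
#' Because `W >= 0`, `B` has nonpositive off-diagonal entries (a
#' Z-matrix) — the gateway to the M-matrix stability certificate.
#'
#' @inheritParams analytic_fixed_point
#' @return An `organics_qep` list with `B`, `K`, `B1`, `B2`, `B3` and the
#'   fixed point used.
#' @export
qep_matrices <- function(params, z) {
  if (!has_identity_recurrence(params, tol = 1e-8)) {
    stop("the quadratic eigenvalue reduction requires identity recurrence")
  }
  fp <- analytic_fixed_point(params, z)
  B1 <- diag(1 / params$tau_a, params$n)
  B2 <- diag(fp$a_s / params$tau_y, params$n)
  B3 <- diag(1 / params$tau_a, params$n) %*% params$W %*% diag(fp$y_s^2, params$n)
  structure(
    list(
      B = B1 + B2 - B3, K = diag(fp$a_s / (params$tau_y * params$tau_a), params$n),
      B1 = B1, B2 = B2, B3 = B3, fp = fp
    ),
    class = "organics_qep"
  )
}

#' Eigenvalues of the quadratic eigenvalue problem
#'
#' Roots of `det(lambda^2 I + lambda B + K) = 0`, computed from the
#' companion-form linearization. For identity recurrence these coincide
#' (as a multiset) with the eigenvalues of the full 2n x 2n Jacobian at
#' the normalization fixed point, via a diagonal similarity.
#'
#' @param qep An `organics_qep` from [qep_matrices()], or any list with
#'   matrices `B` and `K`.
#' @return A complex vector of length `2n`.
#' @export
qep_eigenvalues <- function(qep) {
  n <- nrow(qep$B)
  companion <- rbind(
    cbind(matrix(0, n, n), diag(n)),
    cbind(-qep$K, -qep$B)
  )
  eigen(companion, only.values = TRUE)$values
}

#' M-matrix splitting certificate and diagonal Lyapunov witness
#'
#' Certifies that the damping matrix `B` of the quadratic reduction is
#' Lyapunov diagonally stable, which implies asymptotic stability of the
#' linearized circuit regardless of every other parameter. The
#' certificate has two redundant layers:
#'
#' * a convergent regular splitting `B = M - N` with `M = B1 + B2`
#'   (positive diagonal) and `N = B3 >= 0`; `B` is a nonsingular M-matrix
#'   iff it is a Z-matrix and `rho(M^-1 N) < 1`;
#' * an explicit diagonal witness `T = diag(v / u)` with `u = B^-1 1`,
#'   `v = B^-T 1` (both elementwise positive for a nonsingular M-matrix),
#'   verified by eigendecomposition of `T B + B' T`.
#'
#' Failures are reported in the returned flags, never silently asserted.
#'
#' @param qep An `organics_qep` from [qep_matrices()].
#' @return An `organics_splitting` list: `M`, `N`, `S = M^-1 N`, `rho`,
#'   `is_Z`, `is_M_matrix`, `T_diag`, `witness_min_eigen`, `witness_ok`.
#' @export
splitting_certificate <- function(qep) {
  B <- qep$B
  n <- nrow(B)
  M <- qep$B1 + qep$B2
  N <- qep$B3
  S <- diag(1 / diag(M), n) %*% N
  rho <- if (n == 1) abs(S[1, 1]) else max(Mod(eigen(S, only.values = TRUE)$values))
  offdiag <- B - diag(diag(B), n)
  is_Z <- all(offdiag <= 1e-12)
  is_M <- is_Z && rho < 1
  u <- tryCatch(drop(solve(B, rep(1, n))), error = function(e) rep(NA_real_, n))
  v <- tryCatch(drop(solve(t(B), rep(1, n))), error = function(e) rep(NA_real_, n))
  T_diag <- v / u
  witness_min <- NA_real_
  witness_ok <- FALSE
  if (all(is.finite(T_diag)) && all(u > 0) && all(v > 0)) {
    G <- diag(T_diag, n) %*% B
    G <- G + t(G)
    witness_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    witness_ok <- witness_min > 0
  }
  structure(
    list(
      M = M, N = N, S = S, rho = rho,
      is_Z = is_Z, is_M_matrix = is_M,
      T_diag = T_diag, witness_min_eigen = witness_min, witness_ok = witness_ok
    ),
    class = "organics_splitting"
  )
}

#' Closed-form eigenvalues for the uniform-pool special case
#'
#' When the recurrence is the identity, the normalization pool is uniform
#' (`W` a constant `alpha` times the all-ones matrix) and the scalar
#' parameters are shared across neurons, the damping matrix is diagonal
#' plus rank-one and the stiffness is scalar. The `2n` eigenvalues then
#' come from `n` decoupled quadratics: `n - 1` copies of
#' `lambda^2 + c lambda + k = 0` with `c = 1/tau_a + a_s/tau_y` and
#' `k = a_s/(tau_y tau_a)`, plus one pair from
#' `lambda^2 + (c - (alpha/tau_a) sum(y_s^2)) lambda + k = 0`.
#' Complex-conjugate pairs correspond to damped oscillation.
#'
#' @inheritParams analytic_fixed_point
#' @param alpha Optional uniform normalization weight; inferred from
#'   `params$W` when `NULL` (all entries must agree).
#' @return A complex vector of length `2n`, matching [qep_eigenvalues()]
#'   as a multiset.
#' @export
special_case_eigenvalues <- function(params, z, alpha = NULL) {
  n <- params$n
  if (!has_identity_recurrence(params, tol = 1e-8)) {
    stop("the closed-form case requires identity recurrence")
  }
  for (nm in c("tau_y", "tau_a", "b", "b0", "sigma")) {
    if (max(abs(params[[nm]] - params[[nm]][1])) > 1e-12) {
      stop(sprintf("the closed-form case requires scalar `%s`", nm))
    }
  }
  if (is.null(alpha)) alpha <- params$W[1, 1]
  if (max(abs(params$W - alpha)) > 1e-12) {
    stop("the closed-form case requires a uniform normalization pool W = alpha * ones")
  }
  z <- recycle_z(z, n)
  tau_y <- params$tau_y[1]; tau_a <- params$tau_a[1]
  bz <- params$b * z
  a_s <- sqrt(params$b0[1]^2 * params$sigma[1]^2 + alpha * sum(bz^2))
  y_s <- bz / a_s
  cc <- 1 / tau_a + a_s / tau_y
  k <- a_s / (tau_y * tau_a)
  quad_roots <- function(b_coef) {
    disc <- as.complex(b_coef^2 - 4 * k)
    c((-b_coef + sqrt(disc)) / 2, (-b_coef - sqrt(disc)) / 2)
  }
  c(
    rep(quad_roots(cc), n - 1),
    quad_roots(cc - (alpha / tau_a) * sum(y_s^2))
  )
}

#' Maximum paired discrepancy between two eigenvalue multisets
#'
#' Sorts both sets by real part then imaginary part and reports the
#' largest pairwise distance, normalized by `1 + |lambda|`. Used to check
#' that the quadratic-eigenvalue reduction reproduces the Jacobian
#' spectrum.
#'
#' @param e1,e2 Complex vectors of equal length.
#' @return A nonnegative scalar.
#' @export
eigen_multiset_error <- function(e1, e2) {
  stopifnot(length(e1) == length(e2))
  key <- function(e) order(round(Re(e), 9), round(Im(e), 9))
  e1 <- e1[key(e1)]
  e2 <- e2[key(e2)]
  max(Mod(e1 - e2) / (1 + Mod(e1)))
}

#' Full local stability report at the circuit's operating point
#'
#' Locates a fixed point (closed form for the identity variant,
#' alternating iteration otherwise), evaluates the Jacobian spectrum
#' there, and — for identity recurrence — attaches the quadratic
#' eigenvalue reduction and the M-matrix / diagonal-Lyapunov certificate.
#' A fixed point that cannot be located is reported as not stable
#' (`diverged = TRUE`), never dropped.
#'
#' @inheritParams circuit_rhs
#' @param tol Residual tolerance for the iterative fixed-point solve.
#' @return An `organics_stability` object; see `tidy()` (eigenvalues) and
#'   `glance()` (one-row summary).
#' @export
#' @examples
#' p <- organics_params(n = 2, b = 0.5, b0 = 0.5, sigma = 0.1)
#' glance(assess_stability(p, z = c(1, 0.5)))
assess_stability <- function(params, z,
                             variant = c("identity", "general", "rectified"),
                             tol = 1e-8) {
  variant <- match.arg(variant)
  z <- recycle_z(z, params$n)
  fp <- if (variant == "identity") {
    analytic_fixed_point(params, z)
  } else {
    fp0 <- fixed_point_iteration(params, z, tol = tol)
    if (!isTRUE(fp0$converged)) {
      # polish the stalled iterate; expansive recurrence can defeat the
      # alternating scheme while a nearby fixed point still exists
      fp1 <- newton_fixed_point(params, z, organics_state(fp0$y_s, fp0$a_s),
                                tol = tol)
      if (isTRUE(fp1$converged)) fp1 else fp0
    } else {
      fp0
    }
  }
  diverged <- !isTRUE(fp$converged) || fp$residual > max(tol, 1e-6)
  J <- circuit_jacobian(params, z, fp, variant)
  ev <- eigen(J, only.values = TRUE)$values
  max_real <- max(Re(ev))
  qep <- NULL
  cert <- NULL
  qev <- NULL
  if (variant == "identity" && has_identity_recurrence(params, tol = 1e-8)) {
    qep <- qep_matrices(params, z)
    cert <- splitting_certificate(qep)
    qev <- qep_eigenvalues(qep)
  }
  structure(
    list(
      variant = variant, fixed_point = fp, jacobian = J,
      eigenvalues = ev, max_real = max_real,
      qep = qep, qep_eigenvalues = qev, certificate = cert,
      diverged = diverged,
      stable = !diverged && max_real < -1e-9
    ),
    class = "organics_stability"
  )
}

#' @export
print.organics_stability <- function(x, ...) {
  cat(sprintf(
    "<organics_stability> variant = %s, max Re(lambda) = %.6g, stable = %s\n",
    x$variant, x$max_real, x$stable
  ))
  if (!is.null(x$certificate)) {
    cat(sprintf(
      "  certificate: Z-matrix = %s, rho(S) = %.6g, diagonal witness ok = %s\n",
      x$certificate$is_Z, x$certificate$rho, x$certificate$witness_ok
    ))
  }
  invisible(x)
}

#' @export
tidy.organics_stability <- function(x, ...) {
  out <- tibble::tibble(
    source = "jacobian",
    re = Re(x$eigenvalues), im = Im(x$eigenvalues)
  )
  if (!is.null(x$qep_eigenvalues)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      source = "qep",
      re = Re(x$qep_eigenvalues), im = Im(x$qep_eigenvalues)
    ))
  }
  out
}

#' @export
glance.organics_stability <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    max_real = x$max_real,
    stable = x$stable,
    diverged = x$diverged,
    residual = x$fixed_point$residual,
    rho = if (!is.null(x$certificate)) x$certificate$rho else NA_real_,
    is_Z = if (!is.null(x$certificate)) x$certificate$is_Z else NA,
    is_M_matrix = if (!is.null(x$certificate)) x$certificate$is_M_matrix else NA,
    witness_ok = if (!is.null(x$certificate)) x$certificate$witness_ok else NA
  )
}
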