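#' Lyapunov energy of the identity-recurrence circuit
#'
#' In the vicinity of its normalization fixed point, the circuit with
#' identity recurrence behaves as a set of coupled damped harmonic
#' oscillators and admits an energy (Lyapunov) function
#'
#' \deqn{V(y, a) = \sum_i \frac{t_i}{a_{s,i} y_{s,i}^2}
#'   \left[\frac{\tau_{y,i}}{\tau_{a,i}} a_{s,i} (y_i - y_{s,i})^2 +
#'   (a_i y_i - a_{s,i} y_{s,i})^2\right]}
#'
#' where `t_i` are the diagonal Lyapunov weights from the M-matrix
#' certificate. Each neuron contributes two residuals: a normalization
#' term penalizing departure of the response from its divisively
#' normalized steady state, and an input-matching term penalizing
#' mismatch between the gated response `a_i y_i` and the input drive
#' `b_i z_i` (which equals `a_{s,i} y_{s,i}` at steady state). The ratio
#' `tau_y/tau_a` sets how much each neuron weights normalization relative
#' to input matching. `V` is zero exactly at the fixed point, positive
#' nearby, and non-increasing along trajectories close to it.
#'
#' Channels with zero input drive (`y_s = 0`) have no normalized scale;
#' their terms are skipped with a warning.
#'
#' @inheritParams analytic_fixed_point
#' @param state An [organics_state()] at which to evaluate the energy.
#' @param T_diag Optional positive weights `t_i`; defaults to the diagonal
#'   Lyapunov witness computed by [splitting_certificate()].
#' @return An `organics_energy` list: scalar `V`, the weights used, and a
#'   per-neuron tibble `terms` with columns `normalization`, `matching`,
#'   `total`.
#' @export
#' @examples
#' p <- organics_params(n = 1, b = 0.5, b0 = 0.5, sigma = 0.1)
#' energy_identity(p, z = 1, organics_state(1, 1))$V
energy_identity <- function(params, z, state, T_diag = NULL) {
  z <- recycle_z(z, params$n)
  fp <- analytic_fixed_point(params, z)
  if (is.null(T_diag)) {
    T_diag <- splitting_certificate(qep_matrices(params, z))$T_diag
  }
  live <- fp$y_s != 0
  if (!all(live)) {
    warning("zero-input channels have undefined energy terms; skipped")
  }
  pref <- ifelse(live, T_diag / (fp$a_s * fp$y_s^2), 0)
  norm_term <- pref * (params$tau_y / params$tau_a) * fp$a_s * (state$y - fp$y_s)^2
  match_term <- pref * (state$a * state$y - fp$a_s * fp$y_s)^2
  terms <- tibble::tibble(
    neuron = seq_len(params$n),
    weight = T_diag,
    normalization = norm_term,
    matching = match_term,
    total = norm_term + match_term
  )
  structure(list(V = sum(terms$total), T_diag = T_diag, terms = terms),
            class = "organics_energy")
}

#' Energy of the two-dimensional circuit
#'
#' The scalar specialization of the circuit energy: with one principal
#' and one modulator neuron,
#' `V(y, a) = (tau_y/tau_a) * a_s * (y - b z / a_s)^2 + (a y - b z)^2`,
#' where `a_s = sqrt(b0^2 sigma^2 + w b^2 z^2)` is the steady modulator
#' level. The first term drives the response toward its divisively
#' normalized value, the second drives the instantaneously gated response
#' `a y` toward the input drive `b z`; weaker inputs weight matching more,
#' stronger inputs engage normalization.
#'
#' @param params An [organics_params()] with `n = 1`.
#' @param z Scalar input drive.
#' @param state An [organics_state()] with scalar entries.
#' @return An `organics_energy` list (as in [energy_identity()]).
#' @export
energy_2d <- function(params, z, state) {
  stopifnot(params$n == 1)
  z <- as.numeric(z)[1]
  bz <- params$b[1] * z
  a_s <- sqrt(params$b0[1]^2 * params$sigma[1]^2 + params$W[1, 1] * bz^2)
  norm_term <- (params$tau_y[1] / params$tau_a[1]) * a_s * (state$y[1] - bz / a_s)^2
  match_term <- (state$a[1] * state$y[1] - bz)^2
  terms <- tibble::tibble(
    neuron = 1L, weight = 1,
    normalization = norm_term, matching = match_term,
    total = norm_term + match_term
  )
  structure(list(V = norm_term + match_term, T_diag = 1, terms = terms),
            class = "organics_energy")
}

#' @export
print.organics_energy <- function(x, ...) {
  cat(sprintf("<organics_energy> V = %.6g (normalization %.3g, matching %.3g)\n",
              x$V, sum(x$terms$normalization), sum(x$terms$matching)))
  invisible(x)
}

#' Energy along a simulated trajectory
#'
#' Evaluates [energy_identity()] at every stored time step of a
#' trajectory; the Lyapunov weights are computed once.
#'
#' @param traj An `organics_trajectory` from [simulate_circuit()].
#' @param params,z The circuit and drive used to produce the trajectory.
#' @return A tibble with columns `t` and `V`.
#' @export
trajectory_energy <- function(traj, params, z) {
  T_diag <- splitting_certificate(qep_matrices(params, z))$T_diag
  y <- attr(traj, "y")
  a <- attr(traj, "a")
  tt <- attr(traj, "t")
  V <- vapply(seq_along(tt), function(i) {
    energy_identity(params, z, organics_state(y[i, ], a[i, ]), T_diag = T_diag)$V
  }, numeric(1))
  tibble::tibble(t = tt, V = V)
}
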