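#' Circuit state at an instant
#'
#' Membrane potentials (relative to an arbitrary threshold, so possibly
#' negative) of the principal (`y`) and modulator (`a`) populations.
#'
#' @param y,a Finite numeric vectors of equal length.
#' @return An `organics_state` list.
#' @export
organics_state <- function(y, a) {
  y <- as.numeric(y); a <- as.numeric(a)
  if (length(y) != length(a)) stop("`y` and `a` must have equal length")
  if (!all(is.finite(y), is.finite(a))) stop("state entries must be finite")
  structure(list(y = y, a = a), class = "organics_state")
}

# elementwise halfwave rectification; the one-sided value at 0 is 0
relu <- function(x) pmax(x, 0)

#' Input drive from an external input
#'
#' The circuit receives a weighted encoding `z = W_zx x` of the external
#' input `x`. When no encoding matrix is present the input passes through
#' unchanged (and must already have length `n`).
#'
#' @param x External input vector (length `m`).
#' @param params An [organics_params()] object.
#' @return Length-`n` drive vector `z`.
#' @export
#' @examples
#' p <- organics_params(n = 2)
#' input_drive(c(0.3, -0.4), p)
input_drive <- function(x, params) {
  x <- as.numeric(x)
  if (is.null(params$W_zx)) {
    if (length(x) != params$n) stop("input length must equal n when `W_zx` is absent")
    return(x)
  }
  if (length(x) != ncol(params$W_zx)) stop("input length must match ncol(W_zx)")
  drop(params$W_zx %*% x)
}

#' Firing rates from membrane potentials
#'
#' Principal neurons come in complementary on/off pairs described by a
#' single membrane potential: the pair's rates are the rectified squares
#' `y_plus = max(y, 0)^2` and `y_minus = max(-y, 0)^2`, so at most one of
#' the two fires and `y_plus + y_minus = y^2`. Modulator rates are
#' halfwave-rectified, `a_plus = max(a, 0)`.
#'
#' @param state An [organics_state()].
#' @return A tibble with one row per neuron: columns `y_plus`, `y_minus`,
#'   `a_plus`.
#' @export
firing_rates <- function(state) {
  tibble::tibble(
    neuron = seq_along(state$y),
    y_plus = relu(state$y)^2,
    y_minus = relu(-state$y)^2,
    a_plus = relu(state$a)
  )
}

# shared modulator derivative: da = (-a + sqrt(b0^2 sigma^2 + W (y^2 a+^2))) / tau_a
# The sqrt argument is >= b0^2 sigma^2 > 0 because W >= 0.
modulator_rhs <- function(y, a, params) {
  ap <- relu(a)
  g <- params$b0^2 * params$sigma^2 + drop(params$W %*% (y^2 * ap^2))
  (-a + sqrt(g)) / params$tau_a
}

#' Time derivatives of the circuit state
#'
#' The three dynamical variants share the modulator equation
#' `tau_a * da/dt = -a + sqrt(b0^2 sigma^2 + W(y^2 * max(a,0)^2))` and
#' differ in the principal-neuron equation:
#'
#' * `"identity"` — identity recurrence, simplified to
#'   `tau_y * dy/dt = -max(a,0)*y + b*z`;
#' * `"general"` — arbitrary recurrence,
#'   `tau_y * dy/dt = -y + b*z + (1 - max(a,0)) * (W_r y)`;
#' * `"rectified"` — as `"general"` but the lateral drive is computed from
#'   rectified potentials, `W_r max(y, 0)`, keeping the recurrent input a
#'   function of nonnegative firing activity.
#'
#' The recurrent gain `1 - max(a, 0)` is how the modulators implement the
#' normalization denominator: stronger pooled activity shuts the gain and
#' divides the response.
#'
#' @param state An [organics_state()].
#' @param params An [organics_params()].
#' @param z Length-`n` input drive (see [input_drive()]).
#' @param variant One of `"identity"`, `"general"`, `"rectified"`.
#' @return A list with elements `dy` and `da` (length-`n` derivatives,
#'   per ms).
#' @export
#' @examples
#' p <- organics_params(n = 1, b = 0.5, b0 = 0.5, sigma = 0.1)
#' circuit_rhs(organics_state(1, 1), p, z = 1, variant = "general")
circuit_rhs <- function(state, params, z,
                        variant = c("identity", "general", "rectified")) {
  variant <- match.arg(variant)
  y <- state$y; a <- state$a
  z <- as.numeric(z)
  if (length(z) == 1 && params$n > 1) z <- rep(z, params$n)
  stopifnot(length(z) == params$n)
  ap <- relu(a)
  dy <- switch(variant,
    identity = (-ap * y + params$b * z) / params$tau_y,
    general = (-y + params$b * z + (1 - ap) * drop(params$W_r %*% y)) / params$tau_y,
    rectified = (-y + params$b * z + (1 - ap) * drop(params$W_r %*% relu(y))) / params$tau_y
  )
  list(dy = dy, da = modulator_rhs(y, a, params))
}

#' @rdname circuit_rhs
#' @export
rhs_identity <- function(state, params, z) circuit_rhs(state, params, z, "identity")

#' @rdname circuit_rhs
#' @export
rhs_general <- function(state, params, z) circuit_rhs(state, params, z, "general")

#' @rdname circuit_rhs
#' @export
rhs_rectified <- function(state, params, z) circuit_rhs(state, params, z, "rectified")

# max-norm of the state derivative: the residual used by all fixed-point code
rhs_residual <- function(y, a, params, z, variant) {
  d <- circuit_rhs(organics_state(y, a), params, z, variant)
  max(abs(c(d$dy, d$da)))
}
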