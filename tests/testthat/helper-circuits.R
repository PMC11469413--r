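# shared fixtures: parameter sets from the three 2D phase-portrait regimes
# (all share b = 0.5, tau = 2 ms, w = 1, z = 1)
params_2d <- function(wr, b0, sigma) {
  organics_params(n = 1, tau_y = 2, tau_a = 2, b = 0.5, b0 = b0,
                  sigma = sigma, W_r = wr, W = 1)
}
p2d_contractive <- function() params_2d(wr = 0.5, b0 = 0.5, sigma = 0.1) # fig-a regime
p2d_expansive_low <- function() params_2d(wr = 2, b0 = 0.5, sigma = 0.1) # fig-b regime
p2d_expansive_high <- function() params_2d(wr = 2, b0 = 1, sigma = 1)    # fig-c regime

# central-difference Jacobian of the chosen RHS: the independent oracle
# against which the analytic Jacobian is checked
fd_jacobian <- function(params, z, y, a, variant, h = 1e-6) {
  n <- params$n
  f <- function(x) {
    d <- circuit_rhs(organics_state(x[1:n], x[n + 1:n]), params, z, variant)
    c(d$dy, d$da)
  }
  x0 <- c(y, a)
  J <- matrix(0, 2 * n, 2 * n)
  for (j in seq_len(2 * n)) {
    e <- rep(0, 2 * n)
    e[j] <- h
    J[, j] <- (f(x0 + e) - f(x0 - e)) / (2 * h)
  }
  J
}

max_re_jacobian <- function(params, z, fp, variant) {
  J <- suppressWarnings(circuit_jacobian(params, z, fp, variant))
  max(Re(eigen(J, only.values = TRUE)$values))
}

# identity-recurrence version of a sampled circuit
identity_circuit <- function(n, seed, smax_w = 1) {
  s <- sample_random_circuit(n, smax = smax_w, seed = seed)
  s$params$W_r <- diag(n)
  s
}
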