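test_that("analytic Jacobians agree with central finite differences", {
  for (variant in c("identity", "general", "rectified")) {
    for (k in 1:5) {
      s <- sample_random_circuit(4, smax = 0.8, seed = 40 + k)
      p <- if (variant == "identity") {
        p <- s$params
        p$W_r <- diag(4)
        p
      } else {
        s$params
      }
      fp <- fixed_point_iteration(p, s$z, tol = 1e-10)
      J <- suppressWarnings(circuit_jacobian(p, s$z, fp, variant))
      Jfd <- fd_jacobian(p, s$z, fp$y_s, fp$a_s, variant)
      expect_lt(max(abs(J - Jfd)) / (1 + max(abs(J))), 1e-6)
    }
  }
})

test_that("decoupled circuit has the hand-derived block-diagonal spectrum", {
  # z = 0, W = 0: y-block eigenvalues -b0*sigma/tau_y, a-block -1/tau_a
  p <- organics_params(n = 2, tau_y = c(2, 4), tau_a = c(3, 6),
                       b0 = c(0.5, 0.8), sigma = c(0.4, 0.2),
                       W = matrix(0, 2, 2))
  fp <- analytic_fixed_point(p, z = c(0, 0))
  ev <- sort(Re(eigen(circuit_jacobian(p, c(0, 0), fp, "identity"))$values))
  expected <- sort(c(-p$b0 * p$sigma / p$tau_y, -1 / p$tau_a))
  expect_equal(ev, expected, tolerance = 1e-12)
})

test_that("QEP matrices match the worked scalar case and stay Z-matrices", {
  p <- organics_params(n = 1, b = 0.5, b0 = 0.5, sigma = 0.1)
  q <- qep_matrices(p, z = 1)
  a_s <- sqrt(0.2525)
  y_s <- 0.5 / a_s
  expect_equal(q$K[1, 1], a_s / 4, tolerance = 1e-12)
  expect_equal(q$B[1, 1], 0.5 + a_s / 2 - y_s^2 / 2, tolerance = 1e-12)

  # W = 0 leaves a positive diagonal damping matrix
  p0 <- organics_params(n = 3, W = matrix(0, 3, 3))
  q0 <- qep_matrices(p0, z = c(1, -1, 0.5))
  expect_equal(q0$B3, matrix(0, 3, 3))
  expect_true(all(diag(q0$B) > 0))

  # off-diagonal entries are never positive, for any draw
  for (k in 1:20) {
    s <- identity_circuit(6, seed = 2000 + k)
    q <- qep_matrices(s$params, s$z)
    off <- q$B - diag(diag(q$B))
    expect_true(all(off <= 1e-14))
  }
})

test_that("QEP roots reproduce the Jacobian spectrum as multisets", {
  # scalar case: quadratic formula
  p <- organics_params(n = 1, b = 0.5, b0 = 0.5, sigma = 0.1, tau_y = 3, tau_a = 5)
  q <- qep_matrices(p, z = 1)
  b_c <- q$B[1, 1]
  k_c <- q$K[1, 1]
  manual <- (-b_c + c(1, -1) * sqrt(as.complex(b_c^2 - 4 * k_c))) / 2
  expect_lt(eigen_multiset_error(qep_eigenvalues(q), manual), 1e-10)

  # undamped system oscillates at unit frequency
  qi <- list(B = matrix(0, 2, 2), K = diag(2))
  expect_lt(eigen_multiset_error(qep_eigenvalues(qi), c(1i, 1i, -1i, -1i)), 1e-10)

  # random circuits: companion roots == Jacobian eigenvalues
  for (k in 1:25) {
    s <- identity_circuit(6, seed = 2100 + k)
    fp <- analytic_fixed_point(s$params, s$z)
    ev_j <- eigen(circuit_jacobian(s$params, s$z, fp, "identity"))$values
    ev_q <- qep_eigenvalues(qep_matrices(s$params, s$z))
    expect_lt(eigen_multiset_error(ev_j, ev_q), 1e-6)
  }
})

test_that("the M-matrix splitting certificate holds unconditionally", {
  # W = 0: trivial certificate
  p0 <- organics_params(n = 2, W = matrix(0, 2, 2))
  c0 <- splitting_certificate(qep_matrices(p0, c(1, 2)))
  expect_equal(c0$rho, 0)
  expect_true(c0$is_M_matrix)

  # scalar case has the closed-form contraction ratio
  p <- organics_params(n = 1, b = 0.5, b0 = 0.5, sigma = 0.1, tau_y = 3, tau_a = 5)
  fp <- analytic_fixed_point(p, 1)
  cert <- splitting_certificate(qep_matrices(p, 1))
  expect_equal(cert$rho, fp$y_s^2 / (1 + (5 / 3) * fp$a_s), tolerance = 1e-12)
  expect_lt(cert$rho, 1)

  # any identity-recurrence draw: Z-matrix, convergent splitting,
  # positive diagonal Lyapunov witness, stable spectrum
  for (k in 1:30) {
    s <- identity_circuit(8, seed = 2200 + k, smax_w = 2)
    rep <- assess_stability(s$params, s$z)
    expect_true(rep$certificate$is_Z)
    expect_lt(rep$certificate$rho, 1)
    expect_true(rep$certificate$witness_ok)
    expect_lt(rep$max_real, 0)
    expect_true(rep$stable)
  }
})

test_that("the contraction ratio survives the large-input limit", {
  for (k in 1:5) {
    s <- identity_circuit(6, seed = 2300 + k)
    cert <- splitting_certificate(qep_matrices(s$params, s$z * 1e6))
    expect_lt(cert$rho, 1)
    expect_true(cert$witness_ok)
  }
})

test_that("rank-one closed form matches the generic QEP solver", {
  for (n in c(2, 3, 5, 10)) {
    set.seed(n)
    p <- organics_params(n = n, tau_y = 3, tau_a = 7, b = 0.8, b0 = 0.6,
                         sigma = 0.4, W = matrix(0.7, n, n))
    z <- rnorm(n, sd = 0.5)
    e_closed <- special_case_eigenvalues(p, z)
    e_generic <- qep_eigenvalues(qep_matrices(p, z))
    expect_lt(eigen_multiset_error(e_closed, e_generic), 1e-8)
  }

  # alpha = 0 decouples every pair into the same quadratic
  p0 <- organics_params(n = 3, tau_y = 2, tau_a = 4, b = 1, b0 = 0.5,
                        sigma = 0.8, W = matrix(0, 3, 3))
  e0 <- special_case_eigenvalues(p0, c(1, -0.5, 0.2))
  expect_equal(length(unique(round(e0, 10))), 2)

  # underdamped parameters give conjugate pairs
  pu <- organics_params(n = 2, tau_y = 5, tau_a = 5, b = 1, b0 = 0.5,
                        sigma = 1, W = matrix(0.5, 2, 2))
  eu <- special_case_eigenvalues(pu, c(0.866, 0.866))
  expect_true(any(abs(Im(eu)) > 1e-8))
  expect_lt(max(abs(sort(Im(eu)) + rev(sort(Im(eu))))), 1e-10)
})

test_that("stability assessment flags expansive recurrence when it bites", {
  # contractive 2D regime: stable
  rep_b <- assess_stability(p2d_expansive_low(), 1, variant = "general")
  expect_true(rep_b$stable)

  # strongly expansive random recurrence: some draws are unstable
  res <- vapply(1:15, function(k) {
    s <- sample_random_circuit(10, smax = 3, seed = 2400 + k)
    rep <- assess_stability(s$params, s$z, variant = "general")
    rep$stable
  }, logical(1))
  expect_true(any(!res))
})
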