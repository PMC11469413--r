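test_that("integration preserves fixed points and converges to them", {
  s <- identity_circuit(4, seed = 4000)
  p <- s$params
  fp <- analytic_fixed_point(p, s$z)
  tau_min <- min(c(p$tau_y, p$tau_a))

  # started at the fixed point, the state stays there
  tr <- suppressWarnings(simulate_circuit(
    p, s$z, organics_state(fp$y_s, fp$a_s),
    dt = tau_min / 10, t_end = 5 * max(p$tau_y), method = "rk4"
  ))
  fs <- final_state(tr)
  expect_lt(max(abs(fs$y - fp$y_s), abs(fs$a - fp$a_s)), 1e-9)

  # perturbed start relaxes back (identity recurrence is globally
  # attracting); the relevant horizon is set by the *effective* time
  # constants tau_y / a_s, which stretch when the modulators sit low
  t_relax <- 50 * max(c(p$tau_y / fp$a_s, p$tau_a))
  tr2 <- suppressWarnings(simulate_circuit(
    p, s$z, organics_state(fp$y_s + 0.2, fp$a_s + 0.2),
    dt = tau_min / 10, t_end = t_relax,
    method = "rk4", record_every = 50
  ))
  fs2 <- final_state(tr2)
  expect_false(attr(tr2, "diverged"))
  expect_lt(max(abs(fs2$y - fp$y_s), abs(fs2$a - fp$a_s)), 1e-6)
})

test_that("integrators show their theoretical order on a smooth segment", {
  p <- organics_params(n = 1, tau_y = 2, tau_a = 2, b = 0.5, b0 = 0.5,
                       sigma = 0.5)
  init <- organics_state(0.3, 0.4)
  ref <- final_state(simulate_circuit(p, 1, init, dt = 1e-4, t_end = 2,
                                      method = "rk4", record_every = 1e5))
  err <- function(method, dt) {
    fs <- final_state(simulate_circuit(p, 1, init, dt = dt, t_end = 2,
                                       method = method, record_every = 1e5))
    max(abs(fs$y - ref$y), abs(fs$a - ref$a))
  }
  r_euler <- err("euler", 0.02) / err("euler", 0.01)
  r_rk4 <- err("rk4", 0.04) / err("rk4", 0.02)
  expect_gt(r_euler, 1.7)
  expect_lt(r_euler, 2.3)
  expect_gt(r_rk4, 12)
  expect_lt(r_rk4, 20)
})

test_that("divergence is flagged and truncates the trajectory", {
  # strongly expansive recurrence with low normalization floor blows up
  p <- organics_params(n = 1, tau_y = 2, tau_a = 2, b = 0.5, b0 = 0.01,
                       sigma = 0.01, W_r = 5, W = matrix(0, 1, 1))
  tr <- suppressWarnings(simulate_circuit(p, 1, organics_state(1, 0),
                                          dt = 0.1, t_end = 500,
                                          variant = "general"))
  expect_true(attr(tr, "diverged"))
  expect_lt(max(tr$t), 500)
  expect_true(all(is.finite(tr$value)))
})

test_that("a stiff step size triggers a warning", {
  p <- organics_params(n = 1, tau_y = 2, tau_a = 2)
  expect_warning(
    simulate_circuit(p, 1, organics_state(0, 1), dt = 1.5, t_end = 10),
    "dt"
  )
})

test_that("the random-circuit sampler honors its constraints deterministically", {
  for (smax in c(0.5, 1, 2)) {
    s <- sample_random_circuit(12, smax = smax, seed = 123)
    expect_silent(validate_params(s$params))
    expect_equal(max(svd(s$params$W_r)$d), smax, tolerance = 1e-10)
    expect_lte(sqrt(sum(s$z^2)), 1)
    expect_true(all(s$params$tau_y >= 1 & s$params$tau_y <= 100))
    expect_true(all(s$params$b >= 0.1 & s$params$b <= 2))
  }
  s1 <- sample_random_circuit(6, smax = 1, seed = 77)
  s2 <- sample_random_circuit(6, smax = 1, seed = 77)
  expect_identical(s1, s2)
})

test_that("sweeps are reproducible and identity recurrence is always stable", {
  sw1 <- stability_sweep(n = 5, n_trials = 15, smax = 1, seed = 9)
  sw2 <- stability_sweep(n = 5, n_trials = 15, smax = 1, seed = 9)
  expect_equal(as.data.frame(sw1), as.data.frame(sw2))
  expect_equal(glance(sw1)$fraction_stable, mean(sw1$stable))

  # the certificate regime: stable no matter how strong the normalization
  # weights are (only W_r is constrained by the conjecture, not W)
  for (smax_w in c(1, 3)) {
    swi <- stability_sweep(n = 5, n_trials = 15, smax = smax_w, seed = 11,
                           identity_recurrence = TRUE)
    expect_equal(glance(swi)$fraction_stable, 1)
  }
})

test_that("phase portraits carry consistent fields, nullclines and fixed points", {
  pp <- phase_portrait_2d(p2d_contractive(), z = 1, grid_n = 11)
  expect_equal(nrow(pp$fixed_points), 1)
  expect_true(pp$fixed_points$stable)

  # the sampled field matches the RHS at a grid point
  row <- pp$field[17, ]
  d <- circuit_rhs(organics_state(row$y, row$a), p2d_contractive(), 1, "general")
  expect_equal(row$dy, d$dy)
  expect_equal(row$da, d$da)

  # on the y-nullcline the y-component of the field vanishes
  ync <- pp$nullclines[pp$nullclines$which == "y-nullcline", ]
  expect_gt(nrow(ync), 0)
  mid <- ync[round(nrow(ync) / 2), ]
  dmid <- circuit_rhs(organics_state(mid$y, mid$a), p2d_contractive(), 1, "general")
  expect_lt(abs(dmid$dy), 1e-2)

  # expansive regime overlays the unstable points found by the scan
  ppb <- phase_portrait_2d(p2d_expansive_low(), z = 1, grid_n = 11)
  expect_true(any(ppb$fixed_points$stable))
  expect_true(all(c("stable", "unstable") %in%
    c(ppb$fixed_points$classification, "stable", "unstable")))

  plt <- autoplot(pp)
  expect_s3_class(plt, "ggplot")
})

test_that("trajectory objects are tidy and plottable", {
  p <- organics_params(n = 2, b = 0.5, b0 = 0.5, sigma = 0.3)
  tr <- suppressWarnings(simulate_circuit(p, c(1, 0.5), organics_state(c(0, 0), c(0.2, 0.2)),
                                          dt = 0.2, t_end = 10))
  expect_s3_class(tr, "tbl_df")
  expect_named(tr, c("t", "population", "neuron", "value"))
  expect_setequal(unique(tr$population), c("y", "a"))
  expect_s3_class(autoplot(tr), "ggplot")
})
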