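# organicsr

Simulation, equilibrium analysis and stability certification for a
recurrent cortical circuit that implements **divisive normalization
dynamically** — plus a discrete-time differentiable version of the
circuit trainable by plain backpropagation through time.

## Who this is for

Computational neuroscientists studying normalization circuits
(contrast response, attention, gain control) who need the steady states
and local stability of the model across parameter regimes; and
ML-adjacent researchers interested in recurrent cells whose stability
comes from circuit dynamics rather than from gradient clipping or
post-hoc normalization layers.

## The model

Two populations of `n` neurons. Principal neurons `y` receive an input
drive `z = W_zx x` with gains `b`, and lateral input `W_r y` gated by
the recurrent gain `1 − ⌊a⌋` (`⌊x⌋ = max(x, 0)`). Modulator neurons `a`
pool rectified-squared principal activity through a nonnegative matrix
`W`:

    τ_y ⊙ dy/dt = −y + b ⊙ z + (1 − ⌊a⌋) ⊙ (W_r y)
    τ_a ⊙ da/dt = −a + sqrt(b0² ⊙ σ² + W (y² ⊙ ⌊a⌋²))

With identity recurrence (`W_r = I`) the circuit has the closed-form
fixed point `a_s = sqrt(b0²⊙σ² + W(b²⊙z²))`, `y_s = b⊙z ⊘ a_s`, where
the steady firing rates `⌊±y_s⌋²` satisfy the divisive normalization
equation exactly. Linearization there reduces to a quadratic eigenvalue
problem `det(λ²I + λB + K) = 0` whose damping matrix `B` is an
M-matrix for every admissible parameter set — the package computes the
convergent-splitting and diagonal-Lyapunov certificates that make the
fixed point's asymptotic stability unconditional, the associated energy
(Lyapunov) function, closed-form eigenvalues for the uniform-pool
special case, iterative and Newton equilibrium solvers for arbitrary
`W_r`, exhaustive 2D fixed-point enumeration with phase portraits,
randomized stability sweeps, and an Euler-discretized rectified cell
with dynamic input gains trained by naive BPTT.

## Worked example

```r
library(organicsr)

p <- organics_params(n = 3, tau_y = 2, tau_a = 4, b = 0.8, b0 = 0.6,
                     sigma = 0.3, W = matrix(1/3, 3, 3))
z <- c(1, 0.4, -0.6)

analytic_fixed_point(p, z)
#> <organics_fp> method = analytic, n_iter = 0, residual = 0, converged = TRUE
#>   y_s: 1.33955 0.53582 -0.80373
#>   a_s: 0.597216 0.597216 0.597216

assess_stability(p, z)
#> <organics_stability> variant = identity, max Re(lambda) = -0.160659, stable = TRUE
#>   certificate: Z-matrix = TRUE, rho(S) = 0.414303, diagonal witness ok = TRUE
```

Reading this: all three modulators settle at the same pooled level
`a_s ≈ 0.597` (uniform pool), each principal neuron's response is its
gated drive divided by that level (neuron 3 is negative because its
drive is), the slowest linearized mode decays at rate `0.16/ms`, and
the two stability certificates hold — the damping matrix has
nonpositive off-diagonals with a convergent regular splitting
(`ρ(S) ≈ 0.41 < 1`) and a positive diagonal Lyapunov witness.

Everything returns tidy objects: `tidy()` gives per-neuron or
per-eigenvalue tibbles, `glance()` one-row summaries, and `autoplot()`
draws trajectories, phase portraits, sweep histograms and training
curves. A command-line front end over the same functions is in
`inst/cli/organics.R` (subcommands `fixedpoints`, `stability`,
`simulate`, `phase`, `sweep`, `energy`, `train-toy`), with parameter
sets as JSON via `read_params_json()` / `write_params_json()`.

```r
# 2D phase portrait with enumerated fixed points
p2 <- organics_params(n = 1, tau_y = 2, tau_a = 2, b = 0.5, b0 = 0.5,
                      sigma = 0.1, W_r = 2, W = 1)
find_fixed_points_2d(p2, z = 1)      # 3 fixed points, the positive one stable
autoplot(phase_portrait_2d(p2, z = 1))

# train the discrete cell by plain SGD, no gradient clipping
tt <- train_toy("delayed-recall", steps = 300, lr = 0.05, seed = 0)
glance(tt)[, c("initial_loss", "final_loss", "final_accuracy")]
#> # A tibble: 1 × 3
#>   initial_loss final_loss final_accuracy
#>          <dbl>      <dbl>          <dbl>
#> 1         1.39    0.00802              1
```

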