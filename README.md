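# odestep

Parameter and initial-value estimation for ordinary differential
equation (ODE) models observed with additive measurement noise, using the
**one-step efficient estimator**: a nonparametric smoother supplies a
√n-consistent preliminary estimate, and a single Newton/Levenberg–Marquardt
correction based on the sensitivity equations upgrades it to the
asymptotic efficiency of full nonlinear least squares (NLS) — at the cost
of *one* integration of the model and its sensitivity system instead of a
long iterative search.

The package is aimed at systems biologists, chemical kineticists and
statisticians who fit mechanistic models
`x'(t) = F(x, θ), x(t₁) = ξ` to time-course data and want NLS-quality
point and interval estimates without NLS's starting-value and runtime
headaches.

## The method in brief

For data `Y_ij = x_i(η₀, t_j) + ε_ij` with `η = (ξ, θ)`:

1. **Smooth** each observed state by local quadratic regression to get
   `x̂(t)` and `x̂'(t)`.
2. **Preliminary estimate** `η̂`: the *integral estimator* (match `x̂(t)`
   against `ξ + ∫ F(x̂; θ)`) or the *smooth-and-match estimator* (match
   `x̂'(t)` against `F(x̂; θ)`); both are closed-form linear least squares
   when `F` is linear in `θ`.
3. **One-step correction**:
   `η̄ = η̂ + (JᵀJ + λI)⁻¹ Jᵀ r`, with `J` the stacked trajectory
   sensitivities `∂x/∂η` at `η̂` and `r` the residuals — exactly one
   Levenberg–Marquardt iteration of the least-squares criterion, with the
   damping `λ` escalated until the move decreases the criterion.
4. **Data-driven bandwidth selection**: steps 1–3 run for a grid of
   bandwidths `n^(-1/3)·c`, and the candidate whose corrected estimate
   best fits the data (smallest residual sum of squares of the integrated
   trajectory) is returned.
5. **Inference**: plug-in Fisher-information Wald intervals
   `η̄_j ± z·sqrt((I⁻¹)_jj / n)` with
   `I = σ̂⁻² Σ_i ∫ (dx_i/dη)ᵀ(dx_i/dη) dF_T`.

Six benchmark systems ship in a registry (`registry_names()`): scalar
exponential growth/decay, Lotka–Volterra predator–prey, the stiff
Robertson chemical kinetics, the partially observed Goodwin gene
oscillator, reversible nitrogen-oxide kinetics and the 5-state
alpha-pinene isomerization network. User models plug in via
`define_ode_model()`.

## Worked example

Simulate one noisy Lotka–Volterra dataset (n = 21 equidistant times on
[0, 10], σ = 0.05) and fit all six components of `η = (ξ₁, ξ₂, θ₁…θ₄)`:

```r
library(odestep)
m   <- ode_model("lotka_volterra")
scn <- load_scenario("table2_n21")      # truth: xi = (1, 0.5), theta = (0.5, 0.5, 0.5, 0.5)
ds  <- generate_dataset(scn, replicate = 1)
one_step_fit(m, ds, method = "sme")
#> One-step fit (variant damped, bandwidth 0.8474, sigma2_hat 0.002793, n = 21)
#>  parameter estimate      se    lower    upper
#>       eta1 1.020920 0.02508 0.971762 1.070080
#>       eta2 0.502412 0.02068 0.461872 0.542951
#>       eta3 0.473643 0.02683 0.421061 0.526225
#>       eta4 0.477798 0.02248 0.433747 0.521850
#>       eta5 0.500721 0.02320 0.455252 0.546190
#>       eta6 0.498370 0.02077 0.457661 0.539080
```

The selected bandwidth (0.85 time units) was chosen from the candidate
grid by the residual-fit criterion; every 95% interval covers its true
value, and the standard errors (~0.02–0.027) match the published
asymptotic values for this design. A coverage study over many replicates
is one call:

```r
run_monte_carlo(load_scenario("table2_n51"))   # 500 replicates
```

which prints truth, Monte-Carlo mean, empirical SD ("STE"), mean
estimated asymptotic SD ("ASYM") and 95%-interval coverage per free
parameter. An iterated-NLS baseline (`nls_fit()`, Levenberg–Marquardt
with sensitivity Jacobians) is available for comparison and as the
initializer-quality check (`include_nls = TRUE`).

A thin command-line front end lives in `inst/scripts/odestep`
(`fit` / `simulate` / `mc` subcommands) for shell pipelines.

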