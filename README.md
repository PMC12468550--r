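# tvarnet

Estimation, simulation and forecast benchmarking of **time-varying
autoregressions** — univariate TV-AR and multivariate TV-VAR models in
which the intercept and lag coefficients are smooth functions of time
rather than constants:

$$ y(t) = c(t) + \sum_{k=1}^{r} \alpha_k(t)\,y(t-k) + \phi(t), \qquad
   Y(t) = C(t) + \sum_{k=1}^{r} B_k(t)\,Y(t-k) + \Phi(t). $$

Stationary AR/VAR models assume the dependence structure never changes;
epidemiological, economic and environmental series routinely break that
assumption through structural breaks and drifting regimes.  This package
is for analysts who need to estimate *how* the dependence itself evolves
and to forecast under that evolution.  Four estimators share one
interface:

| method | idea |
|---|---|
| `"pinn"` | a small feed-forward network maps normalized time to the coefficient vector and is trained by minimizing the squared residual of the autoregressive equation itself (the structural equation acts as the physics-style constraint), with L-BFGS-B and backpropagation gradients |
| `"gam"` | each coefficient is a linear combination of smooth basis functions (linear, quadratic, tanh, exponential, Gaussian, cosine), fitted by least squares under an L1 bound on the non-intercept weights |
| `"oks"` | one-sided Gaussian-kernel-weighted least squares at the series endpoint, bandwidth chosen by forward-chaining cross-validation — no look-ahead bias |
| `"stationary"` | constant-coefficient AR/VAR by ordinary least squares, the classical baseline |

Also included: generators for the four synthetic study designs with known
coefficient trajectories (`tvar_scenario()`, `simulate_tvar()`), recursive
multi-step forecasting (`predict()`), full-trajectory roll-forward
reconstruction (`tvar_reconstruct()`), a Monte-Carlo benchmark harness
reporting MAE and the root sample variance of absolute errors
(`tvar_benchmark()`), CSV/JSON input-output and a command-line interface
(`tvar_cli()`, `inst/cli/tvar`).

## Worked example

Simulate a univariate series with a sigmoid-like coefficient drop
(`f(t) = a0 - t/(1 + e^{-10(t-0.5)})`, intercept `t - 0.5`), fit the
network estimator and forecast two steps:

```r
library(tvarnet)
sim <- tvar_scenario(1, n_time = 200, noise_weight = 0.1, seed = 42)
fit <- tvar(sim$series, r = 1, method = "pinn", seed = 42)
fit
#> Time-varying AR(1) fit, method: neural-network (PINN)
#>   200 training points, 1 component
#>   hidden layers [10, 10, 10], activation tanh, final loss 0.008964
predict(fit, h = 2)
#>              y
#> [1,] 0.4811356
#> [2,] 0.4830662
```

The final training loss (0.0090) is essentially the innovation variance
(`(0.1)^2`), i.e. the network explains the series down to the noise
floor.  The fitted trajectories track the generating ones:

```r
cf <- coef(fit, grid = c(0.25, 0.5, 0.75))
cbind(t = c(0.25, 0.5, 0.75), intercept = cf$intercept, lag1 = cf$lag[, 1, 1, 1])
#>         t intercept  lag1
#> [1,] 0.25    -0.280 0.886    # truth: -0.25, 0.897
#> [2,] 0.50    -0.017 0.562    # truth:  0.00, 0.669
#> [3,] 0.75     0.282 0.058    # truth:  0.25, 0.224
```

A small benchmark (10 replications; the study size is 50) compares the
network against the stationary baseline on this design — MAE is the mean
absolute forecast error at the given horizon across replications, RSV the
standard deviation of those absolute errors:

```r
tvar_benchmark(scenarios = 1, methods = c("stationary", "pinn"),
               lags = 1, horizons = c(1, 2), reps = 10, base_seed = 1)
#> Forecast benchmark: 10 replications, base seed 1
#>  scenario     method lag horizon     mae     rsv n_ok
#>         1 stationary   1       1 0.17580 0.13160   10
#>         1 stationary   1       2 0.27990 0.14030   10
#>         1       pinn   1       1 0.08725 0.06305   10
#>         1       pinn   1       2 0.10010 0.07849   10
```

The time-varying estimator roughly halves the one-step error of the
stationary fit, which can only average over the coefficient's transit.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/tvar simulate --scenario 1 --T 200 --seed 7 --out s.csv --truth-out truth.csv
Rscript inst/cli/tvar fit s.csv --method pinn --lags 1 --seed 7 --out fit.json
Rscript inst/cli/tvar forecast --fit fit.json --horizon 2
Rscript inst/cli/tvar benchmark --scenarios 1 --methods stationary,gam --reps 10 --seed 1
```

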