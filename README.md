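# trajsurv

Tools for studying how a noisily measured longitudinal biomarker drives a
time-to-event hazard, built for biostatisticians comparing estimators of
the *link parameter* that couples the two processes.

A subject's biomarker follows a linear random-intercept/random-slope
trajectory

```
Y_ij = Y*_i(t_ij) + e_ij,            e_ij ~ N(0, sigma^2)
Y*_i(t) = (b0 + U1_i) + (b1 + U2_i) t + b_age Age_i,   (U1, U2) ~ N(0, G)
```

and the event hazard depends on the current latent value through the link
parameter gamma:

```
h_i(t) = lam * nu * t^(nu-1) * exp{ a1 Age_i + a2 Sex_i + gamma * Y*_i(t) }
```

gamma is the log hazard ratio per unit of the current trajectory value.
The package provides:

* **Simulator** — event times drawn in closed form by inverting the
  plug-in cumulative hazard with the principal Lambert-W branch
  (`survival_time_exponential`, `survival_time_weibull`,
  `generate_dataset`), baseline-scale calibration to a target censoring
  fraction (`calibrate_lambda`), and an alternative self-consistent scheme
  that numerically inverts the exact integrated hazard.
* **Four estimators of gamma** — `fit_tdcm` (time-dependent Cox,
  last-value-carried-forward), `fit_tsa` (two-step regression calibration:
  mixed model, then Cox on predicted trajectories at event times),
  `fit_mla` (maximum-likelihood Weibull shared-parameter joint model with
  adaptive Gauss-Hermite quadrature and a hybrid ECM/quasi-Newton
  optimizer), and `fit_bsjm` (Bayesian joint model by
  Metropolis-within-Gibbs).
* **Study harness** — `scenario_config` / `run_scenario` compute Type I
  error, bias, coverage and MSE over replicate grids with deterministic
  seeding.

See the vignette (`vignettes/joint-modeling.Rmd`) for the models,
numerical methods and design choices.

## Worked example

```r
library(trajsurv)

params <- gen_params(n = 200, gamma = 0.5)              # Framingham-like panel
params$lam <- calibrate_lambda(params, target_censoring = 0.5, seed = 1)
d <- generate_dataset(params, seed = 2)

fit_tsa(d$panel, d$survival)
#> TSA fit: gamma = 0.4218 (SE 0.2142), 95% CI [0.0020, 0.8416]
#>   age = 0.0550 (0.0157), sex = -0.5604 (0.2052), converged = TRUE
fit_tdcm(d$panel, d$survival)
#> TDCM fit: gamma = 0.2845 (SE 0.1692), 95% CI [-0.0471, 0.6161]
#>   age = 0.0622 (0.0141), sex = -0.5620 (0.2054), converged = TRUE
fit_mla(d$panel, d$survival)
#> MLA fit: gamma = 0.4853 (SE 0.1590), 95% CI [0.1736, 0.7969]
#>   age = 0.0515 (0.0128), sex = -0.5555 (0.2041), converged = TRUE
```

The pattern is the method comparison in miniature: the LVCF Cox fit
(TDCM) attenuates the true link 0.5 toward zero because it plugs noisy,
stale measurements into the hazard; the two-step fit (TSA) largely removes
the attenuation by using model-predicted trajectory values at event times;
the joint ML fit (MLA) uses both sources of information at once and here
lands closest to the truth with the smallest standard error. Age and sex
effects recover their generating values (0.050, -0.500).

Real panels enter through the CSV adapter: `read_long_panel()` (columns
id, time, y, age, sex — remappable) plus `read_survival()` (id, time,
event).

A command-line front end is installed with the package
(`system.file("cli", "trajsurv", package = "trajsurv")`) with
`simulate`, `fit` and `study` subcommands.

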