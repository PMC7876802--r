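---
title: "Linking longitudinal trajectories to survival: models, simulator and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking longitudinal trajectories to survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

A biomarker measured repeatedly over follow-up (say, a log-transformed lipid
level at successive exams) may drive the hazard of a clinical event. The
measurements are noisy and stop at the event, so putting the raw values into
a time-dependent Cox model attenuates the association, while modeling the
latent trajectory raises the classic joint-modeling questions: how much is
gained by full joint likelihood, and how much is lost by simpler two-step
plug-in strategies? `trajsurv` provides the machinery to study this
question by simulation and to fit all four competing estimators to a given
panel.

# Model

Subject $i$ has exam-time measurements
$$Y_{ij} = Y_i^*(t_{ij}) + \epsilon_{ij}, \qquad \epsilon_{ij} \sim N(0, \sigma^2),$$
with a linear latent trajectory
$$Y_i^*(t) = (\beta_0 + U_{1i}) + (\beta_1 + U_{2i})\,t + \beta_{age} Age_i,
\qquad (U_{1i}, U_{2i}) \sim N(0, G),$$
and the event hazard depends on the *current* latent value through the link
parameter $\gamma$:
$$h_i(t) = h_0(t)\, \exp\{\alpha_1 Age_i + \alpha_2 Sex_i + \gamma\, Y_i^*(t)\}.$$
$\gamma$ is the log hazard ratio per unit of the current trajectory value.
The baseline hazard is Weibull, $h_0(t) = \lambda \nu t^{\nu-1}$
($\nu = 1$: Exponential), except in the Bayesian fit where it is constant
(see below).

# The simulator

`gen_params()` + `generate_dataset()` emulate a Framingham-style panel:

* 6 exams at times 0, 4, ..., 20 years (4-year spacing typical of repeated
  cohort exams); configurable.
* Baseline age $\sim N(43.3, 9.58^2)$ truncated to (25, 75); sex
  $\sim$ Bernoulli(0.512) (1 = female). The truncation avoids implausible
  tails; the moments match the cohort the panel imitates.
* Random effects around means (4.250, 0.250) with covariance
  $G = \begin{pmatrix} 0.29 & -0.00465 \\ -0.00465 & 0.00032\end{pmatrix}$,
  residual variance $\sigma^2 = 0.1161$ by default.
* Survival coefficients $\alpha_1 = 0.050$, $\alpha_2 = -0.500$; censoring
  $\sim U(25, 30)$ years with an administrative cut-off at 30.
* The age coefficient inside the trajectory defaults to
  `beta_age_long = 0.050`. The generating tables that the defaults emulate
  print a single age coefficient in the survival block only, so the
  longitudinal value is a package choice (same magnitude), kept as an
  explicit knob.
* The Weibull shape defaults to $\nu = 1.5$ — a moderately increasing
  hazard, plausible for cardiovascular events in mid-life; the sources the
  scenarios emulate do not print the value, so it too is a knob.

**Event times.** The default scheme (`scheme = "table1"`) draws
$M \sim U(0,1)$ and solves the *plug-in* cumulative-hazard equation
$$\lambda T^{\nu} \exp\{X'\beta + \gamma (U_1 + U_2 T)\} = -\log M$$
in closed form on the principal Lambert branch: with
$c = \gamma U_2 / \nu$ and
$A = \{-\log M / (\lambda e^{X'\beta + \gamma U_1})\}^{1/\nu}$,
$T = W_0(cA)/c$ (limit $T = A$ as $c \to 0$; the $|c| \le 10^{-10}$
branch guards Lambert-argument underflow). When $cA < -1/e$ — possible only
for $\gamma U_2 < 0$, a hazard decaying too fast to ever reach the target
level — the event is unreachable and the subject ends censored.

Note that the plug-in expression is *not* the integral of the hazard above:
$\frac{d}{dt}[\lambda t^\nu e^{\gamma U_2 t}] \ne h(t)$. The package
implements the closed form exactly as the generation scheme it reproduces
prescribes, and keeps the discrepancy deliberately: the joint ML fitter
integrates the hazard properly, so the default scheme is *misspecified for
every estimator*, which is precisely the comparison of interest (and a
plausible mechanism for the joint model's upward bias in that setting). The
alternative `scheme = "rizopoulos"` inverts the exact integrated hazard
$H(t) = \int_0^t h(u)\,du$ by vectorized bisection, making the joint model
correctly specified; the two schemes bracket the model-vs-generator
question. Under the self-consistent scheme the joint ML estimate centers on
the true $\gamma$, so published results showing upward joint-model bias in
a nominally self-consistent setting are reproducible here only in direction,
not magnitude — the unprinted details of that scheme (its $\lambda$, $\nu$
and exactly which hazard was inverted) dominate the cell.

**Censoring calibration.** Scenarios are indexed by censoring fraction
(10/50/90%), not by $\lambda$. `calibrate_lambda()` fixes all random draws
once (common random numbers) and bisects on $\log\lambda$; censoring is
monotone in $\lambda$ under common draws, so the result is deterministic
given the seed and reproducible to ±0.02 of the target.

**What the generator does not emulate:** informative censoring, visit-time
irregularity, nonlinear (quadratic/spline) trajectories, serial correlation
within subject, multiple biomarkers, tied event times. Passing tests
therefore speak to estimator behaviour under a clean linear
shared-random-effects world, not to robustness against these violations.

# The four estimators

* **TDCM** (`fit_tdcm`): time-dependent Cox with the observed values
  carried forward (LVCF). Counting-process intervals $(t_{ij}, t_{i,j+1}]$
  carry $Y_{ij}$; a measurement coincident with the event time is *not*
  used (strict carry-forward). Measurement error and staleness attenuate
  $\hat\gamma$ toward zero.
* **TSA** (`fit_tsa`): ordinary regression calibration. Stage 1 fits the
  linear mixed model by ML to all subjects (lme4 engine; random intercept
  and slope, baseline age as fixed covariate — a flag drops it); stage 2
  fits the Cox model on intervals broken at *every distinct event time*, so
  each risk set sees each at-risk subject's empirical-Bayes predicted value
  at that event time. Event-time breakpoints (rather than exam-interval
  breakpoints) are the faithful reading of "predicted values at event
  times". Stage-2 Wald standard errors only: first-stage uncertainty is
  deliberately not propagated, mirroring the procedure under study.
* **MLA** (`fit_joint_ml` / `fit_mla`): Weibull shared-parameter joint
  model maximizing
  $$\sum_i \log \int f(Y_i \mid U)\; h(T_i \mid U)^{\delta_i} S(T_i \mid U)\;
  f(U)\, dU.$$
* **BSJM** (`run_mcmc` / `fit_bsjm`): Bayesian joint model with a constant
  baseline hazard $\lambda_0$ (making the cumulative hazard closed-form),
  normal priors on regression-type parameters, Wishart prior on the
  random-effects precision, inverse-gamma on $\sigma^2$, gamma on
  $\lambda_0$.

The Cox engine behind TDCM/TSA uses Breslow ties (simulated continuous
times make ties measure-zero; Efron is a flag) and a single coefficient for
the time-dependent value — the per-interval-coefficient generality of the
partial-likelihood formulation collapses to one common $\gamma$, matching
how a single link estimate is reported.

# Numerical choices

**Joint likelihood quadrature.** The 2-D random-effects integral uses
tensor Gauss-Hermite quadrature (9 nodes per dimension by default, 15 as a
strict setting, 5 adequate for large-$n$ runs where the per-subject
longitudinal posterior is tight), adaptively centered and scaled by each
subject's *longitudinal* Gaussian posterior, which is available in closed
form from sufficient statistics. Centering makes the $\gamma = 0$ case
exact and keeps node counts small. The inner cumulative hazard
$\int_0^T \nu u^{\nu-1} e^{cu} du$ is computed by 15-point Gauss-Kronrod
after two rounds of integration by parts, which removes the algebraic
endpoint factor $u^{\nu-1}$ (the remaining integrand $u^{\nu+1}e^{cu}$ is
smooth, and the expression is exact at $c = 0$); when $|c|T > 10$ or the
by-parts form loses positivity to cancellation, the direct positive
Kronrod sum is used instead so optimizer excursions are penalized, never
rewarded.

**Optimization.** Positivity is enforced by optimizing $\log\lambda$,
$\log\nu$, $\log\sigma^2$ and the (log-diagonal) Cholesky factor of $G$.
The fit starts from the separate LME and Weibull-margin fits with
$\gamma = 0$, runs an ECM phase (default 10 cycles, cap 50) with quadrature
nodes frozen at the initial centering — closed-form updates for $\sigma^2$
and $G$, short BFGS blocks for the fixed effects and the survival
parameters, each conditional step non-decreasing, so the fixed-node
log-likelihood is monotone — then switches to BFGS on the fully adaptive
log-likelihood with an accurate central-difference gradient
($h = 10^{-6}$). Convergence requires the optimizer's own criterion plus a
score below $10^{-5}(1 + |\ell|)$ — relative, because the attainable
finite-difference accuracy scales with $|\ell|$. Standard errors come from
inverting a central-difference observed-information matrix; a fit whose
information is not positive definite is flagged non-converged.

**MCMC.** $\sigma^2$ (inverse gamma) and the random-effects precision
(Wishart) are conjugate Gibbs blocks; everything the survival factor
touches — fixed effects, $\gamma$, $\alpha$, $\log\lambda_0$, and the
per-subject random effects (updated as independent 2-D blocks) — uses
random-walk Metropolis with per-block scales adapted every 50 iterations
toward 20–40% acceptance *during burn-in only*, then frozen, preserving
the stationary distribution. The default configuration is 4 chains of
101,000 iterations, burn-in 1,000, thinning 50; with that bookkeeping
(101,000 − 1,000)/50 = 2,000 draws are kept per chain, although the
protocol it mirrors reports 500 — both numbers are documented rather than
silently reconciled, and desk-scale runs should pass far smaller values.
Gelman-Rubin $\hat R > 1.1$ on $\gamma$ sets a convergence warning on the
result instead of raising an error, since high-censoring cells genuinely
mix poorly.

**Slow mixing caveat.** The intercept block ($\beta_0$, $\beta_{age}$,
and the $U_{1i}$) is strongly cross-correlated; single-site random walks
traverse it slowly. For the package's purposes (oracle checks on small
data, structural diagnostics) this is acceptable; production-scale
Bayesian analyses would want blocked or recentered updates.

# Simulation-study harness

`scenario_config()` + `run_scenario()` manage a scenario cell: $\lambda$
calibrated once per cell, replicate $r$ seeded deterministically as
`seed + r`, aggregates (mean estimate, mean model SE, empirical SD,
95% coverage, bias, MSE, Type I error under the null) over converged fits
only, with the non-converged count reported. MSE is computed by its
standard definition; both the mean model SE and the empirical SD are
reported because a single "SE" column is ambiguous between them.

The test suite's acceptance checks reproduce published table cells at
desk-scale replicate counts — 800 replicates for Type I error, 300 for the
two-step and LVCF estimators, 40 (n = 100) and 8 (n = 1000) for the joint
ML fits — with tolerances of ±2 Monte-Carlo standard errors *of the
scaled-down run*. `scripts/acceptance.R` recomputes the same quantities
(400 replicates for Type I error, the rest as above). These sizes are the
package's replication choices, small enough for a single CPU and large
enough that the tolerance formula is meaningful.

# Known limitations

* Linear trajectories only; no quadratic/spline forms.
* The joint ML Weibull baseline is parametric; no piecewise-constant or
  spline baseline.
* TSA standard errors ignore first-stage uncertainty by design (that *is*
  the estimator under study); no bootstrap is wired in.
* The Bayesian sampler's mixing on intercept-like blocks is slow (above).
* Exact hyperparameters of the protocol the Bayesian defaults mirror are
  not public; the defaults are diffuse stand-ins and fully overridable.
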