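# ildsmooth

Non-parametric trend estimation for intensive longitudinal data (ILD) —
the dozens-to-hundreds of repeated measurements per person produced by
ecological momentary assessment and similar protocols — plus a simulation
laboratory for comparing smoothers on the non-linear stochastic processes
such data are believed to contain.

Psychological and biobehavioural time series often follow non-linear latent
trajectories: asymptotic growth, sudden mean-level switching, decaying
regulatory oscillations. The common default, global polynomial regression,
handles these poorly. This package implements three flexible alternatives
behind one interface, and the machinery to evaluate them:

* **Local polynomial regression** (`lpr_fit`): at each time point `t*` a
  degree-`p` polynomial in `(t − t*)` is fitted by kernel-weighted least
  squares, `β̂ = (XᵀWX)⁻¹XᵀWy`; the estimate is the local intercept, with
  the bandwidth chosen by exact leave-one-out cross-validation.
* **Gaussian-process regression** (`gp_fit`): a zero-mean GP prior with a
  squared-exponential kernel `α² exp(−Δt²/2ρ²)`; closed-form posterior,
  with `(ρ, α, σₙ)` estimated by penalised marginal-likelihood
  maximisation (half-normal priors on standardized data; optional MCMC).
* **Penalized-spline GAM** (`gam_fit`): a single smooth of time built from
  radial cubic basis functions with an exact bending-energy penalty;
  smoothing weight by GCV, complexity reported as effective degrees of
  freedom (EDF), from 1 (linear) to K − 1.
* **Global polynomial baseline** (`poly_fit`): OLS on raw powers of
  standardized time, degree by GCV.

Every fitter returns a `smoother_fit`: estimates, standard errors, 95%
bands, the hat matrix (so `estimate == hat %*% y`), a wiggliness summary
(bandwidth / lengthscale / EDF / degree) and a convergence flag. Fits are
scored with `mse()` (against the latent truth), `gcv_score()`
(`n·RSS/(n − tr H)²`) and `ci_coverage()`; factorial results are summarised
by partial-η² ANOVAs (`anova_partial_eta2`) with Monte-Carlo standard
errors (`mc_standard_error`).

The synthetic-data module generates latent trajectories from four
stochastic differential equations — exponential (Ornstein–Uhlenbeck)
growth, logistic growth, a cusp catastrophe, and a damped oscillator —
via Euler–Maruyama, with Wiener-process dynamic errors (variance 0.5/1/2
per time step) and standard-normal measurement error, sampled on
equidistant grids of 43–253 observations (`simulate_series`,
`sampling_design`, `design_grid`). `run_study()` orchestrates the full
factorial comparison; `run_idiographic_demo()` screens synthetic
per-person series by GAM EDF (< 1.001 ⇒ effectively linear).

## Worked example

```r
library(ildsmooth)

s <- simulate_series("oscillator", dev = 1, period = "full", frequency = 1,
                     seed = 7)                    # 85 noisy observations
f_gam  <- gam_fit(s, K = min(length(s$times), 35))
f_poly <- poly_fit(s)

f_gam
#> <smoother_fit: gam> 85 eval points; edf = 27.28; converged: TRUE
f_poly
#> <smoother_fit: poly> 85 eval points; degree = 4; converged: TRUE

round(c(mse_gam = mse(f_gam, s), mse_poly = mse(f_poly, s)), 3)
#>  mse_gam mse_poly
#>    0.500   22.226
round(c(gcv_gam = gcv_score(f_gam, s), coverage_gam = ci_coverage(f_gam, s)), 3)
#>      gcv_gam coverage_gam
#>        1.150        0.824
```

The GAM needs about 27 effective degrees of freedom to follow the five
decaying oscillation cycles and lands within 0.5 squared units of the
latent path on average; the best global polynomial (degree 4) cannot
represent the oscillation at all and is ~44× worse. The GAM's 95% band
covers the latent truth at 82% of time points — below nominal, as expected
for rough processes with data-driven smoothing.

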