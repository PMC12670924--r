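# climsent

Spatio-temporal relative-risk modelling of climate-health stressors and
negative social-media sentiment.

## The problem

Heat waves, droughts, pollen seasons and disease outbreaks plausibly leave
traces in how people express themselves online. Given a panel of
region-week post counts — total posts `CT(i,t)` and negative-sentiment
posts `Y(i,t)` for region *i* in ISO week *t* — together with weekly
exposure covariates (maximum temperature, alder/birch/olive pollen
concentrations, the standardized precipitation index, heat-attributable
mortality, West Nile virus cases), the package estimates how each exposure
level shifts the relative risk of a negative post, while absorbing shared
weekly dynamics, regional baselines and abrupt country-level shocks.

It is written for epidemiologists and computational social scientists who
want the full inferential pipeline — exposure categorisation, change-point
detection, hierarchical count regression, calibrated uncertainty — as
tested, reusable functions rather than a one-off analysis script.

## The model

Counts follow a Poisson observation model with a multiplicative
relative-risk decomposition:

```
Y(i,t) ~ Poisson(mu(i,t)),   mu(i,t) = theta_tot * CT(i,t) * RR(i,t)
log RR(i,t) = b0 + s_t + u_i + sum_h f_h(x_h(i,t)) + g_{c(i), I(t)}
```

* `theta_tot` — pooled proportion of negative posts (`sum Y / sum CT`);
* `s_t` — weekly temporal field shared across regions, stationary AR(1)
  prior with correlation `rho`;
* `u_i` — iid Gaussian region effect (no spatial correlation);
* `f_h` — one random effect per discrete exposure level of covariate `h`
  (levels from published cut points, e.g. temperature splits at
  2.96/14.9/26.9 °C);
* `g_{c,I}` — per-country random effects indexed by the piecewise-constant
  intervals `I(t)` of an exact 1-D sparse fused lasso fitted to each
  country's weekly log relative-rate anomaly (solved by dynamic
  programming; penalties selected by BIC).

Fitting is empirical-Bayes with a Laplace approximation: inner Newton
maximisation of the latent log posterior, outer quasi-Newton maximisation
of the marginal likelihood over block precisions and `rho`, sum-to-zero
constraints by orthonormal reparameterisation. Effects are reported as
percent change in RR, `(e^b - 1) * 100`, with Gaussian 95% intervals. An
MCMC cross-check (`mcmc_check()`) validates the approximation on small
panels. A seeded synthetic-panel generator with known ground truth
(`sim_config()` / `generate_panel()`) underpins the entire validation
suite.

## Worked example

The `analysis/` scripts run the pipeline end to end on the reference
synthetic panel (40 regions, 4 countries, 156 weeks, baseline 0.2, one
+0.5 log-RR shock in country C2 over weeks 20-40):

```sh
Rscript analysis/01_simulate.R       # panel + ground truth -> results/
Rscript analysis/02_bin_exposures.R  # exposure levels
Rscript analysis/03_fused_lasso.R    # per-country change points
Rscript analysis/04_fit_model.R      # hierarchical Poisson fit
Rscript analysis/05_report.R         # percent-change summaries
```

Equivalently in R, `run_pipeline(list(seed = 1, out_dir = "results/run1",
simulation = list()))` executes the same stages and writes the same
artifacts into one directory.

Stage 3 prints the detected change points — the configured shock enters
country C2 at week 20 and leaves after week 40, and the pipeline finds
exactly those boundaries:

```
baseline negative proportion theta_tot = 0.20174
C1: 1 interval(s)
C2: 3 interval(s), change points at week(s) 20, 41
C3: 1 interval(s)
C4: 1 interval(s)
```

Stage 4 recovers the latent structure (configured AR(1) rho 0.7,
marginal SD 0.03) and the Pearson residuals are Poisson-calibrated:

```
  theta_tot = 0.20174, log marginal = -27489.8245, converged: TRUE
  AR(1): rho = 0.677, marginal sd = 0.02635
Pearson residuals: mean -0.0006, variance 0.967, lag-1 autocorrelation 0.004
AR(1) rho: configured 0.70, estimated 0.677
```

Stage 5 prints the exposure-response table (`*` marks intervals that
exclude zero); configured truth for temperature is -0.63% (low) and
+0.36% (high), and +0.49% for extreme drought:

```
max_temperature  low              -0.642% (95% CI -1.207, -0.073)  *
max_temperature  mid              -0.062% (95% CI -0.409, +0.288)
max_temperature  average          +0.308% (95% CI -0.047, +0.664)
max_temperature  high             +0.399% (95% CI -0.185, +0.986)
...
spi              extreme_drought  +0.936% (95% CI -0.179, +2.064)
spi              moderate         -0.451% (95% CI -1.023, +0.125)
spi              rainfall         -0.479% (95% CI -1.089, +0.136)
```

Every fitted level effect lies within two posterior SDs of its configured
truth on this run; at the desk-scale post volume (mean 2000 per
region-week, versus hundreds of millions of posts in a full-scale corpus)
only the strongest contrast — cold weeks — is individually significant,
which is exactly what the interval widths say should happen.

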