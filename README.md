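# contactfatigue

Bayesian estimation of social contact intensities from longitudinal
contact surveys, with detection and correction of **reporting fatigue** —
the progressive under-reporting of contacts by panel members as their
number of repeat participations grows.

Longitudinal contact surveys (the CoMix/COVIMOD family) re-invite panel
members over dozens of waves. Repeat participants report systematically
fewer contacts than comparable first-time participants, so pooling all
records biases contact intensity estimates — and everything built on them
(reproduction numbers, mixing matrices, intervention assessments) —
downward. This package implements a complete workflow for such panels:

* **Preprocessing** of socialmixr-style long-format participant/contact
  tables: missing-demographic filtering, child-age imputation from
  reported bands, truncation of contact totals at 30, repeat-count
  derivation.
* **Variable selection** for contact-intensity determinants (Poisson
  regression with a regularized horseshoe prior on tested features) and
  for fatigue determinants (sign-constrained half-RHS prior with the
  `(1 - 2/pi)^(-1)` variance-matching adjustment), selecting features
  whose posterior median effect exceeds a +/-5% change
  (thresholds `log 0.95 = -0.0513`, `log 1.05 = 0.0488`), with the final
  set taken as the union across analysed waves.
* **Fatigue dynamics**: a longitudinal negative-binomial model with a
  Matern-3/2 Gaussian-process calendar trend and four interchangeable
  fatigue terms in the repeat count r — independent fixed effects, one
  identical effect, a GP over r, and a three-parameter **Hill
  dose-response** `rho(r) = -gamma e^zeta r^eta / (1 + e^zeta r^eta)`,
  whose asymptotic reduction is `100(e^-gamma - 1)` percent.
* **De-biasing**: a negative-binomial additive model with a smooth HSGP
  age effect and per-feature Hill adjustments; an incremental-inclusion
  experiment quantifying accuracy against a first-timer-only baseline
  (MAPE and interval coverage over ages 0-84); sequential wave-to-wave
  fitting with propagated priors.
* **Reporting**: post-stratified population and subgroup intensity
  estimates (age group x sex x household size cells), a participant-level
  bootstrap comparator, and tidy CSV outputs.
* A **synthetic cohort generator** reproducing the multi-wave panel
  design (recruitment quotas, Bernoulli retention, covariate-driven
  intensities, calendar trend, planted fatigue, NB noise) with a
  machine-readable ground-truth file, so every stage is testable without
  access to restricted survey data.

Posterior inference runs on a self-contained blocked MCMC engine
(adaptive random-walk Metropolis, coordinate slice updates with
cell-local likelihoods, quadrature-marginalized horseshoe scales, ridge
"shift" moves), with rank-normalized split R-hat diagnostics on every
fit. See the vignette
`vignettes/fatigue-adjusted-contact-intensities.Rmd` for the models,
priors, design decisions and limitations.

## Worked example

Simulate a ten-wave panel under the default study conditions (2,500
participants per wave, 70% retention, Hill fatigue with gamma = 0.88,
zeta = -1.55, eta = 0.94, negative-binomial overdispersion 2) — here
scaled down to 800 participants and 6 waves for a quick run — then
recover the fatigue curve:

```r
library(contactfatigue)

cfg <- cohort_config(n_per_wave = 800, n_waves = 6, seed = 11)
panel <- simulate_contacts(generate_panel(cfg), cfg)
recs  <- preprocess_records(panel, seed = 12)
ds    <- build_design(recs)
ds
#> <cf_wave> 4800 records, waves 1-6 (2000 first-time, 2800 repeating)

fit <- fit_longitudinal_model(ds, variant = "hill",
                              n_iter = 1000, n_warmup = 1200, seed = 1)
subset(posterior_summary(fit),
       parameter %in% c("gamma", "zeta", "eta", "phi"))[, 1:4]
#>    parameter       mean     median       q2.5
#> 21       phi  1.9794521  1.9756955  1.8277724
#> 22     gamma  0.4976748  0.4618202  0.3248421
#> 23      zeta -0.7164677 -0.6943292 -1.6076442
#> 24       eta  1.9724388  1.8490905  0.7429180

reduction_curve(fit, r_grid = c(0, 1, 2, 5))
#>   r    median     lower      upper
#> 1 0   0.00000   0.00000   0.000000
#> 2 1 -14.45718 -21.68154  -8.882395
#> 3 2 -25.66130 -30.78061 -19.977790
#> 4 5 -33.66239 -40.32833 -27.255573
```

The overdispersion is recovered exactly (posterior median 1.98, truth 2)
and the reduction curve is what matters scientifically: by the fifth
repeat participation, reported contacts are about a third lower than a
first-time report from the same person — the bias the de-biasing model
removes. Note that at this scaled-down size the panel only reaches five
repeats, so the asymptote parameter gamma (truth 0.88, here 0.46) is
weakly identified even though the curve over the observed range is
accurate; the full ten-wave default cohort, as run by the acceptance
script and the test suite, recovers all three Hill parameters. At the
asymptote, `percent_reduction(-0.88)` = -58.5% is the maximum reduction
implied by gamma = 0.88.

Downstream, `fit_debias_model()` fits the fatigue-adjusted additive
model for one wave, `incremental_inclusion_experiment()` scores it
against a first-timer-only baseline, and `population_mean_intensity()` /
`subgroup_estimates()` produce post-stratified estimates with
`poststrat_weights()` built from census margins.

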