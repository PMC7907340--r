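# frimpact

Comparative functional-response and impact-potential analysis for
predator–prey depletion experiments.

Invasion ecologists routinely ask whether an invasive predator will hit
prey populations harder than the native predator it displaces. The
standard answer combines two measurements: the **functional response**
(FR) — *per capita* consumption rate across prey densities, summarised by
an attack coefficient *a* and a handling time *h* — and the predator's
**field abundance**. `frimpact` implements that workflow end to end for
depletion-style trials (consumed prey not replaced), from raw trial tables
or a built-in stochastic simulator through to the **Relative Impact
Potential** (RIP) metric.

## The models

**Rogers random predator equation.** In a closed arena prey density falls
as prey are eaten, so consumption over a trial of duration *T* (days)
satisfies the implicit equation

```
N_e = N_0 (1 - exp(a (N_e h - T)))
```

solved explicitly with the Lambert W function:

```
N_e = N_0 - W(a h N_0 exp(-a (T - h N_0))) / (a h)
```

`fit_rogers()` estimates (*a*, *h*) by maximum likelihood (binomial counts
with the Rogers expected proportion), reports SEs, Wald z and p-values,
and both maximum-feeding-rate conventions `1/(T h)` (per experiment) and
`1/h` (per day). `classify_fr_type()` types the response (II vs III)
beforehand by quasibinomial logistic regression; `compare_fits()` tests
between-group differences (*Da*, *Dh*, base minus comparator) with an
indicator-variable joint fit; `bootstrap_fit()` supplies percentile
confidence bands and the bootstrap mean ± SE of the maximum feeding rate.

**Relative Impact Potential.** For focal group A and comparator B,

```
RIP = (FR_A x N_A) / (FR_B x N_B)
```

with FR the maximum feeding rate (prey/day) and N the field abundance
(ind/m²). `rip_score()` propagates the four mean ± SE summaries through a
Monte Carlo ratio distribution (truncated-normal draws by default,
moment-matched lognormal as an option) and reports the mean RIP, central
60%/80% intervals and P(RIP > 1). `rip_biplot_data()` produces the
classic effect × abundance biplot with iso-impact curves.

Supporting modules: a seeded simulator of depletion trials and
overdispersed quadrat surveys (`sim_config()`, `generate_trials()`,
`generate_quadrat_survey()`), predation-frequency contingency tests
(`chi_square_test()`, `fisher_exact_2x2()`, `survival_summary()`),
quadrat abundance summaries and quasi-Poisson group comparisons
(`summarize_abundance()`, `compare_abundance()`), and a one-config
pipeline (`run_pipeline()`) with a thin CLI (`inst/cli/frimpact.R`).

## Worked example

Simulate a 2-day larval-prey experiment (densities 1–15, 11 replicates per
density) for a large-bodied invader, fit and bootstrap it, and compare its
impact potential against a native analogue's published summary:

```r
library(frimpact)

trials <- generate_trials(sim_config(a = 0.392, h = 0.988, T = 2,
  densities = c(1, 2, 3, 5, 8, 10, 15), replicates = 11, seed = 2024,
  predator_label = "large invader", prey_label = "larva"))

fit <- fit_rogers(trials)
summary(fit)
#> Rogers random predator fit (binomial likelihood)
#> 77 trials, T = 2 day(s), logLik = -91.690
#>
#>   Estimate Std. Error z value  Pr(>|z|)
#> a  0.49121    0.20075  2.4469   0.01441 *
#> h  1.14267    0.21603  5.2893 1.228e-07 ***
#>
#> Max feeding rate: 0.4376 prey/experiment (1/Th), 0.8751 prey/day (1/h)

bt <- bootstrap_fit(fit, n_boot = 30, seed = 7)
#> max feeding rate: 0.8999 +/- 0.03451 prey/day (1/h)

quad <- generate_quadrat_survey(14.76, dispersion = 4, n_sites = 12,
                                seed = 3, group = "large invader")
ab <- summarize_abundance(quad)   # 9 ind/m^2 (SE 1.31) in this draw

A <- effect_summary("large invader",
                    bt$max_feeding_rate_per_day$mean,
                    bt$max_feeding_rate_per_day$se,
                    ab$mean_density, ab$se_density)
B <- effect_summary("native", 0.157, 0.012, 17.378, 4.486)
rip_score(A, B, seed = 11)
#> Relative Impact Potential: large invader vs native (100,000 draws, normal law)
#>   mean RIP = 3.26 (median 2.978)
#>   60% CI: 2.324 - 3.935,  80% CI: 2.057 - 4.66
#>   P(RIP > 1) = 99.992%
```

Read: the fitted handling time (1.14 d/prey) gives this group a bootstrap
maximum feeding rate of ~0.90 prey/day; combined with its simulated
abundance, its impact potential is ~3.3 times the native comparator's, and
essentially all Monte Carlo draws exceed parity (P(RIP > 1) ≈ 100%).

The full pipeline version of this analysis is one call:

```r
cfg <- system.file("extdata", "demo_config.yaml", package = "frimpact")
bundle <- run_pipeline(cfg, out_dir = "demo_results")
```

## Documentation

The methods vignette
(`vignettes/functional-response-impact.Rmd`) describes the models, the
likelihood and its numerical safeguards, the simulator's assumptions and
limits, the validation study sizes, and the open design choices (sampling
laws, feeding-rate conventions, sign conventions).
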