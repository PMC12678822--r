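---
title: "Simulating sustainable rates of phenotypic adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sustainable rates of phenotypic adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

How fast can a population keep changing? Species facing a directionally
changing environment — most obviously a warming climate — must move their
phenotypes generation after generation. Observing a steady response is not
evidence of safety: a population can change at a constant pace while
falling further and further behind the environmental optimum, until
mortality rises abruptly and it goes extinct. `kcrit` implements an
individual-based quantitative-genetic simulation designed to ask what
per-generation rates of change populations with realistic genetics can
sustain, and for how long.

## The simulation model

Each population consists of `n` diploid individuals (default carrying
capacity `n = 1000`, in line with effective sizes reported for natural
populations). An individual's genotypic value is the sum of the allelic
effects at its `k` loci (two alleles per locus, no dominance or epistasis);
its phenotype adds a fresh environmental deviate `N(0, sigma_e2)` every
generation, so the phenotypic variance decomposes as
`sigma_T2 = sigma_g2 + sigma_e2`.

One generation consists of:

1. **Viability selection.** Each individual survives an independent coin
   toss with probability equal to its Gaussian fitness
   `w = exp(-(z - theta)^2 / (2 omega^2))`, scaled so a phenotype at the
   optimum `theta` has fitness 1. Smaller `omega` means stronger selection.
2. **Reproduction.** Survivors are sampled with replacement into random
   pairs (never selfing); each parent contributes one gamete; the process
   repeats until the population is back to exactly `n` offspring. Zero or
   one survivor means extinction — a single survivor cannot form a
   non-self pair.
3. **Recombination.** Per gamete, a `Poisson(mu_r)` number of crossovers
   falls uniformly on the `k - 1` boundaries of a single linear map; the
   copied haplotype alternates at each crossover (two hits on one boundary
   cancel). `mu_r` of 3 or 5 mimics a trait whose loci span several
   chromosomes.
4. **Mutation.** Per gamete, a `Poisson(k * mu_m)` number of loci
   (`mu_m = 1e-4` per allele) each receive an additive `N(0, m2)`
   increment to their current allelic value — a continuum-of-alleles
   model. `m2` is chosen so that `2 k mu_m m2 = sigma_m2`: the expected
   new variance per offspring equals the target mutational variance
   regardless of `k`.

A run starts with 10,000 generations of stabilising selection
(`theta = 0`) to bring the genetic variance to its
mutation–selection(–drift) balance, then moves the optimum by a fixed
`delta_env` every generation — independently of the population's response —
until extinction or a cap of 240,000 directional generations.

```{r}
library(kcrit)
cfg <- pop_config(sigma_T2 = 0.022, h2 = 0.4, omega = 5, delta_env = 0.1,
                  mut_scalar = 0.0044, k_loci = 100, mu_r = 3, seed = 42)
traj <- run_population(cfg, stab_gens = 2000, max_dir_gens = 2000)
population_metrics(traj)
```

## Calibrated parameter densities

Rather than exploring a grid, each population draws its fixed starting
conditions from densities fitted to meta-analyses of natural populations,
so an ensemble numerically integrates over a realistic space of phenotypes
and selection regimes:

| parameter | density | units / range |
|---|---|---|
| phenotypic variance `sigma_T2` | Exponential(mean 0.018), rejected outside \[0.01, 0.09\] | log-scale trait variance |
| heritability `h2` | Weibull(shape 1.6, scale 0.4), rejected outside \[0.01, 0.99\] | dimensionless |
| mutation scalar `sigma_m2/sigma_e2` | Gamma(shape 1.1, scale 0.004) | mean 0.0044 |
| selection width `omega` | Uniform(0, 10) | trait units |
| environmental rate `delta_env` | Uniform(0, 0.3) | trait units / generation |

Truncations use rejection sampling, which preserves the shape of the
density (clipping would pile probability mass onto the bounds). The
Gamma form for the mutation scalar is preferred over an exponential
because it has a positive mode: a mutational input of exactly zero should
not be the most probable value in nature. A log-normal density of field
directional-selection intensities (`selection_intensity_reference()`) is
included purely as a reference curve against which realized selection
differentials can be compared; the sampled inputs are the uniforms above,
which were chosen (in the source calibration) to generate comparable
intensities.

## Derived statistics

All rates are trait-scaled by `eq_trait_sd`, the realized phenotypic sd
averaged over the last 1,000 stabilising generations. Using the realized
equilibrium sd rather than the drawn `sqrt(sigma_T2)` keeps the rates and
the critical-rate formula internally consistent: after burn-in the genetic
variance settles wherever mutation, selection and drift put it, not at the
drawn value. Per population:

* `rate_trait` — net phenotypic change per directional generation (endpoint
  difference, not a regression slope), in sd units: approximately a rate in
  haldanes.
* `rate_env = delta_env / eq_trait_sd` — how fast the optimum moves.
* lag — the gap between optimum and phenotypic mean. Both are measured
  from the population's mean at the onset of directional selection, which
  removes the zero-mean drift offset accumulated during burn-in and makes
  the identity `rate_env - rate_trait = lag_rate` exact. Two variants are
  reported: the mean scaled gap (`lag_mean`) and the gap growth per
  generation (`lag_rate`); the latter is the quantity compared against
  `rate_env` on a 1:1 line.
* `gens_to_extinction`, and `gens_to_50pct` — the first directional
  generation with > 50% mortality. Because the simulation restores carrying
  capacity every generation, outright extinction requires near-total
  mortality in a single generation; field data suggest few populations
  recover from > 50% mortality, so the 50% crossing is the more
  conservative lifetime, and `rate_trait_50` truncates the rate there.
* `No` — offspring per surviving parent, `n / mean(survivors)`, averaged
  over the directional phase (the critical-rate derivation assumes a
  roughly stable effective size during environmental change); the
  stabilising tail is the fallback when no directional generations exist.
* `kc` — the critical rate of environmental change
  `k_c = [sg2/(sg2+Vs)] * sqrt((Vs+sg2) * ln(No * omega / sqrt(Vs+sg2)))`
  with `Vs = omega^2 + sigma_e2`, scaled to sd units. `sg2` is the
  *observed* equilibrium genetic variance over the same window as
  `eq_trait_sd`. Populations changing faster than `k_c` are on a
  trajectory to extinction even if they appear to be keeping pace.

## Ensembles and the mutation-adjusted median

`run_ensemble()` samples and runs populations over a `k x mu_r` design.
Each population is a pure function of a per-population seed derived from
the master seed, so tables are reproducible regardless of execution order,
and individual failures are recorded per-row rather than aborting the run.
Survivors (populations that reach the directional cap) are not a random
subset: they are roughly two-fold enriched in mutational input. Equation
re-weighting (`adjusted_median_rate()`) computes a weighted median of
survivor rates with weights `p(sigma_m2/sigma_e2)` from the Gamma density,
normalized by the summed weights — the rate expected of survivors whose
mutational variance is representative of natural populations. Weighted
quantiles use cumulative-weight inversion, with exact agreement with
`median()` under uniform weights; the rank-interpolation choice is ours,
as only the weighting itself is prescribed by the estimator.

Summaries use medians and IQRs throughout because the distributions are
strongly skewed. `binned_summary()` provides equal-count bins (stable rank
order breaks ties) and `lag_survival_regression()` the log–log OLS of
extinction time on lag with a quadratic term.

## Desk-scale study design

The source-scale experiment (120,000 populations, up to 250,000
generations each) is cluster-scale. The package's documented desk-scale
design — used by `scripts/acceptance.R` and the acceptance tests — is 500
populations in the `k = 100, mu_r = 3` cell, with the burn-in reduced to
2,000 generations and the directional cap to 2,000. Two consequences are
worth recording:

* With a 2,000-generation burn-in, weakly selected populations (large
  `omega`) have not fully approached their drift–mutation equilibrium
  variance, so equilibrium trait sds are somewhat smaller than under the
  full 10,000-generation burn-in and trait-scaled rates somewhat larger.
  The headline medians move by far less than the Monte-Carlo tolerances
  applied to them.
* A 2,000-generation cap reclassifies as "survivors" some populations that
  would go extinct between 2,000 and 240,000 generations. Median lifetime
  statistics are robust to this (the capped populations lie above the
  median); survivor-set statistics are interpreted qualitatively at desk
  scale.

```{r}
ens <- run_ensemble(n_pops = 500, master_seed = 1, k_set = 100,
                    mur_set = 3, stab_gens = 2000, max_dir_gens = 2000)
ok <- ens[is.na(ens$error) & !ens$prestab_extinct, ]
median(ok$gens_to_extinction)
median(ok$rate_trait)
```

## Numerical choices and degenerate inputs

* Initialization is not specified by the model description: we draw each
  of the `2k` founder allelic values i.i.d. `N(0, sigma_g2_init / 2k)` so
  the founding genetic variance matches `h2 * sigma_T2`, and rely on the
  burn-in to reach equilibrium. The realized equilibrium heritability may
  drift away from the drawn `h2`; it is recorded, not corrected.
* Mutation increments the existing allelic value rather than replacing it;
  only the increment model injects exactly `2 k mu_m m2` of variance per
  offspring.
* `omega = 0` is allowed: fitness degenerates to the indicator of an exact
  optimum match, so such populations die during burn-in (the
  pre-directional extinctions are retained in ensemble tables, flagged
  `prestab_extinct`, and excluded from directional summaries).
* Extinction is declared at zero survivors or a single survivor (selfing
  is prohibited). The 50% cutoff is applied post hoc in the metrics, never
  inside the simulator.
* Record thinning keeps the stabilising tail (last 1,000 generations) and
  the first 10,000 directional generations in full, then every 100th;
  the accumulators behind the metrics (onset/final means, gap sums,
  survivor means, 50% crossing) are exact regardless of thinning.
* Poisson draws in the gamete model use single-uniform CDF inversion
  (exact, with an `R::rpois` fallback above mean 30); all randomness flows
  through R's global RNG, so a seed fully determines a run.

## The phenology stage

Longitudinal field series (annual trait means and sds, e.g. laying dates)
connect the simulated yardstick to data. `standardized_annual_rate()`
fits an OLS slope to annual means standardized by the pooled within-year
sd (inverse-variance pooling weighted by `n_obs - 1`; the choice of sd is
ours, as source analyses do not state theirs). Advancing phenologies
(earlier dates, negative raw slopes) are reported as positive rates;
multiplying by a generation time converts sd/year into sd/generation.
`rate_decay_fit()` fits the power-law decline of rates with study length,
and `variance_trend_fit()` the linear-plus-square-root trend in annual
variances.

Because the original field tables are external data, the package ships a
synthetic generator instead. `generate_synthetic_phenology()` emulates a
panel of studies with log-normal study lengths (median 29 years),
log-normal advance rates (median 0.022 sd/year), observation noise
`sd/sqrt(n_obs)`, and optional variance erosion. It emulates sampling
noise and variance decline only — not phenotypic plasticity, shared
climate forcing across series, or autocorrelated year effects — so
recovery tests on it demonstrate estimator correctness, not ecological
realism.

## Limitations

Single trait, purely additive architecture (no dominance, epistasis,
linkage heterogeneity or variable per-locus mutation rates), constant
environmental change (no stochastic or fat-tailed climate events), no
migration, no plasticity, fixed carrying capacity with full demographic
recovery every generation. These all push in a known direction: most make
the simulated populations *more* capable of sustained change than real
ones, which is the conservative direction for a yardstick of
vulnerability.
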