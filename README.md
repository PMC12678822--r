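# kcrit

How fast can a population keep changing before it falls fatally behind a
moving environmental optimum? `kcrit` is an individual-based,
multi-locus quantitative-genetic Monte Carlo simulator built to answer
that question for populations with *realistic* genetics: every simulated
population draws its phenotypic variance, heritability, mutational input
and selection regime from probability densities calibrated to
meta-analyses of natural populations. It is aimed at evolutionary
ecologists and quantitative geneticists who want a yardstick for species'
vulnerability to directional environmental change (climate warming being
the motivating case), and at anyone comparing observed field rates of
phenotypic change — e.g. advancing bird phenologies — against what
polygenic adaptation can plausibly sustain.

## The model

Each population holds `n = 1000` diploid individuals with `k` additive
loci. Generations cycle through Gaussian viability selection
(`w = exp(-(z - θ)² / 2ω²)`, survival by independent coin toss), random
mating with replacement back to carrying capacity, Poisson(`μ_r`)
crossovers on a linear map, and continuum-of-alleles mutation: a
Poisson(`k μ_m`) number of loci per gamete receive `N(0, m²)` increments
with `2 k μ_m m² = σ_m²`. After 10,000 generations of stabilising
selection (θ = 0), the optimum moves by `Δ_env` every generation until
extinction or a generation cap.

Per population the package computes trait-scaled (≈ haldane) rates of
phenotypic and environmental change, the lag behind the optimum,
generations to extinction and to the first > 50%-mortality generation,
and the theoretical critical rate of environmental change

```
k_c = [σ_g² / (σ_g² + V_s)] · sqrt( (V_s + σ_g²) · ln( N_o ω / sqrt(V_s + σ_g²) ) ),   V_s = ω² + σ_e²
```

scaled by the equilibrium trait sd (`σ_g²` observed at mutation–selection
balance, `N_o` = offspring per surviving parent). Ensemble tools add
equal-count binning, log–log survival-versus-lag regression, survivor
classification, and the mutation-adjusted weighted median that corrects
survivors' enrichment in mutational input. A phenology stage estimates
standardized rates (sd/year, sd/generation) from longitudinal trait
series and ships a synthetic series generator so the whole pipeline is
testable without external data.

## Worked example

```r
library(kcrit)
cfg <- pop_config(sigma_T2 = 0.022, h2 = 0.4, omega = 5, delta_env = 0.1,
                  mut_scalar = 0.0044, k_loci = 100, mu_r = 3, seed = 42)
traj <- run_population(cfg, stab_gens = 2000, max_dir_gens = 2000)
round(t(population_metrics(traj)), 4)
```

```
eq_geno_var          0.0547
eq_trait_sd          0.2605
rate_env             0.3839
rate_trait           0.0755
lag_mean            32.9464
lag_rate             0.3084
gens_to_extinction 208.0000
gens_to_50pct       68.0000
rate_trait_50        0.0417
survived_cap         0.0000
prestab_extinct      0.0000
No                   2.8346
kc                   0.0428
```

Reading it: after burn-in this population's trait sd is 0.26, so the
optimum moving at `Δ_env = 0.1` demands 0.38 sd of change per generation.
The population manages only 0.0755 sd/generation, lags by 0.31
sd/generation (note `rate_env - rate_trait = lag_rate`), crosses 50%
mortality at directional generation 68 and is extinct by generation 208.
Its theoretical ceiling `k_c = 0.043` sd/generation — an order of
magnitude below the demanded rate — predicts exactly that failure.

The phenology stage, run on a synthetic 29-year series generated with a
0.022 sd/year advance (the package's default field-like panel):

```r
s <- generate_synthetic_phenology(n_series = 1, years = 29, rate_spread = 0,
                                  length_spread = 0, seed = 7)
standardized_annual_rate(s)
```

```
Standardized rate: 0.0212 sd/yr over 29 years (p = 3.33e-06)
  per generation: 0.0424 sd
```

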