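# Independent oracles and fixture builders used across the test files.

# Step-by-step re-evaluation of the critical-rate formula, written
# independently of kc_estimate() so the two can be cross-checked.
oracle_kc <- function(sigma_g2, sigma_e2, omega, No, eq_trait_sd) {
  Vs <- omega * omega + sigma_e2
  denom <- sigma_g2 + Vs
  front <- sigma_g2 / denom
  inside_log <- (No * omega) / sqrt(denom)
  if (inside_log <= 1) return(NA_real_)
  kc_trait_units <- front * sqrt(denom * log(inside_log))
  kc_trait_units / eq_trait_sd
}

# Numerical median of the truncated exponential by CDF inversion
# (integrate + uniroot), independent of the closed form.
oracle_trunc_exp_median <- function(mean, lower, upper) {
  dens <- function(x) dexp(x, rate = 1 / mean)
  Z <- integrate(dens, lower, upper, rel.tol = 1e-12)$value
  cdf <- function(q) integrate(dens, lower, q, rel.tol = 1e-12)$value / Z
  uniroot(function(q) cdf(q) - 0.5, c(lower, upper), tol = 1e-12)$root
}

# Mean of the truncated Weibull by numerical integration.
oracle_trunc_weibull_mean <- function(shape, scale, lower, upper) {
  dens <- function(x) dweibull(x, shape, scale)
  Z <- integrate(dens, lower, upper, rel.tol = 1e-12)$value
  integrate(function(x) x * dens(x), lower, upper, rel.tol = 1e-12)$value / Z
}

# Minimal trajectory object with the summary fields the metrics read;
# used to feed constructed values through the metric formulas.
synthetic_trajectory <- function(delta_env = 0.01, eq_trait_sd = 0.1,
                                 eq_geno_var = 0.005, onset_mean = 0,
                                 final_mean = 0, dir_gens = 10,
                                 sum_gap = 0, survived_cap = FALSE,
                                 extinct_at = dir_gens,
                                 gens_to_50pct = NA_integer_,
                                 mean_at_50 = NA_real_,
                                 mean_survivors_directional = 1000,
                                 mean_survivors_stab_tail = 1000,
                                 n_pop = 1000, omega = 1,
                                 max_dir_gens = 240000,
                                 records = data.frame()) {
  cfg <- pop_config(sigma_T2 = eq_trait_sd^2, h2 = 0.5, omega = omega,
                    delta_env = delta_env, mut_scalar = 0.004,
                    n_pop = n_pop)
  traj <- list(
    config = cfg, stab_gens = 100L, max_dir_gens = as.integer(max_dir_gens),
    records = records, prestab_extinct = FALSE,
    extinct_stab_at = NA_integer_,
    extinct_at = if (survived_cap) NA_integer_ else as.integer(extinct_at),
    survived_cap = survived_cap, dir_gens = as.integer(dir_gens),
    onset_mean = onset_mean, final_mean = final_mean, sum_gap = sum_gap,
    eq_geno_var = eq_geno_var, eq_pheno_var = eq_trait_sd^2,
    eq_trait_sd = eq_trait_sd,
    mean_survivors_directional = mean_survivors_directional,
    mean_survivors_stab_tail = mean_survivors_stab_tail,
    gens_to_50pct = gens_to_50pct, mean_at_50 = mean_at_50
  )
  class(traj) <- "trajectory"
  traj
}

# Small standard configuration for simulator tests.
test_config <- function(sigma_T2 = 0.022, h2 = 0.4, omega = 5,
                        delta_env = 0.1, mut_scalar = 0.0044,
                        k_loci = 100, mu_r = 3, n_pop = 1000, seed = 7) {
  pop_config(sigma_T2 = sigma_T2, h2 = h2, omega = omega,
             delta_env = delta_env, mut_scalar = mut_scalar,
             k_loci = k_loci, mu_r = mu_r, n_pop = n_pop, seed = seed)
}
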