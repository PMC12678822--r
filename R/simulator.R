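#' Initialize a population's allelic values
#'
#' Returns a `2k x n_pop` matrix of allelic effect values (column = one
#' diploid individual; rows 1..k are the first haplotype, rows k+1..2k the
#' second). Each value is drawn i.i.d. N(0, sigma_g2_init / (2k)) so the
#' expected genotypic variance of the founding population equals
#' `h2 * sigma_T2`; the stabilising burn-in then takes the population to its
#' mutation-selection(-drift) equilibrium.
#'
#' @param config a [pop_config()].
#' @return numeric matrix of dimension `2 * k_loci` by `n_pop`.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "pop_config"))
  k2 <- 2L * config$k_loci
  sd_allele <- sqrt(config$sigma_g2_init / k2)
  matrix(rnorm(k2 * config$n_pop, 0, sd_allele), nrow = k2,
         ncol = config$n_pop)
}

#' Genotypic values
#'
#' Genotypic value of each individual: the sum of its `2k` allelic values.
#'
#' @param alleles `2k x n` allele matrix.
#' @return numeric vector of length `n`.
#' @export
genotypic_values <- function(alleles) colSums(alleles)

#' Phenotypic values
#'
#' Phenotype = genotype + environmental deviate, with fresh
#' N(0, sigma_e2) draws on every call.
#'
#' @param genotypes numeric vector of genotypic values.
#' @param sigma_e2 environmental variance.
#' @return numeric vector of phenotypes.
#' @export
phenotypes <- function(genotypes, sigma_e2) {
  stopifnot(sigma_e2 >= 0)
  if (sigma_e2 == 0) return(genotypes)
  genotypes + rnorm(length(genotypes), 0, sqrt(sigma_e2))
}

#' Gaussian survival probability
#'
#' Viability fitness `w = exp(-(phenotype - optimum)^2 / (2 omega^2))`,
#' scaled so phenotypes at the optimum have fitness 1. With `omega = 0`
#' fitness is the indicator of an exact optimum match.
#'
#' @param phenotype numeric phenotypic value(s).
#' @param optimum the fitness-function mean (theta).
#' @param omega standard deviation of the fitness function.
#' @return survival probabilities in \[0, 1\].
#' @export
gaussian_fitness <- function(phenotype, optimum, omega) {
  stopifnot(omega >= 0)
  if (omega == 0) return(as.numeric(phenotype == optimum))
  exp(-(phenotype - optimum)^2 / (2 * omega^2))
}

#' Viability selection by independent coin tosses
#'
#' Each individual survives independently with probability equal to its
#' Gaussian fitness.
#'
#' @inheritParams gaussian_fitness
#' @return integer indices of the survivors.
#' @export
select_survivors <- function(phenotype, optimum, omega) {
  w <- gaussian_fitness(phenotype, optimum, omega)
  which(runif(length(phenotype)) < w)
}

#' Build one gamete from a parent
#'
#' Crossover count ~ Poisson(`mu_r`) with positions uniform over the `k - 1`
#' inter-locus boundaries of a single linear map (the copied haplotype
#' alternates at each crossover; two crossovers in one boundary cancel);
#' mutation count ~ Poisson(`k * mu_m`) over distinct loci, each mutation
#' adding a N(0, `m2`) increment to the existing allelic value
#' (continuum-of-alleles).
#'
#' @param hap1,hap2 the parent's two haplotypes (length-`k` numeric vectors).
#' @param mu_r mean recombination events per haploid genome.
#' @param mu_m per-allele mutation probability.
#' @param m2 per-mutation effect variance.
#' @return length-`k` haploid allele vector.
#' @export
make_gamete <- function(hap1, hap2, mu_r, mu_m, m2) {
  cpp_make_gamete(as.numeric(hap1), as.numeric(hap2), mu_r, mu_m, m2)
}

#' Random mating with replacement back to carrying capacity
#'
#' Repeats `n_offspring` times: draw two distinct parents uniformly with
#' replacement from the survivors; each contributes one gamete via
#' [make_gamete()]; the offspring's diploid genome is the pair of gametes.
#' Zero or one survivor cannot form a non-self pair and signals extinction.
#'
#' @param alleles `2k x n` allele matrix of the parental generation.
#' @param survivors integer indices of surviving individuals.
#' @param n_offspring number of offspring (the carrying capacity).
#' @inheritParams make_gamete
#' @return list with `alleles` (`2k x n_offspring`) and `genotypes`.
#' @export
reproduce <- function(alleles, survivors, n_offspring, mu_r, mu_m, m2) {
  if (length(survivors) < 2)
    stop("extinction: fewer than 2 survivors, cannot form a non-self pair")
  cpp_reproduce(alleles, as.integer(survivors), as.integer(n_offspring),
                mu_r, mu_m, m2)
}

#' Run one population to extinction or the generation cap
#'
#' Simulates `stab_gens` generations of stabilising selection (optimum fixed
#' at 0), then moves the optimum by `delta_env` every generation,
#' independently of the population's response, until extinction (fewer than
#' two survivors) or `max_dir_gens` directional generations. Equilibrium
#' summaries (genetic variance, trait sd, survivor counts) are averaged over
#' the final `tail_window` stabilising generations. Per-generation records
#' are kept in full for that tail window and for the first
#' `dir_record_full` directional generations, then subsampled every
#' `dir_record_thin` generations; the summary accumulators used by the
#' metrics are exact regardless of thinning.
#'
#' @param config a [pop_config()].
#' @param stab_gens stabilising (burn-in) generations, >= 1 (default 10000).
#' @param max_dir_gens cap on directional generations (default 240000).
#' @param tail_window equilibrium averaging window (default 1000, truncated
#'   to `stab_gens`).
#' @param dir_record_full directional generations recorded in full
#'   (default 10000).
#' @param dir_record_thin thinning interval beyond that (default 100).
#' @param seed RNG seed; defaults to the seed stored in `config`.
#' @return object of class `trajectory`.
#' @export
run_population <- function(config, stab_gens = 10000, max_dir_gens = 240000,
                           tail_window = 1000, dir_record_full = 10000,
                           dir_record_thin = 100, seed = config$seed) {
  stopifnot(inherits(config, "pop_config"), stab_gens >= 1, max_dir_gens >= 0)
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  alleles <- init_population(config)
  res <- cpp_run_population(
    alleles, config$sigma_e2, config$omega, config$delta_env,
    config$mu_r, config$mu_m, config$m2,
    as.integer(stab_gens), as.integer(max_dir_gens),
    as.integer(min(tail_window, stab_gens)),
    as.integer(dir_record_full), as.integer(dir_record_thin)
  )
  records <- as.data.frame(res$records)
  traj <- list(
    config = config,
    stab_gens = as.integer(stab_gens),
    max_dir_gens = as.integer(max_dir_gens),
    records = records,
    prestab_extinct = res$prestab_extinct,
    extinct_stab_at = if (res$extinct_stab_at < 0) NA_integer_
                      else res$extinct_stab_at,
    extinct_at = if (res$extinct_dir_at < 0) NA_integer_
                 else res$extinct_dir_at,
    survived_cap = res$survived_cap,
    dir_gens = res$dir_gens,
    onset_mean = res$onset_mean,
    final_mean = res$final_mean,
    sum_gap = res$sum_gap,
    eq_geno_var = res$eq_geno_var,
    eq_pheno_var = res$eq_pheno_var,
    eq_trait_sd = sqrt(res$eq_pheno_var),
    mean_survivors_directional = if (res$dir_gens > 0)
      res$sum_surv_dir / res$dir_gens else NA_real_,
    mean_survivors_stab_tail = res$mean_surv_stab_tail,
    gens_to_50pct = if (res$first50 < 0) NA_integer_ else res$first50,
    mean_at_50 = res$mean_at_50
  )
  class(traj) <- "trajectory"
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cfg <- x$config
  cat("Population trajectory\n")
  cat(sprintf("  stabilising %d gens, directional cap %d gens\n",
              x$stab_gens, x$max_dir_gens))
  if (isTRUE(x$prestab_extinct)) {
    cat(sprintf("  extinct during stabilising phase at generation %d\n",
                x$extinct_stab_at))
  } else if (isTRUE(x$survived_cap)) {
    cat(sprintf("  survived the directional cap (%d generations)\n",
                x$dir_gens))
  } else {
    cat(sprintf("  extinct after %d directional generations\n", x$extinct_at))
  }
  cat(sprintf("  equilibrium: sigma_g2 = %.4g, trait sd = %.4g\n",
              x$eq_geno_var, x$eq_trait_sd))
  cat(sprintf("  config: omega = %.3g, delta_env = %.4g, k = %d, mu_r = %g\n",
              cfg$omega, cfg$delta_env, cfg$k_loci, cfg$mu_r))
  invisible(x)
}
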