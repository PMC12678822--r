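#' Sample phenotypic variances
#'
#' Draws within-population phenotypic variances (log-scale trait units
#' squared) from an Exponential distribution with mean 0.018, truncated by
#' rejection to \[0.01, 0.09\]. The lower bound avoids 'basement' variances
#' where drift dominates; the upper bound matches the range observed in
#' field meta-analyses. Rejection (rather than clipping) keeps the truncated
#' density exact, with no point masses at the bounds.
#'
#' @param n number of draws.
#' @param mean mean of the untruncated Exponential (default 0.018).
#' @param lower,upper truncation bounds (defaults 0.01 and 0.09).
#' @return numeric vector of length `n`.
#' @export
sample_phenotypic_variance <- function(n = 1, mean = 0.018,
                                       lower = 0.01, upper = 0.09) {
  stopifnot(mean > 0, lower <= upper)
  if (lower == upper) return(rep(lower, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rexp(max(n - length(out), 16L) * 2L, rate = 1 / mean)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Sample heritabilities
#'
#' Draws broad-sense heritabilities from a Weibull(shape = 1.6, scale = 0.4)
#' distribution truncated by rejection to \[0.01, 0.99\].
#'
#' @param n number of draws.
#' @param shape,scale Weibull parameters (defaults 1.6 and 0.4).
#' @param lower,upper truncation bounds (defaults 0.01 and 0.99).
#' @return numeric vector of length `n`.
#' @export
sample_heritability <- function(n = 1, shape = 1.6, scale = 0.4,
                                lower = 0.01, upper = 0.99) {
  stopifnot(shape > 0, scale > 0, lower <= upper)
  out <- numeric(0)
  while (length(out) < n) {
    x <- rweibull(max(n - length(out), 16L) * 2L, shape = shape, scale = scale)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Sample mutational heritabilities
#'
#' Draws the mutation scalar \eqn{\sigma_m^2/\sigma_e^2} (per-generation
#' mutational variance relative to the environmental variance) from a
#' Gamma(shape = 1.1, scale = 0.004) distribution: mean 0.0044, 95% interior
#' range roughly 0.0002 to 0.019. Unlike an exponential fit this density has
#' a positive mode, reflecting that a mutational input of zero is not the
#' most frequent value in nature.
#'
#' @param n number of draws.
#' @param shape,scale Gamma parameters (defaults 1.1 and 0.004).
#' @return numeric vector of length `n`.
#' @export
sample_mut_scalar <- function(n = 1, shape = 1.1, scale = 0.004) {
  stopifnot(shape > 0, scale >= 0)
  if (scale == 0) return(rep(0, n))
  rgamma(n, shape = shape, scale = scale)
}

#' Sample selection-regime parameters
#'
#' Draws the width of the Gaussian fitness function `omega ~ U(0, 10)` and
#' the per-generation optimum shift `delta_env ~ U(0, 0.3)`, independently.
#'
#' @param n number of draws.
#' @return data.frame with columns `omega` and `delta_env`.
#' @export
sample_selection_widths <- function(n = 1) {
  data.frame(omega = runif(n, 0, 10), delta_env = runif(n, 0, 0.3))
}

#' Mutational-heritability probability density
#'
#' Gamma(1.1, scale 0.004) density of the mutation scalar
#' \eqn{\sigma_m^2/\sigma_e^2}. Used as the weight
#' \eqn{p(\sigma_m^2/\sigma_e^2)} when adjusting survivor rates of change so
#' that mutational inputs are representative of natural populations.
#'
#' @param x positive mutation scalar value(s).
#' @param shape,scale Gamma parameters (defaults 1.1 and 0.004).
#' @return density value(s).
#' @export
mut_scalar_pdf <- function(x, shape = 1.1, scale = 0.004) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("mut_scalar_pdf is defined for x > 0 only")
  dgamma(x, shape = shape, scale = scale)
}

#' Median of the truncated exponential phenotypic-variance density
#'
#' Closed form: for an Exponential with mean `m` truncated to \[a, b\], the
#' median is \eqn{-m \log(0.5 (e^{-a/m} + e^{-b/m}))}.
#'
#' @param mean untruncated mean (default 0.018).
#' @param lower,upper truncation bounds (defaults 0.01 and 0.09).
#' @return the median of the truncated distribution.
#' @export
trunc_exp_median <- function(mean = 0.018, lower = 0.01, upper = 0.09) {
  -mean * log(0.5 * (exp(-lower / mean) + exp(-upper / mean)))
}

#' Reference density for realized directional-selection intensities
#'
#' Log-normal (meanlog -2.56, sdlog 1.19) density of standardized
#' directional-selection coefficients observed in field meta-analyses. The
#' simulation draws `omega` and `delta_env` uniformly; this density is a
#' reference for checking that realized selection intensities are comparable
#' to field values, not a sampled input.
#'
#' @param x positive standardized selection differential(s).
#' @return density value(s).
#' @export
selection_intensity_reference <- function(x) {
  dlnorm(x, meanlog = -2.56, sdlog = 1.19)
}

#' Construct a population configuration
#'
#' Bundles the fixed starting conditions of one simulated population and the
#' variance components derived from them: initial genetic variance
#' \eqn{\sigma_g^2 = h^2 \sigma_T^2}, environmental variance
#' \eqn{\sigma_e^2 = (1 - h^2) \sigma_T^2}, mutational variance
#' \eqn{\sigma_m^2 = (\sigma_m^2/\sigma_e^2) \cdot \sigma_e^2}, and the
#' per-mutation effect variance \eqn{m^2 = \sigma_m^2 / (2 k \mu_m)} so that
#' the expected variance injected per offspring equals \eqn{\sigma_m^2}.
#'
#' @param sigma_T2 phenotypic variance (log-scale trait units squared).
#' @param h2 broad-sense heritability, in (0, 1).
#' @param omega width (sd) of the Gaussian fitness function; 0 means fitness
#'   is the indicator of an exact optimum match.
#' @param delta_env per-generation optimum shift during directional selection.
#' @param mut_scalar mutational heritability \eqn{\sigma_m^2/\sigma_e^2}.
#' @param k_loci number of diploid loci (the study design uses 100, 500,
#'   1000 or 5000).
#' @param mu_r mean recombination events per haploid genome (study design: 3
#'   or 5).
#' @param n_pop carrying capacity (default 1000).
#' @param mu_m per-allele mutation probability (default 1e-4).
#' @param seed optional integer RNG seed attached to the configuration.
#' @return object of class `pop_config`.
#' @export
pop_config <- function(sigma_T2, h2, omega, delta_env, mut_scalar,
                       k_loci = 100, mu_r = 3, n_pop = 1000, mu_m = 1e-4,
                       seed = NULL) {
  stopifnot(
    is.numeric(sigma_T2), sigma_T2 > 0,
    is.numeric(h2), h2 > 0, h2 < 1,
    is.numeric(omega), omega >= 0,
    is.numeric(delta_env), delta_env >= 0,
    is.numeric(mut_scalar), mut_scalar > 0,
    k_loci >= 1, mu_r >= 0, n_pop >= 2, mu_m >= 0, mu_m <= 1
  )
  sigma_e2 <- (1 - h2) * sigma_T2
  sigma_m2 <- mut_scalar * sigma_e2
  cfg <- list(
    sigma_T2 = sigma_T2, h2 = h2, omega = omega, delta_env = delta_env,
    mut_scalar = mut_scalar, k_loci = as.integer(k_loci), mu_r = mu_r,
    n_pop = as.integer(n_pop), mu_m = mu_m,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    sigma_g2_init = h2 * sigma_T2,
    sigma_e2 = sigma_e2,
    sigma_m2 = sigma_m2,
    m2 = sigma_m2 / (2 * k_loci * mu_m)
  )
  class(cfg) <- "pop_config"
  cfg
}

#' @export
print.pop_config <- function(x, ...) {
  cat("Population configuration (pop_config)\n")
  cat(sprintf("  sigma_T2 = %.4g  h2 = %.3f  omega = %.3g  delta_env = %.4g\n",
              x$sigma_T2, x$h2, x$omega, x$delta_env))
  cat(sprintf("  mut_scalar = %.4g  k_loci = %d  mu_r = %g  n_pop = %d  mu_m = %g\n",
              x$mut_scalar, x$k_loci, x$mu_r, x$n_pop, x$mu_m))
  cat(sprintf("  derived: sigma_g2_init = %.4g  sigma_e2 = %.4g  sigma_m2 = %.4g  m2 = %.4g\n",
              x$sigma_g2_init, x$sigma_e2, x$sigma_m2, x$m2))
  if (!is.na(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Sample a population configuration
#'
#' Draws the five empirically calibrated input variables (phenotypic
#' variance, heritability, mutation scalar, omega, delta_env) independently
#' from their densities and returns a complete [pop_config()]. A pure
#' function of `(seed, k_loci, mu_r, n_pop, mu_m)` when `seed` is given.
#'
#' @inheritParams pop_config
#' @return object of class `pop_config`.
#' @export
sample_config <- function(k_loci = 100, mu_r = 3, n_pop = 1000, mu_m = 1e-4,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sel <- sample_selection_widths(1)
  pop_config(
    sigma_T2 = sample_phenotypic_variance(1),
    h2 = sample_heritability(1),
    omega = sel$omega,
    delta_env = sel$delta_env,
    mut_scalar = sample_mut_scalar(1),
    k_loci = k_loci, mu_r = mu_r, n_pop = n_pop, mu_m = mu_m, seed = seed
  )
}
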