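#' Trait-scaled rate of phenotypic change
#'
#' Net phenotypic change per directional generation in units of the
#' equilibrium trait sd:
#' `(final mean - onset mean) / directional generations / eq_trait_sd`.
#' The onset mean is the phenotypic mean in the last stabilising generation;
#' rates are endpoint differences, not regression slopes.
#'
#' @param traj a [run_population()] trajectory.
#' @return rate in trait sds per generation.
#' @export
trait_rate <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$dir_gens < 1)
    stop("trait_rate undefined: no directional generations elapsed")
  (traj$final_mean - traj$onset_mean) / traj$dir_gens / traj$eq_trait_sd
}

#' Trait-scaled rate of environmental change
#'
#' `delta_env / eq_trait_sd`: how fast the optimum moves, in units of the
#' realized equilibrium trait sd.
#'
#' @param traj a [run_population()] trajectory.
#' @return rate in trait sds per generation.
#' @export
env_rate <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$config$delta_env / traj$eq_trait_sd
}

#' Phenotypic lag behind the moving optimum
#'
#' The per-generation gap between the optimum and the phenotypic mean,
#' trait-scaled. Both the optimum and the mean are measured from the
#' population's position at the onset of directional selection, which
#' removes the (zero-mean) drift offset accumulated during the burn-in. Two
#' variants are returned:
#' * `lag_mean`: mean scaled gap over the directional generations survived;
#' * `lag_rate`: final scaled gap divided by generations survived — the
#'   quantity compared 1:1 against `env_rate`, and identically equal to
#'   `env_rate - trait_rate`.
#'
#' @param traj a [run_population()] trajectory.
#' @return list with elements `lag_mean` and `lag_rate` (sd units and
#'   sd units per generation).
#' @export
lag_per_generation <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  d <- traj$dir_gens
  if (d < 1)
    stop("lag undefined: no directional generations elapsed")
  sdT <- traj$eq_trait_sd
  lag_mean <- (traj$sum_gap / d + traj$onset_mean) / sdT
  theta_final <- traj$config$delta_env * d
  lag_rate <- (theta_final - (traj$final_mean - traj$onset_mean)) / d / sdT
  list(lag_mean = lag_mean, lag_rate = lag_rate)
}

#' First directional generation with more than 50% mortality
#'
#' Few natural populations recover from > 50% mortality in a single
#' generation; the first directional generation crossing that threshold is
#' used as an alternative extinction cutoff.
#'
#' @param traj a [run_population()] trajectory.
#' @return directional generation index, or `NA` if mortality never
#'   exceeded 0.5.
#' @export
time_to_50pct <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$gens_to_50pct
}

#' Expected offspring per surviving parent
#'
#' `N_o = n_pop / mean(survivor count per generation)`, the expected number
#' of offspring per surviving parent under random mating with replacement
#' back to carrying capacity. The averaging window is the directional phase
#' up to extinction; if no directional generations were run (or no survivors
#' were seen there), the stabilising tail window is used instead.
#'
#' @param traj a [run_population()] trajectory.
#' @return `N_o` (dimensionless, >= 1 when mortality is non-negative).
#' @export
offspring_per_parent <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  m <- traj$mean_survivors_directional
  if (!is.finite(m) || m <= 0) m <- traj$mean_survivors_stab_tail
  if (!is.finite(m) || m <= 0) return(NA_real_)
  traj$config$n_pop / m
}

#' Critical rate of environmental change
#'
#' Theoretical maximum sustainable per-generation rate of environmental
#' change,
#' \deqn{k_c = \frac{\sigma_g^2}{\sigma_g^2 + V_s}
#'   \sqrt{(V_s + \sigma_g^2)\,
#'   \ln\!\left[\frac{N_o\,\omega}{\sqrt{V_s + \sigma_g^2}}\right]}}
#' with \eqn{V_s = \omega^2 + \sigma_e^2}, divided by `eq_trait_sd` to give
#' trait sds per generation. `sigma_g2` is the genetic variance observed at
#' the mutation-selection balance equilibrium and `No` the offspring per
#' surviving parent. A non-positive log argument (or `omega <= 0`) means the
#' population cannot sustain any change and returns `NA`; `sigma_g2 = 0`
#' returns 0.
#'
#' @param sigma_g2 equilibrium genetic variance (trait units squared).
#' @param sigma_e2 environmental variance (trait units squared).
#' @param omega width of the Gaussian fitness function (trait units).
#' @param No offspring per surviving parent.
#' @param eq_trait_sd equilibrium phenotypic sd used for trait scaling.
#' @return `k_c` in trait sds per generation.
#' @export
kc_estimate <- function(sigma_g2, sigma_e2, omega, No, eq_trait_sd) {
  stopifnot(length(sigma_g2) == 1)
  if (!is.finite(sigma_g2) || !is.finite(omega) || !is.finite(No) ||
      !is.finite(eq_trait_sd) || eq_trait_sd <= 0)
    return(NA_real_)
  if (sigma_g2 == 0) return(0)
  if (omega <= 0 || sigma_g2 < 0) return(NA_real_)
  Vs <- omega^2 + sigma_e2
  tot <- Vs + sigma_g2
  logarg <- No * omega / sqrt(tot)
  if (logarg <= 1) return(NA_real_)
  (sigma_g2 / tot) * sqrt(tot * log(logarg)) / eq_trait_sd
}

#' Realized selection intensity series
#'
#' Per recorded generation, the standardized selection differential
#' `(survivor phenotypic mean - pre-selection phenotypic mean) / phenotypic
#' sd`. Comparable against the field-derived log-normal reference density
#' [selection_intensity_reference()].
#'
#' @param traj a [run_population()] trajectory.
#' @return data.frame with columns `generation`, `phase` and `intensity`.
#' @export
realized_selection_intensity <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  r <- traj$records
  keep <- is.finite(r$surv_pheno_mean) & r$pheno_var > 0
  data.frame(
    generation = r$generation[keep],
    phase = r$phase[keep],
    intensity = (r$surv_pheno_mean[keep] - r$pheno_mean[keep]) /
      sqrt(r$pheno_var[keep])
  )
}

#' Per-population metric row
#'
#' Collects all per-population derived statistics into a one-row data.frame:
#' trait-scaled rates of phenotypic and environmental change, both lag
#' variants, generations to extinction (the cap value for populations that
#' survived it), the 50%-mortality cutoff time and the rate truncated at
#' that cutoff, offspring per surviving parent, the critical rate `kc`, and
#' the equilibrium summaries. Populations extinct before directional
#' selection get `NA` metrics with `prestab_extinct = TRUE`.
#'
#' @param traj a [run_population()] trajectory.
#' @return one-row data.frame.
#' @export
population_metrics <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (isTRUE(traj$prestab_extinct) || traj$dir_gens < 1) {
    return(data.frame(
      eq_geno_var = traj$eq_geno_var, eq_trait_sd = traj$eq_trait_sd,
      rate_env = NA_real_, rate_trait = NA_real_,
      lag_mean = NA_real_, lag_rate = NA_real_,
      gens_to_extinction = NA_real_, gens_to_50pct = NA_real_,
      rate_trait_50 = NA_real_, survived_cap = FALSE,
      prestab_extinct = isTRUE(traj$prestab_extinct),
      No = NA_real_, kc = NA_real_
    ))
  }
  lag <- lag_per_generation(traj)
  No <- offspring_per_parent(traj)
  rt <- trait_rate(traj)
  g50 <- traj$gens_to_50pct
  rate50 <- if (!is.na(g50)) {
    (traj$mean_at_50 - traj$onset_mean) / g50 / traj$eq_trait_sd
  } else rt
  data.frame(
    eq_geno_var = traj$eq_geno_var,
    eq_trait_sd = traj$eq_trait_sd,
    rate_env = env_rate(traj),
    rate_trait = rt,
    lag_mean = lag$lag_mean,
    lag_rate = lag$lag_rate,
    gens_to_extinction = if (isTRUE(traj$survived_cap))
      as.numeric(traj$max_dir_gens) else as.numeric(traj$extinct_at),
    gens_to_50pct = if (is.na(g50)) NA_real_ else as.numeric(g50),
    rate_trait_50 = rate50,
    survived_cap = isTRUE(traj$survived_cap),
    prestab_extinct = FALSE,
    No = No,
    kc = kc_estimate(traj$eq_geno_var, traj$config$sigma_e2,
                     traj$config$omega, No, traj$eq_trait_sd)
  )
}
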