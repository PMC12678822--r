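config_row <- function(cfg) {
  data.frame(
    seed = cfg$seed, k_loci = cfg$k_loci, mu_r = cfg$mu_r,
    n_pop = cfg$n_pop, mu_m = cfg$mu_m, sigma_T2 = cfg$sigma_T2,
    h2 = cfg$h2, omega = cfg$omega, delta_env = cfg$delta_env,
    mut_scalar = cfg$mut_scalar, sigma_g2_init = cfg$sigma_g2_init,
    sigma_e2 = cfg$sigma_e2, sigma_m2 = cfg$sigma_m2, m2 = cfg$m2
  )
}

metrics_na_row <- function() {
  data.frame(
    eq_geno_var = NA_real_, eq_trait_sd = NA_real_, rate_env = NA_real_,
    rate_trait = NA_real_, lag_mean = NA_real_, lag_rate = NA_real_,
    gens_to_extinction = NA_real_, gens_to_50pct = NA_real_,
    rate_trait_50 = NA_real_, survived_cap = NA, prestab_extinct = NA,
    No = NA_real_, kc = NA_real_
  )
}

#' Run a parameter-sampled ensemble of populations
#'
#' For each cell of the `k_set x mur_set` design, samples `n_pops`
#' configurations from the calibrated densities and runs each population.
#' Every population is a pure function of its own derived seed, so the
#' table is reproducible from `master_seed` regardless of execution order.
#' Individual run failures are recorded in the `error` column and never
#' abort the ensemble. The full study design is
#' `k_set = c(100, 500, 1000, 5000)`, `mur_set = c(3, 5)`,
#' `n_pops = 15000` with caps 10000/240000; the desk-scale default analyses
#' a single cell.
#'
#' @param n_pops populations per design cell.
#' @param master_seed integer master seed.
#' @param k_set loci counts (default 100).
#' @param mur_set mean recombination rates (default 3).
#' @param n_pop carrying capacity (default 1000).
#' @param mu_m per-allele mutation probability (default 1e-4).
#' @param stab_gens stabilising generations per run.
#' @param max_dir_gens directional generation cap per run.
#' @param tail_window equilibrium averaging window (default 1000).
#' @param progress print one line per 100 populations (default FALSE).
#' @return data.frame with one row per population: the configuration
#'   fields, the [population_metrics()] fields, and `error`.
#' @export
run_ensemble <- function(n_pops, master_seed, k_set = 100, mur_set = 3,
                         n_pop = 1000, mu_m = 1e-4, stab_gens = 10000,
                         max_dir_gens = 240000, tail_window = 1000,
                         progress = FALSE) {
  stopifnot(n_pops >= 1)
  design <- expand.grid(k_loci = k_set, mu_r = mur_set,
                        KEEP.OUT.ATTRS = FALSE)
  total <- nrow(design) * n_pops
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, total)
  rows <- vector("list", total)
  idx <- 0L
  for (d in seq_len(nrow(design))) {
    for (r in seq_len(n_pops)) {
      idx <- idx + 1L
      rows[[idx]] <- tryCatch({
        cfg <- sample_config(design$k_loci[d], design$mu_r[d], n_pop, mu_m,
                             seed = seeds[idx])
        # sample_config seeded the stream; the run continues it so the
        # simulation draws are disjoint from the parameter draws
        traj <- run_population(cfg, stab_gens = stab_gens,
                               max_dir_gens = max_dir_gens,
                               tail_window = tail_window, seed = NULL)
        cbind(config_row(cfg), population_metrics(traj),
              error = NA_character_)
      }, error = function(e) {
        cfg <- tryCatch(sample_config(design$k_loci[d], design$mu_r[d],
                                      n_pop, mu_m, seed = seeds[idx]),
                        error = function(e2) NULL)
        crow <- if (is.null(cfg)) {
          data.frame(seed = seeds[idx], k_loci = design$k_loci[d],
                     mu_r = design$mu_r[d], n_pop = n_pop, mu_m = mu_m,
                     sigma_T2 = NA_real_, h2 = NA_real_, omega = NA_real_,
                     delta_env = NA_real_, mut_scalar = NA_real_,
                     sigma_g2_init = NA_real_, sigma_e2 = NA_real_,
                     sigma_m2 = NA_real_, m2 = NA_real_)
        } else config_row(cfg)
        cbind(crow, metrics_na_row(), error = conditionMessage(e))
      })
      if (progress && idx %% 100L == 0L)
        message(sprintf("population %d / %d", idx, total))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the populations that tracked the environment
#'
#' Returns the rows classified as long-term survivors: by default those
#' that reached the directional cap (`survived_cap`), or, with
#' `min_directional`, those that survived at least that many directional
#' generations (a threshold of 0 keeps every analysed population).
#' Populations extinct before directional selection are always excluded.
#'
#' @param table an ensemble table from [run_ensemble()].
#' @param min_directional optional survival threshold in directional
#'   generations.
#' @return the survivor subset of `table`.
#' @export
classify_survivors <- function(table, min_directional = NULL) {
  ok <- is.na(table$error) & !vapply(table$prestab_extinct, isTRUE, logical(1))
  if (is.null(min_directional)) {
    keep <- ok & vapply(table$survived_cap, isTRUE, logical(1))
  } else {
    keep <- ok & !is.na(table$gens_to_extinction) &
      table$gens_to_extinction >= min_directional
  }
  table[keep, , drop = FALSE]
}

#' Weighted quantiles by cumulative-weight inversion
#'
#' Sorts `x`, accumulates normalized weights, and returns the first value
#' whose cumulative weight reaches each probability; when a probability is
#' hit exactly at an observation boundary the two adjacent values are
#' averaged, so uniform weights reproduce [stats::median()] exactly.
#'
#' @param x numeric values.
#' @param w non-negative weights.
#' @param probs probabilities (default 0.5).
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs = 0.5) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0,
            all(probs >= 0 & probs <= 1))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  n <- length(x)
  vapply(probs, function(p) {
    i <- which(cw >= p - 1e-12)[1]
    if (is.na(i)) return(x[n])
    if (i < n && abs(cw[i] - p) <= 1e-12) (x[i] + x[i + 1]) / 2 else x[i]
  }, numeric(1))
}

#' @rdname weighted_quantile
#' @export
weighted_median <- function(x, w) weighted_quantile(x, w, 0.5)

#' Mutation-adjusted median rate of phenotypic change
#'
#' Weighted median (and IQR) of the survivors' trait-scaled rates of
#' phenotypic change, each survivor weighted by the probability density of
#' its mutation scalar [mut_scalar_pdf()] and normalized by the summed
#' weights. This is the rate expected for surviving populations whose
#' per-generation mutational input is representative of natural
#' populations, correcting the survivors' roughly two-fold enrichment in
#' mutational heritability.
#'
#' @param survivors a survivor subset from [classify_survivors()].
#' @param rate_col column holding the rates (default `"rate_trait"`).
#' @return list with `median`, `q25`, `q75` and `n`.
#' @export
adjusted_median_rate <- function(survivors, rate_col = "rate_trait") {
  if (nrow(survivors) == 0)
    stop("adjusted_median_rate undefined for an empty survivor set")
  x <- survivors[[rate_col]]
  w <- mut_scalar_pdf(survivors$mut_scalar)
  q <- weighted_quantile(x, w, c(0.25, 0.5, 0.75))
  list(median = q[2], q25 = q[1], q75 = q[3], n = nrow(survivors))
}

#' Equal-count binned summaries
#'
#' Divides the rows into `n_bins` bins with (as near as possible) equal
#' numbers of populations, ordered by `x_col` (ties broken by stable rank
#' order), and summarises `y_col` within each bin by its median, quartiles
#' and range.
#'
#' @param table a data.frame.
#' @param x_col,y_col column names.
#' @param n_bins number of equal-count bins (>= 1).
#' @return data.frame with one row per bin.
#' @export
binned_summary <- function(table, x_col, y_col, n_bins) {
  stopifnot(n_bins >= 1)
  x <- table[[x_col]]
  y <- table[[y_col]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  o <- order(x)
  n <- length(o)
  stopifnot(n >= n_bins)
  edges <- round(seq(0, n, length.out = n_bins + 1))
  out <- lapply(seq_len(n_bins), function(b) {
    idx <- o[(edges[b] + 1):edges[b + 1]]
    qs <- quantile(y[idx], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(
      bin = b, n = length(idx),
      x_median = median(x[idx]), x_min = min(x[idx]), x_max = max(x[idx]),
      y_median = qs[2], y_q25 = qs[1], y_q75 = qs[3],
      y_min = min(y[idx]), y_max = max(y[idx])
    )
  })
  do.call(rbind, out)
}

#' Log-log survival-versus-lag regression
#'
#' Ordinary least squares of `log10(generations to extinction)` on
#' `log10(lag rate)` and its square, over the extinct populations with
#' positive lag. Returns the coefficients, R-squared and the two-tailed
#' p-value of the quadratic term; a significant negative quadratic term
#' indicates that survival time falls faster than logarithmically as lag
#' grows.
#'
#' @param table an ensemble table from [run_ensemble()].
#' @return list with `coefficients`, `r_squared`, `quadratic_p` and `n`.
#' @export
lag_survival_regression <- function(table) {
  keep <- is.na(table$error) &
    !vapply(table$prestab_extinct, isTRUE, logical(1)) &
    !vapply(table$survived_cap, isTRUE, logical(1)) &
    is.finite(table$gens_to_extinction) & table$gens_to_extinction > 0 &
    is.finite(table$lag_rate) & table$lag_rate > 0
  d <- table[keep, , drop = FALSE]
  if (nrow(d) < 3)
    stop("lag_survival_regression undefined with fewer than 3 usable rows")
  lx <- log10(d$lag_rate)
  ly <- log10(d$gens_to_extinction)
  fit <- lm(ly ~ lx + I(lx^2))
  sm <- summary(fit)
  co <- coef(fit)
  names(co) <- c("intercept", "log_lag", "log_lag_sq")
  list(coefficients = co, r_squared = sm$r.squared,
       quadratic_p = sm$coefficients["I(lx^2)", 4], n = nrow(d))
}
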