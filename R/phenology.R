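#' Pooled within-population trait sd of a phenology series
#'
#' Inverse-variance-style pooling: the square root of the mean annual
#' variance, weighted by `n_obs - 1` where annual sample sizes are
#' available and equally otherwise.
#'
#' @param series a phenology data.frame with `trait_sd` and optionally
#'   `n_obs`.
#' @return pooled sd (same units as the trait).
#' @export
pooled_trait_sd <- function(series) {
  stopifnot(all(is.finite(series$trait_sd)), all(series$trait_sd > 0))
  w <- if (!is.null(series$n_obs) && all(is.finite(series$n_obs)))
    pmax(series$n_obs - 1, 1) else rep(1, nrow(series))
  sqrt(sum(w * series$trait_sd^2) / sum(w))
}

#' Standardized annual rate of phenological change
#'
#' OLS slope of the annual trait means, standardized by the pooled
#' within-population sd, on calendar year. Advancing phenologies (dates
#' getting earlier, i.e. a negative raw slope) are reported as positive
#' rates. Multiplying by the generation time converts to sd per generation.
#'
#' @param series data.frame with columns `year`, `trait_mean`, `trait_sd`
#'   and optionally `n_obs` and `generation_time`; at least 3 years.
#' @param generation_time years per generation; defaults to the series'
#'   `generation_time` column when present.
#' @return object of class `rate_estimate`: a list with `rate_per_annum`,
#'   `rate_per_generation`, `years_studied`, `slope_se` and `slope_p`
#'   (two-tailed); a constant series gives rate 0 with `slope_p = NA`.
#' @export
standardized_annual_rate <- function(series, generation_time = NULL) {
  stopifnot(nrow(series) >= 3)
  series <- series[order(series$year), , drop = FALSE]
  stopifnot(!anyDuplicated(series$year))
  if (is.null(generation_time) && !is.null(series$generation_time))
    generation_time <- series$generation_time[1]
  sd_pool <- pooled_trait_sd(series)
  z <- series$trait_mean / sd_pool
  if (var(series$trait_mean) == 0) {
    rate <- 0
    se <- 0
    p <- NA_real_
  } else {
    fit <- lm(z ~ year, data = data.frame(z = z, year = series$year))
    sm <- summary(fit)$coefficients
    rate <- -sm["year", "Estimate"]
    se <- sm["year", "Std. Error"]
    p <- sm["year", "Pr(>|t|)"]
  }
  out <- list(
    rate_per_annum = rate,
    rate_per_generation = if (is.null(generation_time)) NA_real_
                          else rate * generation_time,
    years_studied = nrow(series),
    slope_se = se,
    slope_p = p
  )
  class(out) <- "rate_estimate"
  out
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Standardized rate: %.4f sd/yr over %d years (p = %.3g)\n",
              x$rate_per_annum, x$years_studied, x$slope_p))
  if (is.finite(x$rate_per_generation))
    cat(sprintf("  per generation: %.4f sd\n", x$rate_per_generation))
  invisible(x)
}

#' Power-law decay of rates with study length
#'
#' Fits `rate = a * years^b` by OLS on the log-log scale across a set of
#' populations with positive rates — the pattern whereby the longer a
#' population has been studied, the slower its apparent rate of change.
#'
#' @param rates data.frame with columns `rate_per_annum` and
#'   `years_studied` (one row per population).
#' @return list with `a`, `b`, `r` (log-log correlation) and `n`.
#' @export
rate_decay_fit <- function(rates) {
  keep <- is.finite(rates$rate_per_annum) & rates$rate_per_annum > 0 &
    is.finite(rates$years_studied) & rates$years_studied > 0
  d <- rates[keep, , drop = FALSE]
  if (nrow(d) < 4)
    stop("rate_decay_fit needs at least 4 populations with positive rates")
  lx <- log(d$years_studied)
  ly <- log(d$rate_per_annum)
  fit <- lm(ly ~ lx)
  list(a = exp(coef(fit)[[1]]), b = coef(fit)[[2]],
       r = if (var(ly) > 0 && var(lx) > 0) cor(lx, ly) else 0, n = nrow(d))
}

#' Trend in within-population phenotypic variance
#'
#' OLS of the annual variance (`trait_sd^2`) on the year index `t` (years
#' since the first observation), and on `t` together with `sqrt(t)` — the
#' square-root term captures an initially faster decline.
#'
#' @param series phenology data.frame with >= 4 years of `trait_sd`.
#' @return list with components `linear` (coefficients and p-values of the
#'   `t`-only fit) and `with_sqrt` (the `t + sqrt(t)` fit).
#' @export
variance_trend_fit <- function(series) {
  stopifnot(nrow(series) >= 4, all(is.finite(series$trait_sd)))
  series <- series[order(series$year), , drop = FALSE]
  t <- series$year - min(series$year)
  v <- series$trait_sd^2
  f1 <- lm(v ~ t)
  f2 <- lm(v ~ t + sqrt(t))
  s1 <- summary(f1)$coefficients
  s2 <- summary(f2)$coefficients
  list(
    linear = list(coefficients = coef(f1),
                  p_linear = s1["t", "Pr(>|t|)"]),
    with_sqrt = list(coefficients = coef(f2),
                     p_linear = s2["t", "Pr(>|t|)"],
                     p_sqrt = s2["sqrt(t)", "Pr(>|t|)"])
  )
}

#' Generate synthetic longitudinal phenology series
#'
#' Emulates a panel of field phenology studies (annual trait means and sds
#' for bird-like populations with advancing phenology): per-series study
#' lengths are log-normal around `years`, standardized advance rates are
#' log-normal around `rate_sd_per_annum`, annual means decline accordingly
#' with observation noise `sd0 / sqrt(n_obs)`, and within-year variance can
#' decline over the series through linear and square-root-of-time
#' components. Defaults mimic a panel with median advance about 0.022
#' sd/yr over a median of 29 years. This generator emulates sampling noise
#' and variance erosion only — not plasticity, shared climate forcing
#' across series, or autocorrelated year effects.
#'
#' @param n_series number of populations (default 25).
#' @param years median study length in years (default 29).
#' @param rate_sd_per_annum median standardized advance, sd/yr
#'   (default 0.022; 0 gives flat expected series).
#' @param rate_spread log-scale spread of per-series rates (default 0.7).
#' @param length_spread log-scale spread of study lengths (default 0.35;
#'   0 fixes every series at `years`).
#' @param variance_decline total fractional decline of the annual variance
#'   over a series attributed to the linear term (default 0).
#' @param variance_decline_sqrt fractional decline attributed to the
#'   square-root-of-time term (default 0).
#' @param n_obs annual sample size driving observation noise (default 50;
#'   `Inf` gives noise-free means).
#' @param generation_time years per generation (default 2).
#' @param start_year first calendar year (default 1960).
#' @param seed optional RNG seed.
#' @return data.frame with columns `species`, `year`, `trait_mean`,
#'   `trait_sd`, `n_obs`, `generation_time`.
#' @export
generate_synthetic_phenology <- function(n_series = 25, years = 29,
                                         rate_sd_per_annum = 0.022,
                                         rate_spread = 0.7,
                                         length_spread = 0.35,
                                         variance_decline = 0,
                                         variance_decline_sqrt = 0,
                                         n_obs = 50, generation_time = 2,
                                         start_year = 1960, seed = NULL) {
  stopifnot(n_series >= 1, years >= 3, rate_sd_per_annum >= 0,
            variance_decline >= 0, variance_decline_sqrt >= 0,
            variance_decline + variance_decline_sqrt < 1, n_obs > 1)
  if (!is.null(seed)) set.seed(seed)
  sd0 <- 1
  out <- lapply(seq_len(n_series), function(i) {
    ny <- if (length_spread > 0)
      max(7, round(rlnorm(1, log(years), length_spread))) else years
    rate <- if (rate_sd_per_annum > 0 && rate_spread > 0)
      rlnorm(1, log(rate_sd_per_annum), rate_spread) else rate_sd_per_annum
    t <- 0:(ny - 1)
    frac <- t / max(t)
    v <- sd0^2 * pmax(1 - variance_decline * frac -
                        variance_decline_sqrt * sqrt(frac), 0.05)
    noise <- if (is.finite(n_obs)) rnorm(ny, 0, sd0 / sqrt(n_obs)) else 0
    data.frame(
      species = sprintf("species_%02d", i),
      year = start_year + t,
      trait_mean = 100 - rate * sd0 * t + noise,
      trait_sd = sqrt(v),
      n_obs = if (is.finite(n_obs)) n_obs else NA_real_,
      generation_time = generation_time
    )
  })
  do.call(rbind, out)
}

#' Read a phenology series table from CSV
#'
#' Thin reader for longitudinal trait series. The file must provide (after
#' applying `col_map`) the columns `year`, `trait_mean` and `trait_sd`;
#' `n_obs`, `species` and `generation_time` are optional.
#'
#' @param path CSV file path.
#' @param col_map named character vector mapping required names to the
#'   file's column names, e.g. `c(trait_mean = "mean_laying_date")`.
#' @return data.frame in the package's phenology layout.
#' @export
read_phenology_csv <- function(path, col_map = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(d))
        stop(sprintf("column '%s' not found in %s", col_map[[nm]], path))
      names(d)[names(d) == col_map[[nm]]] <- nm
    }
  }
  need <- c("year", "trait_mean", "trait_sd")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing phenology columns: ", paste(miss, collapse = ", "))
  d
}
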