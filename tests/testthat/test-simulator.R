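test_that("initial populations carry the configured genetic variance", {
  cfg <- test_config(n_pop = 20000, k_loci = 50)
  set.seed(21)
  al <- init_population(cfg)
  expect_equal(dim(al), c(100, 20000))
  g <- genotypic_values(al)
  # genotype = sum of 2k iid N(0, sigma_g2_init/(2k)) values
  expect_equal(var(g), cfg$sigma_g2_init, tolerance = 0.05)
  expect_equal(mean(g), 0, tolerance = 4 * sqrt(cfg$sigma_g2_init / 20000))

  cfg0 <- pop_config(sigma_T2 = 0.02, h2 = 1e-12, omega = 1,
                     delta_env = 0, mut_scalar = 0.004, n_pop = 10)
  cfg0$sigma_g2_init <- 0  # exactly no genetic variance
  expect_true(all(init_population(cfg0) == 0))

  set.seed(5)
  a <- init_population(test_config(n_pop = 50, k_loci = 10))
  set.seed(5)
  b <- init_population(test_config(n_pop = 50, k_loci = 10))
  expect_identical(a, b)
})

test_that("phenotypes add fresh environmental noise to genotypes", {
  g <- rnorm(50000, 2, 0.1)
  expect_identical(phenotypes(g, 0), g)
  set.seed(22)
  p <- phenotypes(g, 0.05)
  expect_equal(mean(p), mean(g), tolerance = 4 * sqrt(0.05 / 50000) + 1e-3)
  expect_equal(var(p), var(g) + 0.05, tolerance = 0.01)
})

test_that("Gaussian fitness is scaled to 1 at the optimum", {
  expect_equal(gaussian_fitness(3, 3, 2), 1)
  expect_equal(gaussian_fitness(1, 0, 1), exp(-1 / 2))
  expect_equal(gaussian_fitness(5, 0, 1e9), 1, tolerance = 1e-12)
  # omega = 0 degenerates to the indicator of an exact match
  expect_equal(gaussian_fitness(c(0, 1), 0, 0), c(1, 0))
})

test_that("survival is an independent coin toss with probability w", {
  expect_identical(select_survivors(rep(0.5, 100), 0.5, 1), 1:100)
  ph <- seq(-1, 1, length.out = 200)
  w <- gaussian_fitness(ph, 0, 0.5)
  set.seed(23)
  counts <- replicate(2000, length(select_survivors(ph, 0, 0.5)))
  expected <- sum(w)
  se <- sqrt(sum(w * (1 - w)) / 2000)
  expect_lt(abs(mean(counts) - expected), 4 * se)
  # very strong selection with off-optimum phenotypes kills everyone
  set.seed(24)
  expect_length(select_survivors(rnorm(1000, 1, 0.1), 0, 1e-6), 0)
})

test_that("gametes recombine along a linear map and mutate additively", {
  k <- 100
  hapA <- rep(0, k)
  hapB <- rep(1, k)
  # no crossovers, no mutation: gamete is one parental haplotype
  set.seed(25)
  for (i in 1:20) {
    g <- make_gamete(hapA, hapB, mu_r = 0, mu_m = 0, m2 = 1e-4)
    expect_true(all(g == 0) || all(g == 1))
  }
  # with recombination the gamete is a mosaic of the two haplotypes and
  # draws each locus from either parent with overall probability 1/2
  set.seed(26)
  gs <- replicate(4000, make_gamete(hapA, hapB, mu_r = 3, mu_m = 0, m2 = 0))
  expect_true(all(gs %in% c(0, 1)))
  expect_equal(mean(gs), 0.5, tolerance = 0.02)
  switches <- apply(gs, 2, function(g) sum(diff(g) != 0))
  # switch points only arise from crossovers: mean <= mu_r (pairwise
  # cancellation and same-source switches can only reduce the count)
  expect_lt(mean(switches), 3 + 4 * sd(switches) / sqrt(ncol(gs)))
  expect_gt(mean(switches), 1)
})

test_that("mutation counts and injected variance match the mutational model", {
  k <- 100
  mu_m <- 0.01  # inflated so counts are measurable
  m2 <- 4e-4
  zero <- rep(0, k)
  set.seed(27)
  gs <- replicate(20000, make_gamete(zero, zero, mu_r = 0, mu_m = mu_m,
                                     m2 = m2))
  nmut <- colSums(gs != 0)
  lambda <- k * mu_m
  expect_lt(abs(mean(nmut) - lambda), 4 * sqrt(lambda / 20000))
  # per-gamete injected variance = k mu_m m2 (half the diploid sigma_m2)
  v <- var(colSums(gs))
  expect_equal(v, lambda * m2, tolerance = 0.1)
})

test_that("reproduction returns the population to carrying capacity", {
  cfg <- test_config(n_pop = 200, k_loci = 20)
  set.seed(28)
  al <- init_population(cfg)
  for (ns in c(2, 3, 17, 200)) {
    off <- reproduce(al, seq_len(ns), cfg$n_pop, cfg$mu_r, cfg$mu_m, cfg$m2)
    expect_equal(ncol(off$alleles), 200)
    expect_equal(off$genotypes, colSums(off$alleles))
  }
  expect_error(reproduce(al, integer(0), 200, 3, 1e-4, 1e-4), "extinction")
  expect_error(reproduce(al, 1L, 200, 3, 1e-4, 1e-4), "extinction")
})

test_that("with two survivors every offspring allele comes from them", {
  cfg <- test_config(n_pop = 50, k_loci = 10)
  set.seed(29)
  al <- init_population(cfg)
  off <- reproduce(al, c(4L, 9L), 50, mu_r = 3, mu_m = 0, m2 = 0)
  pool <- c(al[, 4], al[, 9])
  expect_true(all(off$alleles %in% pool))
})

test_that("reproduction is directionally unbiased", {
  cfg <- test_config(n_pop = 400, k_loci = 20)
  set.seed(30)
  al <- init_population(cfg)
  surv <- sample.int(400, 150)
  parent_mean <- mean(colSums(al[, surv]))
  means <- replicate(300, {
    off <- reproduce(al, surv, 400, mu_r = 3, mu_m = cfg$mu_m, m2 = cfg$m2)
    mean(off$genotypes)
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - parent_mean), 4 * se)
})

test_that("identical configuration and seed give identical trajectories", {
  cfg <- test_config(n_pop = 300, k_loci = 50, seed = 31)
  t1 <- run_population(cfg, stab_gens = 60, max_dir_gens = 40)
  t2 <- run_population(cfg, stab_gens = 60, max_dir_gens = 40)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$eq_geno_var, t2$eq_geno_var)
})

test_that("a neutral stabilising-only run survives with a bounded mean", {
  cfg <- pop_config(sigma_T2 = 0.022, h2 = 0.4, omega = 8, delta_env = 0,
                    mut_scalar = 0.0044, k_loci = 100, mu_r = 3,
                    n_pop = 500, seed = 32)
  traj <- run_population(cfg, stab_gens = 300, max_dir_gens = 50)
  expect_true(traj$survived_cap)
  expect_true(is.na(traj$extinct_at))
  expect_lt(max(abs(traj$records$pheno_mean)), 10 * sqrt(cfg$sigma_T2))
  # survived_cap XOR extinction bookkeeping
  expect_true(xor(traj$survived_cap,
                  !is.na(traj$extinct_at) || traj$prestab_extinct))
})

test_that("a near-maximal rate of environmental change kills quickly", {
  cfg <- pop_config(sigma_T2 = 0.022, h2 = 0.4, omega = 0.3,
                    delta_env = 0.29, mut_scalar = 0.0044, k_loci = 100,
                    mu_r = 3, n_pop = 500, seed = 33)
  traj <- run_population(cfg, stab_gens = 200, max_dir_gens = 2000)
  expect_false(traj$survived_cap)
  expect_lt(traj$extinct_at, 50)
})

test_that("tiny omega drives extinction before directional selection", {
  cfg <- pop_config(sigma_T2 = 0.022, h2 = 0.4, omega = 1e-4,
                    delta_env = 0.1, mut_scalar = 0.0044, k_loci = 100,
                    mu_r = 3, n_pop = 200, seed = 34)
  traj <- run_population(cfg, stab_gens = 100, max_dir_gens = 100)
  expect_true(traj$prestab_extinct)
  expect_false(traj$survived_cap)
  expect_true(is.na(traj$extinct_at))
})

test_that("phenotypic variance decomposes into genetic plus environmental", {
  cfg <- test_config(n_pop = 1000, k_loci = 100, delta_env = 0.02, seed = 35)
  traj <- run_population(cfg, stab_gens = 300, max_dir_gens = 100)
  r <- traj$records
  gap <- r$pheno_var - (r$geno_var + cfg$sigma_e2)
  # per-generation sampling error of a variance at n = 1000 is a few
  # percent; the mean over hundreds of generations must be far tighter
  expect_lt(abs(mean(gap)) / mean(r$pheno_var), 0.02)
})

test_that("realized initial heritability matches the drawn h2", {
  devs <- sapply(1:3, function(i) {
    cfg <- test_config(n_pop = 1000, k_loci = 100, seed = 40 + i)
    traj <- run_population(cfg, stab_gens = 5, max_dir_gens = 0,
                           tail_window = 5)
    r1 <- traj$records[1, ]
    r1$geno_var / r1$pheno_var - cfg$h2
  })
  expect_lt(abs(mean(devs)), 0.06)
})

test_that("neutral evolution gains sigma_m2 of genetic variance per generation", {
  slopes <- sapply(1:3, function(i) {
    cfg <- pop_config(sigma_T2 = 0.02, h2 = 0.05, omega = 1e6,
                      delta_env = 0, mut_scalar = 0.01, k_loci = 100,
                      mu_r = 3, n_pop = 1000, seed = 50 + i)
    traj <- run_population(cfg, stab_gens = 250, max_dir_gens = 0,
                           tail_window = 250)
    r <- traj$records
    coef(lm(geno_var ~ generation, data = r))[["generation"]]
  })
  cfg <- pop_config(sigma_T2 = 0.02, h2 = 0.05, omega = 1e6, delta_env = 0,
                    mut_scalar = 0.01, k_loci = 100, mu_r = 3, n_pop = 1000)
  expect_equal(mean(slopes), cfg$sigma_m2, tolerance = 0.25)
})

test_that("directional onset transiently inflates the genetic variance", {
  ratios <- sapply(1:3, function(i) {
    cfg <- pop_config(sigma_T2 = 0.03, h2 = 0.5, omega = 1,
                      delta_env = 0.03, mut_scalar = 0.008, k_loci = 100,
                      mu_r = 3, n_pop = 1000, seed = 60 + i)
    traj <- run_population(cfg, stab_gens = 1200, max_dir_gens = 400,
                           tail_window = 400)
    r <- traj$records
    max(r$geno_var[r$phase == 1]) / traj$eq_geno_var
  })
  expect_gt(median(ratios), 1)
})
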