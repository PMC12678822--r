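#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// uniform integer in [0, n)
static inline int rand_below(int n) {
  int i;
  do { i = (int)(unif_rand() * n); } while (i >= n);
  return i;
}

// Poisson draw by CDF inversion from a single uniform; p0 = exp(-lambda)
// precomputed by the caller. Falls back to R::rpois for large means.
static inline int rpois_inv(double lambda, double p0) {
  if (lambda <= 0) return 0;
  if (lambda > 30) return (int)R::rpois(lambda);
  double u = unif_rand();
  double p = p0, cum = p0;
  int m = 0;
  while (u > cum && m < 10000) {
    ++m;
    p *= lambda / m;
    cum += p;
  }
  return m;
}

struct GameteScratch {
  std::vector<int> co;
  std::vector<int> hits;
};

// fused copy + sum over a locus range
static inline double copy_sum(const double* h, int a, int b, double* out) {
  double s = 0.0;
  for (int j = a; j < b; ++j) {
    out[j] = h[j];
    s += h[j];
  }
  return s;
}

// Build one gamete from a parent's two haplotypes.
// Crossover count ~ Poisson(mu_r), positions uniform over the k-1 inter-locus
// boundaries; the copied haplotype alternates at each crossover (two
// crossovers in the same boundary cancel pairwise via the parity toggle).
// Mutation count ~ Poisson(k * mu_m); mutated loci distinct; each mutation
// adds a N(0, m_sd^2) increment to the existing allelic value
// (continuum-of-alleles). Returns the gamete's summed allelic value.
static double gamete_into(const double* hA, const double* hB, int k,
                          double mu_r, double p0_r, double k_mu_m,
                          double p0_m, double m_sd, double* out,
                          GameteScratch& sc) {
  const double* src[2] = {hA, hB};
  int cur = (unif_rand() < 0.5) ? 1 : 0;
  const int nco = (k > 1) ? rpois_inv(mu_r, p0_r) : 0;
  double s;
  if (nco == 0) {
    s = copy_sum(src[cur], 0, k, out);
  } else {
    sc.co.resize(nco);
    for (int i = 0; i < nco; ++i) sc.co[i] = 1 + rand_below(k - 1);
    std::sort(sc.co.begin(), sc.co.end());
    s = 0.0;
    int start = 0, ci = 0;
    while (ci < nco) {
      const int b = sc.co[ci];
      if (b > start) {
        s += copy_sum(src[cur], start, b, out);
        start = b;
      }
      while (ci < nco && sc.co[ci] == b) { cur ^= 1; ++ci; }
    }
    s += copy_sum(src[cur], start, k, out);
  }
  int nmu = rpois_inv(k_mu_m, p0_m);
  if (nmu > k) nmu = k;
  if (nmu > 0) {
    // distinct loci; nmu is almost always 0 or 1, rejection is cheap
    sc.hits.clear();
    for (int i = 0; i < nmu; ++i) {
      int L;
      bool dup;
      do {
        L = rand_below(k);
        dup = false;
        for (size_t j = 0; j < sc.hits.size(); ++j)
          if (sc.hits[j] == L) { dup = true; break; }
      } while (dup);
      sc.hits.push_back(L);
      double d = norm_rand() * m_sd;
      out[L] += d;
      s += d;
    }
  }
  return s;
}

// Fill dst (2k x n_offspring, column-major) by random mating with replacement
// among survivors; the two parents of an offspring are distinct individuals.
static void reproduce_core(const double* src, int k,
                           const std::vector<int>& surv, int n_offspring,
                           double mu_r, double k_mu_m, double m_sd,
                           double* dst, double* geno) {
  const int ns = (int)surv.size();
  const size_t two_k = (size_t)2 * k;
  const double p0_r = std::exp(-mu_r);
  const double p0_m = std::exp(-k_mu_m);
  GameteScratch sc;
  sc.co.reserve(64);
  sc.hits.reserve(16);
  for (int i = 0; i < n_offspring; ++i) {
    int a = surv[rand_below(ns)];
    int b;
    do { b = surv[rand_below(ns)]; } while (b == a);
    const double* pa = src + two_k * a;
    const double* pb = src + two_k * b;
    double* off = dst + two_k * i;
    double s1 = gamete_into(pa, pa + k, k, mu_r, p0_r, k_mu_m, p0_m,
                            m_sd, off, sc);
    double s2 = gamete_into(pb, pb + k, k, mu_r, p0_r, k_mu_m, p0_m,
                            m_sd, off + k, sc);
    geno[i] = s1 + s2;
  }
}

// [[Rcpp::export]]
NumericVector cpp_make_gamete(NumericVector hapA, NumericVector hapB,
                              double mu_r, double mu_m, double m2) {
  const int k = hapA.size();
  if (hapB.size() != k) stop("haplotypes must have equal length");
  NumericVector out(k);
  GameteScratch sc;
  const double km = (double)k * mu_m;
  gamete_into(REAL(hapA), REAL(hapB), k, mu_r, std::exp(-mu_r), km,
              std::exp(-km), std::sqrt(m2), REAL(out), sc);
  return out;
}

// [[Rcpp::export]]
List cpp_reproduce(NumericMatrix alleles, IntegerVector survivors,
                   int n_offspring, double mu_r, double mu_m, double m2) {
  const int two_k = alleles.nrow();
  const int k = two_k / 2;
  if (two_k != 2 * k) stop("allele matrix must have 2*k rows");
  std::vector<int> surv(survivors.size());
  for (int i = 0; i < survivors.size(); ++i) {
    surv[i] = survivors[i] - 1;  // to 0-based
    if (surv[i] < 0 || surv[i] >= alleles.ncol())
      stop("survivor index out of range");
  }
  if ((int)surv.size() < 2) stop("need at least 2 survivors to reproduce");
  NumericMatrix out(two_k, n_offspring);
  NumericVector geno(n_offspring);
  reproduce_core(REAL(alleles), k, surv, n_offspring, mu_r,
                 (double)k * mu_m, std::sqrt(m2), REAL(out), REAL(geno));
  return List::create(_["alleles"] = out, _["genotypes"] = geno);
}

// One full population run: stab_gens generations of stabilising selection
// (optimum fixed at 0) followed by directional selection (optimum moved by
// delta_env every generation) until extinction (<= 1 survivor) or
// max_dir_gens. Records are thinned: last tail_window stabilising
// generations in full, directional generations up to dir_full in full, then
// every dir_thin-th (extinction / cap generations always recorded).
// [[Rcpp::export]]
List cpp_run_population(NumericMatrix alleles, double sigma_e2, double omega,
                        double delta_env, double mu_r, double mu_m, double m2,
                        int stab_gens, int max_dir_gens, int tail_window,
                        int dir_full, int dir_thin) {
  const int two_k = alleles.nrow();
  const int k = two_k / 2;
  const int n = alleles.ncol();
  if (stab_gens < 1) stop("stab_gens must be >= 1");
  const double e_sd = std::sqrt(sigma_e2);
  const double m_sd = std::sqrt(m2);
  const double k_mu_m = (double)k * mu_m;
  const double two_om2 = 2.0 * omega * omega;

  std::vector<double> cur(alleles.begin(), alleles.end());
  std::vector<double> nxt(cur.size());
  std::vector<double> geno(n), ph(n);
  for (int i = 0; i < n; ++i) {
    const double* p = cur.data() + (size_t)two_k * i;
    double s = 0.0;
    for (int j = 0; j < two_k; ++j) s += p[j];
    geno[i] = s;
  }

  std::vector<int> surv;
  surv.reserve(n);
  std::vector<double> rec;  // 10 values per recorded generation

  double theta = 0.0;
  bool extinct = false, prestab = false;
  int extinct_dir_at = -1, extinct_stab_at = -1;
  double eq_g = 0.0, eq_p = 0.0;
  int eq_n = 0;
  double surv_stab_sum = 0.0;
  int surv_stab_n = 0;
  double onset_mean = NA_REAL, final_mean = NA_REAL;
  double sum_gap = 0.0, sum_surv_dir = 0.0;
  int dir_gens = 0;
  int first50 = -1;
  double mean_at_50 = NA_REAL;

  const int total = stab_gens + max_dir_gens;
  const int stab_rec_from = stab_gens - tail_window;

  for (int gen = 1; gen <= total; ++gen) {
    const bool dirphase = gen > stab_gens;
    const int dgen = dirphase ? gen - stab_gens : 0;
    if (dirphase) theta += delta_env;

    double sp = 0, sp2 = 0, sg = 0, sg2 = 0;
    for (int i = 0; i < n; ++i) {
      double pi = geno[i];
      if (e_sd > 0) pi += norm_rand() * e_sd;
      ph[i] = pi;
      sp += pi;
      sp2 += pi * pi;
      sg += geno[i];
      sg2 += geno[i] * geno[i];
    }
    const double pm = sp / n;
    const double pv = n > 1 ? (sp2 - n * pm * pm) / (n - 1.0) : 0.0;
    const double gm = sg / n;
    const double gv = n > 1 ? (sg2 - n * gm * gm) / (n - 1.0) : 0.0;

    surv.clear();
    double ssurv = 0.0;
    if (omega > 0) {
      for (int i = 0; i < n; ++i) {
        const double d = ph[i] - theta;
        const double w = std::exp(-(d * d) / two_om2);
        if (unif_rand() < w) { surv.push_back(i); ssurv += ph[i]; }
      }
    } else {
      // omega = 0: fitness is the indicator of an exact optimum match
      for (int i = 0; i < n; ++i)
        if (ph[i] == theta) { surv.push_back(i); ssurv += ph[i]; }
    }
    const int ns = (int)surv.size();
    const double mort = 1.0 - (double)ns / n;
    const double smean = ns > 0 ? ssurv / ns : NA_REAL;
    const bool dying = ns <= 1;

    const bool recit = dirphase
      ? (dgen <= dir_full || dgen % dir_thin == 0 || dying ||
         dgen == max_dir_gens)
      : (gen > stab_rec_from || dying);
    if (recit) {
      rec.push_back(gen);
      rec.push_back(dirphase ? 1.0 : 0.0);
      rec.push_back(theta);
      rec.push_back(pm);
      rec.push_back(pv);
      rec.push_back(gm);
      rec.push_back(gv);
      rec.push_back(ns);
      rec.push_back(mort);
      rec.push_back(smean);
    }

    if (!dirphase) {
      if (gen > stab_rec_from) {
        eq_g += gv;
        eq_p += pv;
        ++eq_n;
        surv_stab_sum += ns;
        ++surv_stab_n;
      }
      if (gen == stab_gens) onset_mean = pm;
    } else {
      dir_gens = dgen;
      sum_gap += theta - pm;
      sum_surv_dir += ns;
      final_mean = pm;
      if (first50 < 0 && mort > 0.5) {
        first50 = dgen;
        mean_at_50 = pm;
      }
    }

    if (dying) {
      extinct = true;
      if (dirphase) extinct_dir_at = dgen;
      else { prestab = true; extinct_stab_at = gen; }
      break;
    }
    reproduce_core(cur.data(), k, surv, n, mu_r, k_mu_m, m_sd,
                   nxt.data(), geno.data());
    cur.swap(nxt);
    if (gen % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  const int nrec = (int)(rec.size() / 10);
  NumericMatrix recm(nrec, 10);
  for (int r = 0; r < nrec; ++r)
    for (int c = 0; c < 10; ++c) recm(r, c) = rec[(size_t)r * 10 + c];
  colnames(recm) = CharacterVector::create(
      "generation", "phase", "optimum", "pheno_mean", "pheno_var",
      "geno_mean", "geno_var", "n_survivors", "mortality", "surv_pheno_mean");

  return List::create(
      _["records"] = recm,
      _["prestab_extinct"] = prestab,
      _["extinct_stab_at"] = extinct_stab_at,
      _["extinct_dir_at"] = extinct_dir_at,
      _["survived_cap"] = !extinct,
      _["dir_gens"] = dir_gens,
      _["onset_mean"] = onset_mean,
      _["final_mean"] = final_mean,
      _["sum_gap"] = sum_gap,
      _["sum_surv_dir"] = sum_surv_dir,
      _["eq_geno_var"] = eq_n > 0 ? eq_g / eq_n : NA_REAL,
      _["eq_pheno_var"] = eq_n > 0 ? eq_p / eq_n : NA_REAL,
      _["mean_surv_stab_tail"] =
          surv_stab_n > 0 ? surv_stab_sum / surv_stab_n : NA_REAL,
      _["first50"] = first50,
      _["mean_at_50"] = mean_at_50);
}
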