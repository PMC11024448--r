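// Adaptive Metropolis-within-Gibbs sampler for Bernoulli-logit models with
// weighted random-effect terms:
//
//   y_i ~ Bernoulli(logit^-1(x_i' beta + sum_k sum_j w_kij u_kj))
//   u_kj ~ Normal(0, sigma_k^2),  beta ~ Normal(0, prior_beta_sd^2),
//   sigma_k ~ half-Normal(prior_sigma_scale)
//
// Term k supplies, per observation row, a list of level indices and weights
// (CSR layout). A multiple-membership term has weights summing to one over
// each row; a plain random intercept is the special case of a single level
// with weight one. Updates: joint adaptive Metropolis for beta (Haario-style
// covariance adaptation during warmup), single-site random-walk Metropolis
// for each attached u level with Robbins-Monro scale tuning (unattached
// levels are drawn from their conditional, the prior), and random-walk
// Metropolis on log sigma_k. Each chain uses its own deterministic RNG
// stream derived from the seed.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double stable_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli-logit log-likelihood contribution of one row
static inline double llrow(double y, double eta) {
  return y * eta - stable_log1pexp(eta);
}

struct ReTerm {
  int n_levels;
  std::vector<int> row_ptr, idx;      // per-row memberships (CSR over rows)
  std::vector<double> w;
  std::vector<int> rev_ptr, rev_row;  // per-level attachments (CSR over levels)
  std::vector<double> rev_w;
  double sigma_fixed;                 // NaN = free
};

// In-place lower Cholesky of a small SPD matrix; returns false on failure.
static bool chol_lower(std::vector<double>& A, int p) {
  for (int j = 0; j < p; ++j) {
    double d = A[j * p + j];
    for (int k = 0; k < j; ++k) d -= A[j * p + k] * A[j * p + k];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    A[j * p + j] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = A[i * p + j];
      for (int k = 0; k < j; ++k) s -= A[i * p + k] * A[j * p + k];
      A[i * p + j] = s / d;
    }
  }
  return true;
}

// [[Rcpp::export(name = ".mm_logit_mcmc")]]
List mm_logit_mcmc(NumericVector y, NumericMatrix X, List re_terms,
                   int n_chains, int n_warmup, int n_draws,
                   double prior_beta_sd, double prior_sigma_scale,
                   int seed, bool save_u,
                   NumericVector beta_init, NumericMatrix beta_prop_cov) {
  const int n = y.size();
  const int p = X.ncol();
  const int K = re_terms.size();

  std::vector<ReTerm> terms(K);
  int total_levels = 0;
  for (int k = 0; k < K; ++k) {
    List t = re_terms[k];
    ReTerm& T = terms[k];
    T.n_levels = as<int>(t["n_levels"]);
    T.row_ptr = as<std::vector<int>>(t["row_ptr"]);
    T.idx = as<std::vector<int>>(t["idx"]);
    T.w = as<std::vector<double>>(t["w"]);
    double sf = as<double>(t["sigma_fixed"]);
    T.sigma_fixed = sf;
    // reverse index: which rows attach to each level, with what weight
    std::vector<int> cnt(T.n_levels, 0);
    for (size_t e = 0; e < T.idx.size(); ++e) cnt[T.idx[e]]++;
    T.rev_ptr.assign(T.n_levels + 1, 0);
    for (int j = 0; j < T.n_levels; ++j) T.rev_ptr[j + 1] = T.rev_ptr[j] + cnt[j];
    T.rev_row.resize(T.idx.size());
    T.rev_w.resize(T.idx.size());
    std::vector<int> fill(T.n_levels, 0);
    for (int i = 0; i < n; ++i) {
      for (int e = T.row_ptr[i]; e < T.row_ptr[i + 1]; ++e) {
        int j = T.idx[e];
        int pos = T.rev_ptr[j] + fill[j]++;
        T.rev_row[pos] = i;
        T.rev_w[pos] = T.w[e];
      }
    }
    total_levels += T.n_levels;
  }

  List chains(n_chains);
  for (int c = 0; c < n_chains; ++c) {
    std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761u + 977u * (c + 1));
    std::normal_distribution<double> rnorm01(0.0, 1.0);
    std::uniform_real_distribution<double> runif01(0.0, 1.0);

    std::vector<double> beta(p);
    for (int j = 0; j < p; ++j) beta[j] = beta_init[j];
    std::vector<std::vector<double>> u(K);
    std::vector<double> sigma(K);
    for (int k = 0; k < K; ++k) {
      u[k].assign(terms[k].n_levels, 0.0);
      double sf = terms[k].sigma_fixed;
      sigma[k] = std::isnan(sf) ? 1.0 : sf;
    }

    std::vector<double> eta(n, 0.0);  // u = 0 at start
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
      eta[i] = e;
    }
    // cached per-row random-effect contribution of each term
    std::vector<std::vector<double>> re_eta(K, std::vector<double>(n, 0.0));

    // adaptation state; the proposal starts from the supplied covariance
    // (typically the Wald covariance of the fixed-effects-only fit) scaled
    // by 2.38^2 / p, and Haario adaptation refines it during warmup
    std::vector<double> bmean(p, 0.0), bcov(p * p, 0.0), prop_chol(p * p, 0.0);
    {
      std::vector<double> C0(p * p);
      double scale = 5.6644 / p;
      for (int j = 0; j < p; ++j)
        for (int k = 0; k < p; ++k)
          C0[j * p + k] = beta_prop_cov(j, k) * scale;
      for (int j = 0; j < p; ++j) C0[j * p + j] += 1e-12;
      if (chol_lower(C0, p)) {
        prop_chol = C0;
      } else {
        for (int j = 0; j < p; ++j)
          prop_chol[j * p + j] = 0.1 / std::sqrt((double)p);
      }
    }
    // overdisperse the chain starts around beta_init
    {
      std::vector<double> z(p);
      for (int j = 0; j < p; ++j) z[j] = rnorm01(rng);
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        for (int k = 0; k <= j; ++k) s += prop_chol[j * p + k] * z[k];
        beta[j] += 2.0 * s;
      }
      for (int i = 0; i < n; ++i) {
        double e = 0.0;
        for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
        eta[i] = e;
      }
    }
    double log_lambda = 0.0;
    int n_hist = 0;
    std::vector<std::vector<double>> ls_u(K);
    for (int k = 0; k < K; ++k) ls_u[k].assign(terms[k].n_levels, std::log(1.0));
    std::vector<double> ls_sigma(K, std::log(0.5));
    std::vector<double> ls_scale(K, std::log(0.1));

    NumericMatrix beta_draws(n_draws, p);
    NumericMatrix sigma_draws(n_draws, K);
    NumericMatrix u_draws(save_u ? n_draws : 0, save_u ? total_levels : 0);
    double beta_acc = 0.0; int beta_try = 0;

    const int n_iter = n_warmup + n_draws;
    std::vector<double> bprop(p), deta(n);
    for (int it = 0; it < n_iter; ++it) {
      const bool warm = it < n_warmup;

      // ---- beta: joint adaptive Metropolis ----
      {
        std::vector<double> z(p);
        for (int j = 0; j < p; ++j) z[j] = rnorm01(rng);
        double lam = std::exp(log_lambda);
        for (int j = 0; j < p; ++j) {
          double s = 0.0;
          for (int k = 0; k <= j; ++k) s += prop_chol[j * p + k] * z[k];
          bprop[j] = beta[j] + lam * s;
        }
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          double d = 0.0;
          for (int j = 0; j < p; ++j) d += X(i, j) * (bprop[j] - beta[j]);
          deta[i] = d;
          dll += llrow(y[i], eta[i] + d) - llrow(y[i], eta[i]);
        }
        double dpr = 0.0;
        for (int j = 0; j < p; ++j)
          dpr -= (bprop[j] * bprop[j] - beta[j] * beta[j]) /
                 (2.0 * prior_beta_sd * prior_beta_sd);
        bool acc = std::log(runif01(rng)) < dll + dpr;
        if (acc) {
          beta = bprop;
          for (int i = 0; i < n; ++i) eta[i] += deta[i];
        }
        if (warm) {
          // Robbins-Monro scale tuning toward 0.234 acceptance
          double g = 1.0 / std::sqrt(it / 10.0 + 1.0);
          log_lambda += g * ((acc ? 1.0 : 0.0) - 0.234);
          // covariance history over the second half of warmup only, so the
          // shape estimate is not fed by the pre-adaptation transient;
          // re-estimation happens once, at the end of warmup
          if (it >= n_warmup / 2) {
            ++n_hist;
            for (int j = 0; j < p; ++j) {
              double dj = beta[j] - bmean[j];
              bmean[j] += dj / n_hist;
              for (int k = 0; k <= j; ++k) {
                double dk = beta[k] - bmean[k];
                bcov[j * p + k] += dj * dk;  // lower triangle accumulation
              }
            }
          }
          if (it == n_warmup - 1 && n_hist >= std::max(50, 4 * p)) {
            std::vector<double> C(p * p, 0.0);
            for (int j = 0; j < p; ++j)
              for (int k = 0; k <= j; ++k) {
                double v = bcov[j * p + k] / (n_hist - 1);
                C[j * p + k] = v;
                C[k * p + j] = v;
              }
            double scale = 5.6644 / p;  // 2.38^2 / p
            for (int j = 0; j < p; ++j)
              for (int k = 0; k < p; ++k) C[j * p + k] *= scale;
            for (int j = 0; j < p; ++j) C[j * p + j] += 1e-9;
            if (chol_lower(C, p)) { prop_chol = C; log_lambda = 0.0; }
          }
        } else {
          beta_acc += acc ? 1.0 : 0.0;
          ++beta_try;
        }
      }

      // ---- u: single-site Metropolis / prior Gibbs ----
      for (int k = 0; k < K; ++k) {
        ReTerm& T = terms[k];
        if (!std::isnan(T.sigma_fixed) && T.sigma_fixed == 0.0) continue;
        double s2 = sigma[k] * sigma[k];
        for (int j = 0; j < T.n_levels; ++j) {
          int a0 = T.rev_ptr[j], a1 = T.rev_ptr[j + 1];
          if (a0 == a1) {  // unattached: conditional is the prior
            u[k][j] = sigma[k] * rnorm01(rng);
            continue;
          }
          double uj = u[k][j];
          double up = uj + std::exp(ls_u[k][j]) * rnorm01(rng);
          double dll = 0.0;
          for (int a = a0; a < a1; ++a) {
            int i = T.rev_row[a];
            double d = T.rev_w[a] * (up - uj);
            dll += llrow(y[i], eta[i] + d) - llrow(y[i], eta[i]);
          }
          dll -= (up * up - uj * uj) / (2.0 * s2);
          bool acc = std::log(runif01(rng)) < dll;
          if (acc) {
            for (int a = a0; a < a1; ++a) {
              double d = T.rev_w[a] * (up - uj);
              eta[T.rev_row[a]] += d;
              re_eta[k][T.rev_row[a]] += d;
            }
            u[k][j] = up;
          }
          if (warm) {
            double g = 1.0 / std::sqrt(it / 10.0 + 1.0);
            ls_u[k][j] += g * ((acc ? 1.0 : 0.0) - 0.44);
          }
        }
      }

      // ---- joint (sigma, u) rescaling: funnel move ----
      // propose sigma' = c sigma, u' = c u with log c ~ N(0, s^2); the
      // Normal(u; 0, sigma) density and the transform Jacobian cancel, so
      // the ratio is likelihood x half-Normal prior x log-scale Jacobian
      for (int k = 0; k < K; ++k) {
        ReTerm& T = terms[k];
        if (!std::isnan(T.sigma_fixed)) continue;
        double eps = std::exp(ls_scale[k]) * rnorm01(rng);
        double cm1 = std::expm1(eps);
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          double d = cm1 * re_eta[k][i];
          if (d != 0.0) dll += llrow(y[i], eta[i] + d) - llrow(y[i], eta[i]);
        }
        double sc = sigma[k], sp = sigma[k] * std::exp(eps);
        dll += (-sp * sp + sc * sc) /
               (2.0 * prior_sigma_scale * prior_sigma_scale) + eps;
        bool acc = std::log(runif01(rng)) < dll;
        if (acc) {
          for (int i = 0; i < n; ++i) {
            double d = cm1 * re_eta[k][i];
            eta[i] += d;
            re_eta[k][i] += d;
          }
          for (int j = 0; j < T.n_levels; ++j) u[k][j] *= std::exp(eps);
          sigma[k] = sp;
        }
        if (warm) {
          double g = 1.0 / std::sqrt(it / 10.0 + 1.0);
          ls_scale[k] += g * ((acc ? 1.0 : 0.0) - 0.44);
        }
      }

      // ---- sigma: random walk on log scale ----
      for (int k = 0; k < K; ++k) {
        ReTerm& T = terms[k];
        if (!std::isnan(T.sigma_fixed)) continue;
        int m = T.n_levels;
        double S = 0.0;
        for (int j = 0; j < m; ++j) S += u[k][j] * u[k][j];
        double lsig = std::log(sigma[k]);
        double lprop = lsig + std::exp(ls_sigma[k]) * rnorm01(rng);
        double sp = std::exp(lprop), sc = sigma[k];
        double lp_new = -m * lprop - S / (2.0 * sp * sp)
                        - sp * sp / (2.0 * prior_sigma_scale * prior_sigma_scale)
                        + lprop;  // Jacobian of log transform
        double lp_old = -m * lsig - S / (2.0 * sc * sc)
                        - sc * sc / (2.0 * prior_sigma_scale * prior_sigma_scale)
                        + lsig;
        bool acc = std::log(runif01(rng)) < lp_new - lp_old;
        if (acc) sigma[k] = sp;
        if (warm) {
          double g = 1.0 / std::sqrt(it / 10.0 + 1.0);
          ls_sigma[k] += g * ((acc ? 1.0 : 0.0) - 0.44);
        }
      }

      // ---- record ----
      if (!warm) {
        int d = it - n_warmup;
        for (int j = 0; j < p; ++j) beta_draws(d, j) = beta[j];
        for (int k = 0; k < K; ++k) sigma_draws(d, k) = sigma[k];
        if (save_u) {
          int off = 0;
          for (int k = 0; k < K; ++k) {
            for (int j = 0; j < terms[k].n_levels; ++j)
              u_draws(d, off + j) = u[k][j];
            off += terms[k].n_levels;
          }
        }
      }
      if (it % 256 == 0) Rcpp::checkUserInterrupt();
    }

    chains[c] = List::create(
      _["beta"] = beta_draws,
      _["sigma"] = sigma_draws,
      _["u"] = u_draws,
      _["beta_accept"] = beta_try > 0 ? beta_acc / beta_try : NA_REAL);
  }
  return chains;
}
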