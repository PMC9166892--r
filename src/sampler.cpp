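// Adaptive Metropolis-within-Gibbs sampler for the Faking Mixture model.
//
// The discrete faking indicator is marginalized analytically, so the
// target is the mixture likelihood
//   P(X_jk = r | theta_j) = pf * softmax(beta_m)_r + (1 - pf) * honest_jkr,
//   pf = Phi(theta_j + alpha_m),  alpha_m = Phi^{-1}(max(SS_m, floor)),
//   SS_m = sum_r (P_mr - 1/R)^2,
// times the priors: free beta ~ N(0, sqrt(Vbeta)), theta ~ N(Mtheta,
// sqrt(Vtheta)), Mtheta ~ N(1, 2), Vtheta ~ InvGamma(1.5, 1) (conjugate,
// Gibbs), Vbeta ~ truncN(5, 10) on (0, 15) (random-walk MH on log scale
// with Jacobian). beta_m1 is fixed at 0 in every beta block.
//
// Beta blocks are indexed separately from questionnaire blocks so that two
// groups can share rank-order parameters on common blocks (multigroup fit):
// person j (group g) on questionnaire block k uses beta block bmap(g-1, k).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double ldnorm(double x, double m, double s) {
  return R::dnorm(x, m, s, 1);
}

// honest array (N x K x R), column-major
static inline double hon(const NumericVector& h, int N, int K, int j, int k,
                         int r) {
  return h[j + (R_xlen_t)N * k + (R_xlen_t)N * K * r];
}

static void softmax_row(const std::vector<double>& b, std::vector<double>& p) {
  const int R = (int)b.size();
  double mx = b[0];
  for (int r = 1; r < R; ++r) if (b[r] > mx) mx = b[r];
  double s = 0.0;
  for (int r = 0; r < R; ++r) { p[r] = std::exp(b[r] - mx); s += p[r]; }
  for (int r = 0; r < R; ++r) p[r] /= s;
}

static double alpha_of(const std::vector<double>& p, double floor_ss) {
  const int R = (int)p.size();
  double ss = 0.0, m = 1.0 / R;
  for (int r = 0; r < R; ++r) ss += (p[r] - m) * (p[r] - m);
  if (ss < floor_ss) ss = floor_ss;
  return R::qnorm(ss, 0.0, 1.0, 1, 0);
}

// Cholesky factor (lower) of a small SPD matrix stored row-major; returns
// false if not positive definite.
static bool chol_small(std::vector<double>& a, int n) {
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = a[i * n + j];
      for (int k = 0; k < j; ++k) s -= a[i * n + k] * a[j * n + k];
      if (i == j) {
        if (s <= 0.0) return false;
        a[i * n + i] = std::sqrt(s);
      } else {
        a[i * n + j] = s / a[j * n + j];
      }
    }
    for (int j = i + 1; j < n; ++j) a[i * n + j] = 0.0;
  }
  return true;
}

static inline double ig_logpdf(double v, double a, double b) {
  return a * std::log(b) - R::lgammafn(a) - (a + 1.0) * std::log(v) - b / v;
}

static inline double tnorm_logpdf(double v, double m, double s, double lo,
                                  double hi) {
  if (v <= lo || v >= hi) return R_NegInf;
  double z = R::pnorm(hi, m, s, 1, 0) - R::pnorm(lo, m, s, 1, 0);
  return R::dnorm(v, m, s, 1) - std::log(z);
}

struct Model {
  int N, K, R, M, G;
  const IntegerMatrix X;       // N x K, 1..R
  const NumericVector honest;  // N x K x R
  const IntegerVector group;   // N, 1..G
  const IntegerMatrix bmap;    // G x K, 1..M
  double floor_ss;
  // state
  std::vector<std::vector<double>> beta;  // M x R, col 0 == 0
  std::vector<std::vector<double>> P;     // softmax rows
  std::vector<double> alpha;              // M
  std::vector<double> theta;              // N
  double mtheta, vtheta, vbeta;
  std::vector<double> PF;                 // N x K, Phi(theta_j + alpha_m)
  // structure: for each beta block m, the (g, k) columns using it;
  // persons listed per group
  std::vector<std::vector<std::pair<int,int>>> uses;
  std::vector<std::vector<int>> persons_of;

  Model(const IntegerMatrix& X_, const NumericVector& honest_,
        const IntegerVector& group_, const IntegerMatrix& bmap_, int R_,
        double floor_ss_)
      : X(X_), honest(honest_), group(group_), bmap(bmap_) {
    N = X.nrow(); K = X.ncol(); R = R_;
    G = bmap.nrow(); floor_ss = floor_ss_;
    M = 0;
    for (int g = 0; g < G; ++g)
      for (int k = 0; k < K; ++k) if (bmap(g, k) > M) M = bmap(g, k);
    uses.assign(M, {});
    for (int g = 0; g < G; ++g)
      for (int k = 0; k < K; ++k) uses[bmap(g, k) - 1].push_back({g, k});
    persons_of.assign(G, {});
    for (int j = 0; j < N; ++j) persons_of[group[j] - 1].push_back(j);
  }

  void refresh_block(int m) {
    softmax_row(beta[m], P[m]);
    alpha[m] = alpha_of(P[m], floor_ss);
  }

  void init_caches() {
    P.assign(M, std::vector<double>(R));
    alpha.assign(M, 0.0);
    for (int m = 0; m < M; ++m) refresh_block(m);
    PF.assign((size_t)N * K, 0.0);
    for (int j = 0; j < N; ++j)
      for (int k = 0; k < K; ++k)
        PF[j + (size_t)N * k] =
            R::pnorm(theta[j] + alpha[bmap(group[j] - 1, k) - 1], 0, 1, 1, 0);
  }

  inline double term(int j, int k, double pf, const std::vector<double>& p)
      const {
    int r = X(j, k) - 1;
    return pf * p[r] + (1.0 - pf) * hon(honest, N, K, j, k, r);
  }

  double loglik() const {
    double ll = 0.0;
    for (int j = 0; j < N; ++j) {
      int g = group[j] - 1;
      for (int k = 0; k < K; ++k) {
        double t = term(j, k, PF[j + (size_t)N * k], P[bmap(g, k) - 1]);
        ll += (t > 0.0) ? std::log(t) : R_NegInf;
      }
    }
    return ll;
  }

  double log_prior(const NumericVector& prior, bool fix_vt,
                   bool fix_vb) const {
    double lp = 0.0;
    double sdb = std::sqrt(vbeta), sdt = std::sqrt(vtheta);
    for (int m = 0; m < M; ++m)
      for (int r = 1; r < R; ++r) lp += ldnorm(beta[m][r], 0.0, sdb);
    for (int j = 0; j < N; ++j) lp += ldnorm(theta[j], mtheta, sdt);
    lp += ldnorm(mtheta, prior[0], prior[1]);
    if (!fix_vt) lp += ig_logpdf(vtheta, prior[2], prior[3]);
    if (!fix_vb) lp += tnorm_logpdf(vbeta, prior[4], prior[5], prior[6],
                                    prior[7]);
    return lp;
  }
};

// [[Rcpp::export]]
double fm_log_posterior_cpp(IntegerMatrix X, NumericVector honest,
                            IntegerVector group, IntegerMatrix bmap, int R,
                            NumericMatrix beta, NumericVector theta,
                            double mtheta, double vtheta, double vbeta,
                            NumericVector prior, bool fix_vtheta,
                            bool fix_vbeta, double floor_ss = 1e-10) {
  Model mod(X, honest, group, bmap, R, floor_ss);
  mod.beta.assign(mod.M, std::vector<double>(R, 0.0));
  for (int m = 0; m < mod.M; ++m)
    for (int r = 0; r < R; ++r) mod.beta[m][r] = beta(m, r);
  mod.theta.assign(theta.begin(), theta.end());
  mod.mtheta = mtheta; mod.vtheta = vtheta; mod.vbeta = vbeta;
  mod.init_caches();
  return mod.loglik() + mod.log_prior(prior, fix_vtheta, fix_vbeta);
}

// [[Rcpp::export]]
List fm_run_chain(IntegerMatrix X, NumericVector honest, IntegerVector group,
                  IntegerMatrix bmap, int R, NumericVector prior,
                  bool fix_vtheta, double vtheta_fixed, bool fix_vbeta,
                  double vbeta_fixed, int n_iter, int n_warmup, int thin,
                  NumericMatrix beta_init, NumericVector theta_init,
                  double mtheta_init, double vtheta_init, double vbeta_init,
                  double floor_ss, double target_accept, int adapt_batch) {
  Model mod(X, honest, group, bmap, R, floor_ss);
  const int N = mod.N, K = mod.K, M = mod.M;
  mod.beta.assign(M, std::vector<double>(R, 0.0));
  for (int m = 0; m < M; ++m)
    for (int r = 0; r < R; ++r) mod.beta[m][r] = beta_init(m, r);
  mod.theta.assign(theta_init.begin(), theta_init.end());
  mod.mtheta = mtheta_init;
  mod.vtheta = fix_vtheta ? vtheta_fixed : vtheta_init;
  mod.vbeta = fix_vbeta ? vbeta_fixed : vbeta_init;
  mod.init_caches();

  // proposal log-scales and batch acceptance counters
  std::vector<std::vector<double>> ls_beta(M, std::vector<double>(R, -1.0));
  std::vector<std::vector<int>> acc_beta(M, std::vector<int>(R, 0));
  std::vector<double> ls_theta(N, -0.7);
  std::vector<int> acc_theta(N, 0);
  double ls_v = -0.7; int acc_v = 0;
  int batch_n = 0;

  const int n_keep = (n_iter - n_warmup) / thin;
  NumericMatrix draws_beta(n_keep, M * (R - 1));
  NumericMatrix draws_theta(n_keep, N);
  NumericVector draws_mtheta(n_keep), draws_vtheta(n_keep),
      draws_vbeta(n_keep), draws_lp(n_keep);

  // joint per-block adaptive-Metropolis state: running mean / scatter of
  // each block's free-beta vector (Welford), global log-scale per block
  const int d = R - 1;
  std::vector<std::vector<double>> am_mean(M, std::vector<double>(d, 0.0));
  std::vector<std::vector<double>> am_scat(M, std::vector<double>(d * d, 0.0));
  long am_n = 0;
  std::vector<double> ls_joint(M, 0.0);
  std::vector<int> acc_joint(M, 0);

  std::vector<double> newP(R), pf_new_block(N), pf_new_pers(K);
  std::vector<double> zvec(d), step(d), bprop(d), Lmat(d * d);
  double ssb = 0.0;  // sum of squared free betas, kept current
  for (int m = 0; m < M; ++m)
    for (int r = 1; r < R; ++r) ssb += mod.beta[m][r] * mod.beta[m][r];
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    double sdb = std::sqrt(mod.vbeta);
    // --- free rank-order parameters, one at a time ---
    for (int m = 0; m < M; ++m) {
      for (int r = 1; r < R; ++r) {
        double cur = mod.beta[m][r];
        double prop = cur + std::exp(ls_beta[m][r]) * norm_rand();
        mod.beta[m][r] = prop;
        softmax_row(mod.beta[m], newP);
        double alpha_new = alpha_of(newP, floor_ss);
        mod.beta[m][r] = cur;
        double delta = ldnorm(prop, 0.0, sdb) - ldnorm(cur, 0.0, sdb);
        for (const auto& gk : mod.uses[m]) {
          for (int j : mod.persons_of[gk.first]) {
            double pf_new =
                R::pnorm(mod.theta[j] + alpha_new, 0, 1, 1, 0);
            pf_new_block[j] = pf_new;
            double tn = mod.term(j, gk.second, pf_new, newP);
            double to = mod.term(j, gk.second,
                                 mod.PF[j + (size_t)N * gk.second],
                                 mod.P[m]);
            delta += (tn > 0 ? std::log(tn) : R_NegInf) -
                     (to > 0 ? std::log(to) : R_NegInf);
          }
        }
        if (std::log(unif_rand()) < delta) {
          ssb += prop * prop - cur * cur;
          mod.beta[m][r] = prop;
          mod.P[m] = newP;
          mod.alpha[m] = alpha_new;
          for (const auto& gk : mod.uses[m])
            for (int j : mod.persons_of[gk.first])
              mod.PF[j + (size_t)N * gk.second] = pf_new_block[j];
          acc_beta[m][r]++;
        }
      }
    }
    // --- joint block update: adaptive-Metropolis proposal on the whole
    //     free-beta vector of each block, using its running covariance ---
    {
      ++am_n;
      for (int m = 0; m < M; ++m) {       // Welford update of mean/scatter
        for (int r = 0; r < d; ++r) {
          double delta1 = mod.beta[m][r + 1] - am_mean[m][r];
          am_mean[m][r] += delta1 / am_n;
          for (int c = 0; c <= r; ++c) {
            double delta2 = mod.beta[m][c + 1] - am_mean[m][c];
            am_scat[m][r * d + c] += delta1 * delta2;
          }
        }
      }
    }
    if (am_n > 10 * d) {
      double sc = 2.38 * 2.38 / d;
      for (int m = 0; m < M; ++m) {
        for (int r = 0; r < d; ++r)
          for (int c = 0; c <= r; ++c) {
            double v = sc * am_scat[m][r * d + c] / (am_n - 1);
            Lmat[r * d + c] = v;
            Lmat[c * d + r] = v;
          }
        for (int r = 0; r < d; ++r) Lmat[r * d + r] += 1e-8;
        if (!chol_small(Lmat, d)) continue;
        double scale = std::exp(ls_joint[m]);
        for (int r = 0; r < d; ++r) zvec[r] = norm_rand();
        double delta = 0.0;
        for (int r = 0; r < d; ++r) {
          double s = 0.0;
          for (int c = 0; c <= r; ++c) s += Lmat[r * d + c] * zvec[c];
          bprop[r] = mod.beta[m][r + 1] + scale * s;
          delta += ldnorm(bprop[r], 0.0, sdb) -
                   ldnorm(mod.beta[m][r + 1], 0.0, sdb);
        }
        std::vector<double> btmp(mod.beta[m]);
        for (int r = 0; r < d; ++r) btmp[r + 1] = bprop[r];
        softmax_row(btmp, newP);
        double alpha_new = alpha_of(newP, floor_ss);
        for (const auto& gk : mod.uses[m]) {
          for (int j : mod.persons_of[gk.first]) {
            double pf_new = R::pnorm(mod.theta[j] + alpha_new, 0, 1, 1, 0);
            pf_new_block[j] = pf_new;
            double tn = mod.term(j, gk.second, pf_new, newP);
            double to = mod.term(j, gk.second,
                                 mod.PF[j + (size_t)N * gk.second],
                                 mod.P[m]);
            delta += (tn > 0 ? std::log(tn) : R_NegInf) -
                     (to > 0 ? std::log(to) : R_NegInf);
          }
        }
        if (std::log(unif_rand()) < delta) {
          for (int r = 0; r < d; ++r) {
            double cur = mod.beta[m][r + 1];
            ssb += bprop[r] * bprop[r] - cur * cur;
            mod.beta[m][r + 1] = bprop[r];
          }
          mod.P[m] = newP;
          mod.alpha[m] = alpha_new;
          for (const auto& gk : mod.uses[m])
            for (int j : mod.persons_of[gk.first])
              mod.PF[j + (size_t)N * gk.second] = pf_new_block[j];
          acc_joint[m]++;
        }
      }
    }
    // --- faking traits ---
    double sdt = std::sqrt(mod.vtheta);
    for (int j = 0; j < N; ++j) {
      double cur = mod.theta[j];
      double prop = cur + std::exp(ls_theta[j]) * norm_rand();
      double delta = ldnorm(prop, mod.mtheta, sdt) -
                     ldnorm(cur, mod.mtheta, sdt);
      int g = mod.group[j] - 1;
      for (int k = 0; k < K; ++k) {
        int m = mod.bmap(g, k) - 1;
        double pf_new = R::pnorm(prop + mod.alpha[m], 0, 1, 1, 0);
        pf_new_pers[k] = pf_new;
        double tn = mod.term(j, k, pf_new, mod.P[m]);
        double to = mod.term(j, k, mod.PF[j + (size_t)N * k], mod.P[m]);
        delta += (tn > 0 ? std::log(tn) : R_NegInf) -
                 (to > 0 ? std::log(to) : R_NegInf);
      }
      if (std::log(unif_rand()) < delta) {
        mod.theta[j] = prop;
        for (int k = 0; k < K; ++k)
          mod.PF[j + (size_t)N * k] = pf_new_pers[k];
        acc_theta[j]++;
      }
    }
    // --- hyperparameters ---
    {  // Mtheta: conjugate normal draw
      double prec0 = 1.0 / (prior[1] * prior[1]);
      double sum_t = 0.0;
      for (int j = 0; j < N; ++j) sum_t += mod.theta[j];
      double prec = prec0 + N / mod.vtheta;
      double mean = (prec0 * prior[0] + sum_t / mod.vtheta) / prec;
      mod.mtheta = mean + norm_rand() / std::sqrt(prec);
    }
    if (!fix_vtheta) {  // conjugate inverse-gamma draw
      double ss = 0.0;
      for (int j = 0; j < N; ++j) {
        double d = mod.theta[j] - mod.mtheta;
        ss += d * d;
      }
      double shape = prior[2] + 0.5 * N, rate = prior[3] + 0.5 * ss;
      mod.vtheta = 1.0 / R::rgamma(shape, 1.0 / rate);
    }
    if (!fix_vbeta) {  // random walk on log(Vbeta), Jacobian-corrected
      int nfree = M * (R - 1);
      double cur = mod.vbeta;
      double prop = std::exp(std::log(cur) + std::exp(ls_v) * norm_rand());
      if (prop > prior[6] && prop < prior[7]) {
        double delta =
            -0.5 * nfree * std::log(prop) - ssb / (2.0 * prop) -
            (-0.5 * nfree * std::log(cur) - ssb / (2.0 * cur)) +
            tnorm_logpdf(prop, prior[4], prior[5], prior[6], prior[7]) -
            tnorm_logpdf(cur, prior[4], prior[5], prior[6], prior[7]) +
            std::log(prop) - std::log(cur);
        if (std::log(unif_rand()) < delta) { mod.vbeta = prop; acc_v++; }
      }
    }
    // --- proposal adaptation during warmup ---
    if (it < n_warmup && (it + 1) % adapt_batch == 0) {
      batch_n++;
      double inc = std::min(0.1, 1.0 / std::sqrt((double)batch_n));
      for (int m = 0; m < M; ++m)
        for (int r = 1; r < R; ++r) {
          double rate = (double)acc_beta[m][r] / adapt_batch;
          ls_beta[m][r] += (rate > target_accept) ? inc : -inc;
          acc_beta[m][r] = 0;
        }
      for (int j = 0; j < N; ++j) {
        double rate = (double)acc_theta[j] / adapt_batch;
        ls_theta[j] += (rate > target_accept) ? inc : -inc;
        acc_theta[j] = 0;
      }
      double rate_v = (double)acc_v / adapt_batch;
      ls_v += (rate_v > target_accept) ? inc : -inc;
      acc_v = 0;
      for (int m = 0; m < M; ++m) {   // joint proposals target ~0.23
        double rate_j = (double)acc_joint[m] / adapt_batch;
        ls_joint[m] += (rate_j > 0.23) ? inc : -inc;
        acc_joint[m] = 0;
      }
    }
    // --- store ---
    if (it >= n_warmup && (it - n_warmup) % thin == 0 && kept < n_keep) {
      int c = 0;
      for (int m = 0; m < M; ++m)
        for (int r = 1; r < R; ++r) draws_beta(kept, c++) = mod.beta[m][r];
      for (int j = 0; j < N; ++j) draws_theta(kept, j) = mod.theta[j];
      draws_mtheta[kept] = mod.mtheta;
      draws_vtheta[kept] = mod.vtheta;
      draws_vbeta[kept] = mod.vbeta;
      draws_lp[kept] =
          mod.loglik() + mod.log_prior(prior, fix_vtheta, fix_vbeta);
      kept++;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["beta"] = draws_beta, _["theta"] = draws_theta,
      _["mtheta"] = draws_mtheta, _["vtheta"] = draws_vtheta,
      _["vbeta"] = draws_vbeta, _["lp"] = draws_lp,
      _["n_kept"] = kept);
}
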