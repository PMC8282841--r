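#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Draw an index in [0, K) with probability weights w (sum = s).
static inline int sample_cat(const double *w, int K, double s) {
  double u = unif_rand() * s;
  double acc = 0.0;
  for (int k = 0; k < K - 1; ++k) {
    acc += w[k];
    if (u < acc) return k;
  }
  return K - 1;
}

static inline double clampp(double p) {
  const double eps = 1e-9;
  if (p < eps) return eps;
  if (p > 1.0 - eps) return 1.0 - eps;
  return p;
}

// Gibbs sampler for the dominant-marker admixture model.
//
// X: N x L band scores in {0,1}, NA for missing.
// Dominant-diploid model: each individual carries two allele copies per
// locus; the band is absent iff both copies are null, so
// P(x=0 | Q_i, P) = (sum_k Q_ik (1 - P_kl))^2. Haploid model: one copy,
// P(x=0) = sum_k Q_ik (1 - P_kl).
// Correlated frequency model: P_kl ~ Beta(p_l(1-F_k)/F_k,
// (1-p_l)(1-F_k)/F_k) with the ancestral frequencies p_l (flat prior)
// and the per-cluster F_k (Uniform(f_lower, f_upper) prior) both updated
// by random-walk Metropolis on the logit scale; independent model:
// Beta(1,1) prior, p_anc and F not updated.
// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix X, int K, int burnin, int sweeps,
                         double alpha, NumericVector p_anc,
                         bool correlated, bool diploid,
                         NumericVector F_init, double f_lower,
                         double f_upper, double f_prop_sd) {
  const int N = X.nrow(), L = X.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > N) stop("K must not exceed the number of individuals");

  std::vector<double> pa(L);
  for (int l = 0; l < L; ++l) pa[l] = clampp(p_anc[l]);

  NumericMatrix P(K, L), Q(N, K);
  std::vector<double> F(K);
  for (int k = 0; k < K; ++k)
    F[k] = F_init[k % F_init.size()];
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l)
      P(k, l) = clampp(p_anc[l] + 0.1 * (unif_rand() - 0.5));
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k)
      Q(i, k) = 1.0 / K;

  NumericMatrix Qsum(N, K), Psum(K, L);
  NumericVector Fsum(K);
  const int total = burnin + sweeps;
  NumericVector lnl_trace(sweeps);

  std::vector<double> w1(K), w0(K);
  std::vector<double> nband(K * L), nnull(K * L);
  std::vector<double> ncop(N * K);

  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(nband.begin(), nband.end(), 0.0);
    std::fill(nnull.begin(), nnull.end(), 0.0);
    std::fill(ncop.begin(), ncop.end(), 0.0);
    double lnl = 0.0;

    // (a) augment allele copies: cluster of origin + allelic state
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        const int x = X(i, l);
        if (x == NA_INTEGER) continue;
        double S1 = 0.0, S0 = 0.0;
        for (int k = 0; k < K; ++k) {
          w1[k] = Q(i, k) * P(k, l);
          w0[k] = Q(i, k) * (1.0 - P(k, l));
          S1 += w1[k];
          S0 += w0[k];
        }
        const double T = S1 + S0;  // = 1 up to rounding
        if (diploid) {
          const double p0 = (S0 / T) * (S0 / T);
          lnl += (x == 0) ? std::log(p0) : std::log(1.0 - p0);
          if (x == 0) {
            int k1 = sample_cat(w0.data(), K, S0);
            int k2 = sample_cat(w0.data(), K, S0);
            nnull[k1 * L + l] += 1.0;
            nnull[k2 * L + l] += 1.0;
            ncop[i * K + k1] += 1.0;
            ncop[i * K + k2] += 1.0;
          } else {
            // condition the two iid copies on "not both null"
            const double pbb = S1 * S1, pbn = 2.0 * S1 * S0;
            const double u = unif_rand() * (pbb + pbn);
            int k1 = sample_cat(w1.data(), K, S1);  // a band copy always
            nband[k1 * L + l] += 1.0;
            ncop[i * K + k1] += 1.0;
            int k2;
            if (u < pbb) {
              k2 = sample_cat(w1.data(), K, S1);
              nband[k2 * L + l] += 1.0;
            } else {
              k2 = sample_cat(w0.data(), K, S0);
              nnull[k2 * L + l] += 1.0;
            }
            ncop[i * K + k2] += 1.0;
          }
        } else {  // haploid: one copy, state equals the band score
          const double p0 = S0 / T;
          lnl += (x == 0) ? std::log(p0) : std::log(1.0 - p0);
          int k1 = (x == 0) ? sample_cat(w0.data(), K, S0)
                            : sample_cat(w1.data(), K, S1);
          if (x == 0) nnull[k1 * L + l] += 1.0;
          else nband[k1 * L + l] += 1.0;
          ncop[i * K + k1] += 1.0;
        }
      }
    }
    if (!R_finite(lnl))
      stop("non-finite log-likelihood at sweep %d", sweep + 1);

    // (b) frequency update from the Beta full conditional
    for (int k = 0; k < K; ++k) {
      double a0 = 1.0, b0 = 1.0, lam = 0.0;
      if (correlated) lam = (1.0 - F[k]) / F[k];
      for (int l = 0; l < L; ++l) {
        if (correlated) {
          a0 = pa[l] * lam;
          b0 = (1.0 - pa[l]) * lam;
        }
        P(k, l) = clampp(R::rbeta(a0 + nband[k * L + l],
                                  b0 + nnull[k * L + l]));
      }
    }

    // (c') random-walk Metropolis on logit(p_anc_l) under a flat prior,
    // target prod_k Beta(P_kl; p_l lam_k, (1-p_l) lam_k)
    if (correlated) {
      std::vector<double> lam(K);
      for (int k = 0; k < K; ++k) lam[k] = (1.0 - F[k]) / F[k];
      for (int l = 0; l < L; ++l) {
        const double p = pa[l];
        const double lp = std::log(p / (1.0 - p)) + norm_rand() * 0.3;
        const double pnew = clampp(1.0 / (1.0 + std::exp(-lp)));
        double lr = std::log(pnew * (1.0 - pnew)) -
                    std::log(p * (1.0 - p));
        for (int k = 0; k < K; ++k) {
          lr += R::dbeta(P(k, l), pnew * lam[k],
                         (1.0 - pnew) * lam[k], 1) -
                R::dbeta(P(k, l), p * lam[k], (1.0 - p) * lam[k], 1);
        }
        if (R_finite(lr) && std::log(unif_rand()) < lr) pa[l] = pnew;
      }
    }

    // (c) admixture update from the Dirichlet full conditional
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + ncop[i * K + k], 1.0);
        Q(i, k) = g;
        s += g;
      }
      if (s <= 0.0) s = 1.0;
      for (int k = 0; k < K; ++k) Q(i, k) /= s;
    }

    // (d) random-walk Metropolis on logit(F_k), Uniform(f_lower,f_upper)
    // prior; symmetric proposal in logit space needs the F(1-F) Jacobian
    if (correlated) {
      for (int k = 0; k < K; ++k) {
        const double f = F[k];
        const double lf = std::log(f / (1.0 - f)) +
                          norm_rand() * f_prop_sd;
        const double fnew = 1.0 / (1.0 + std::exp(-lf));
        if (fnew <= f_lower || fnew >= f_upper) continue;
        const double lam_o = (1.0 - f) / f;
        const double lam_n = (1.0 - fnew) / fnew;
        double lr = std::log(fnew * (1.0 - fnew)) -
                    std::log(f * (1.0 - f));
        for (int l = 0; l < L; ++l) {
          lr += R::dbeta(P(k, l), pa[l] * lam_n,
                         (1.0 - pa[l]) * lam_n, 1) -
                R::dbeta(P(k, l), pa[l] * lam_o,
                         (1.0 - pa[l]) * lam_o, 1);
        }
        if (R_finite(lr) && std::log(unif_rand()) < lr) F[k] = fnew;
      }
    }

    // (e) accumulate
    if (sweep >= burnin) {
      const int t = sweep - burnin;
      lnl_trace[t] = lnl;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k) {
        Fsum[k] += F[k];
        for (int l = 0; l < L; ++l) Psum(k, l) += P(k, l);
      }
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= sweeps;
  for (int k = 0; k < K; ++k) {
    Fsum[k] /= sweeps;
    for (int l = 0; l < L; ++l) Psum(k, l) /= sweeps;
  }

  return List::create(_["Q"] = Qsum, _["P"] = Psum, _["F_k"] = Fsum,
                      _["lnL"] = lnl_trace);
}
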