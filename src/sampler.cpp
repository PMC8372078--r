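// Gibbs/slice sampler for the binomial liability-threshold animal model.
//
// Model, per assay record i (one record per phenotyped animal):
//   l_i = mu + alpha_a * eta_{a(i)} + alpha_d * delta_{d(i)}
//            + alpha_m * gamma_{m(i)} + e_i,          e_i ~ N(0, Vr fixed)
//   y_i ~ Binomial(n_i, link^{-1}(l_i))
//   eta ~ N(0, A)   (additive; A = haplodiploid relationship matrix)
//   delta_k, gamma_k ~ N(0, 1)  (testing day, mother; iid)
//   alpha_* ~ N(0, alpha_v)     (parameter expansion)
// so each variance component V = alpha^2 has a scaled chi-square(1 df)
// prior. Each expansion parameter is updated by a slice move on its
// MARGINAL conditional (the corresponding Gaussian block integrated out;
// collapsed Gibbs), which avoids the funnel-shaped (alpha, eta) geometry,
// and the block is then redrawn conjugately. The animal block works in the
// eigenbasis of A (Q, lambda), making every sweep O(N^2). Latent
// liabilities get a univariate stepping-out slice update. Uses R's RNG, so
// results are reproducible from set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// lik_mode 0: y = successes ~ Bin(n, linkinv(l))
// lik_mode 1: y = flies emerged ~ Bin(n, s * (1 - linkinv(l))), i.e. the
//   day's baseline survival s thins the non-killed larvae; the
//   day-standardization lives in the likelihood instead of the data.
static inline double loglik_bin(double l, int y, int n, int link,
                                int lik_mode, double s) {
  if (n <= 0) return 0.0;
  double lp, lq;                       // log q, log(1 - q)
  if (link == 0) {            // probit
    lp = R::pnorm(l, 0.0, 1.0, 1, 1);
    lq = R::pnorm(l, 0.0, 1.0, 0, 1);
  } else {                    // logit
    lp = -std::log1p(std::exp(-l));
    lq = -std::log1p(std::exp(l));
  }
  if (lik_mode == 0) return y * lp + (n - y) * lq;
  // emerged ~ Bin(n, s (1 - q))
  double log_pe = std::log(s) + lq;              // log P(emerge)
  double pe = std::exp(log_pe);
  double log_qe = (pe < 1.0) ? std::log1p(-pe) : -700.0;
  return y * log_pe + (n - y) * log_qe;
}

// generic stepping-out + shrinkage slice sampler
template <class F>
static double slice1(double x0, F logf, double w) {
  const double f0 = logf(x0);
  const double logy = f0 - R::exp_rand();
  double L = x0 - w * R::unif_rand();
  double Rr = L + w;
  int k = 0;
  while (logf(L) > logy && k++ < 50) L -= w;
  k = 0;
  while (logf(Rr) > logy && k++ < 50) Rr += w;
  for (int it = 0; it < 100; ++it) {
    double x1 = L + R::unif_rand() * (Rr - L);
    if (logf(x1) > logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

// [[Rcpp::export(name = ".tamSampler")]]
arma::mat tam_sampler(const arma::ivec& y, const arma::ivec& ntr,
                      const arma::ivec& day, const arma::ivec& mom,
                      const arma::mat& Q, const arma::vec& lambda,
                      int n_samples, int burn_in, int thin,
                      double alpha_v, double vr, int link,
                      bool use_lik, int lik_mode,
                      const arma::vec& surv) {
  const int N = y.n_elem;
  const int nd = day.max() + 1;
  const int nm = mom.max() + 1;
  arma::vec eta(N, arma::fill::zeros);
  arma::vec delta(nd, arma::fill::zeros);
  arma::vec gam(nm, arma::fill::zeros);
  arma::vec l(N, arma::fill::zeros);
  arma::vec ndl(nd, arma::fill::zeros), nml(nm, arma::fill::zeros);
  for (int i = 0; i < N; ++i) { ndl[day[i]] += 1.0; nml[mom[i]] += 1.0; }
  double aa = 0.3, ad = 0.3, am = 0.3, mu = 0.0;
  const double sdr = std::sqrt(vr);
  const int total = burn_in + n_samples;
  const int nkeep = n_samples / thin;
  arma::mat out(nkeep, 4);
  int kept = 0;

  arma::vec r(N), w(N), rp(N), S;

  for (int it = 0; it < total; ++it) {
    // latent liabilities
    for (int i = 0; i < N; ++i) {
      double m = mu + aa * eta[i] + ad * delta[day[i]] + am * gam[mom[i]];
      if (use_lik) {
        const int yi = y[i], ni = ntr[i];
        const double si = surv[i];
        l[i] = slice1(l[i], [&](double x) {
          return loglik_bin(x, yi, ni, link, lik_mode, si) -
                 0.5 * (x - m) * (x - m) / vr;
        }, 1.0);
      } else {
        l[i] = m + sdr * R::norm_rand();
      }
    }

    // animal block: collapsed slice on alpha_a, then eta | alpha_a
    for (int i = 0; i < N; ++i)
      r[i] = l[i] - mu - ad * delta[day[i]] - am * gam[mom[i]];
    rp = Q.t() * r;
    aa = slice1(aa, [&](double a) {
      double s = 0.0;
      for (int k2 = 0; k2 < N; ++k2) {
        double v = a * a * lambda[k2] + vr;
        s += std::log(v) + rp[k2] * rp[k2] / v;
      }
      return -0.5 * s - 0.5 * a * a / alpha_v;
    }, 0.5);
    for (int k2 = 0; k2 < N; ++k2) {
      double prec = aa * aa / vr + 1.0 / lambda[k2];
      double mean = (aa / vr) * rp[k2] / prec;
      w[k2] = mean + R::norm_rand() / std::sqrt(prec);
    }
    eta = Q * w;

    // testing-day block, collapsed the same way via per-level sums
    for (int i = 0; i < N; ++i)
      r[i] = l[i] - mu - aa * eta[i] - am * gam[mom[i]];
    S.zeros(nd);
    for (int i = 0; i < N; ++i) S[day[i]] += r[i];
    ad = slice1(ad, [&](double a) {
      // level sums S_k ~ N(0, n_k (vr + a^2 n_k)); within-level contrasts
      // do not involve a
      double s = 0.0;
      for (int k2 = 0; k2 < nd; ++k2) {
        double v = vr + a * a * ndl[k2];
        s += std::log(v) - a * a * S[k2] * S[k2] / (vr * v);
      }
      return -0.5 * s - 0.5 * a * a / alpha_v;
    }, 0.5);
    for (int k2 = 0; k2 < nd; ++k2) {
      double prec = ad * ad * ndl[k2] / vr + 1.0;
      double mean = (ad / vr) * S[k2] / prec;
      delta[k2] = mean + R::norm_rand() / std::sqrt(prec);
    }

    // mother block
    for (int i = 0; i < N; ++i)
      r[i] = l[i] - mu - aa * eta[i] - ad * delta[day[i]];
    S.zeros(nm);
    for (int i = 0; i < N; ++i) S[mom[i]] += r[i];
    am = slice1(am, [&](double a) {
      double s = 0.0;
      for (int k2 = 0; k2 < nm; ++k2) {
        double v = vr + a * a * nml[k2];
        s += std::log(v) - a * a * S[k2] * S[k2] / (vr * v);
      }
      return -0.5 * s - 0.5 * a * a / alpha_v;
    }, 0.5);
    for (int k2 = 0; k2 < nm; ++k2) {
      double prec = am * am * nml[k2] / vr + 1.0;
      double mean = (am / vr) * S[k2] / prec;
      gam[k2] = mean + R::norm_rand() / std::sqrt(prec);
    }

    // intercept (flat prior)
    {
      double s = 0.0;
      for (int i = 0; i < N; ++i)
        s += l[i] - aa * eta[i] - ad * delta[day[i]] - am * gam[mom[i]];
      mu = s / N + sdr * R::norm_rand() / std::sqrt((double) N);
    }

    if (!std::isfinite(mu) || !std::isfinite(aa)) {
      stop("sampler diverged (non-finite state) at iteration %d", it + 1);
    }

    if (it >= burn_in && ((it - burn_in) % thin) == (thin - 1) &&
        kept < nkeep) {
      out(kept, 0) = mu;
      out(kept, 1) = aa * aa;
      out(kept, 2) = ad * ad;
      out(kept, 3) = am * am;
      ++kept;
    }
  }
  return out.rows(0, kept - 1);
}
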