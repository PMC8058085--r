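// Gibbs engine for the spike-and-slab Weibull (log-scale Gumbel) model.
//
// All randomness goes through R's RNG so that set.seed() fully determines a
// run.  The serial sampler is the bulk-synchronous sampler with one worker
// and synchronisation after every marker.
#include <Rcpp.h>
#include "ars.h"
using namespace Rcpp;

static const double EULER_K = 0.5772156649015328606; // = -digamma(1)
static const double EXP_CAP = 700.0;                 // overflow guard for exp()

static inline double capexp(double v, bool* warned) {
  if (v > EXP_CAP) { *warned = true; v = EXP_CAP; }
  return std::exp(v);
}

// ---- exported: one ARS draw from an R-level log-density ---------------------
// [[Rcpp::export]]
NumericVector cpp_ars_draw(Function logf, NumericVector init,
                           double lb, double ub, int n) {
  auto f = [&](double x) { return as<double>(logf(x)); };
  std::vector<double> in(init.begin(), init.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    bw::Ars a(f, in, lb, ub);
    out[i] = a.draw();
  }
  return out;
}

// ---- marker kernel ----------------------------------------------------------
// Log marginal likelihoods on the common scale of Eq-41-style normalisation:
// entry 0 is the Dirac spike, log(sqrt(pi)); entries k>=1 are
// log( sigma_hat_k * sqrt(2) * sum_r w_r g_k(sigma_hat_k sqrt(2) t_r)/T ),
// computed in log space with a max-shift.
static std::vector<double> marker_logmarg(
    double V0, double V1, double V2, double Vnm,
    double sumdx, double sj, double xbarj,
    double alpha, double sigmaG2, const NumericVector& Ck,
    const NumericVector& qx, const NumericVector& qw) {
  int L = Ck.size(), m = qx.size();
  std::vector<double> lm(L + 1);
  lm[0] = 0.5 * std::log(M_PI);
  for (int k = 0; k < L; ++k) {
    double cs2 = Ck[k] * sigmaG2;
    double sig_term = ((1.0 - 2.0 * xbarj) * V1 + 4.0 * (1.0 - xbarj) * V2 +
                       xbarj * xbarj * Vnm) / (sj * sj);
    double rad = 1.0 + alpha * alpha * cs2 * sig_term;
    if (rad <= 0) Rcpp::stop("marker kernel: negative radicand in sigma_hat");
    double sigk = 1.0 / (std::sqrt(2.0) * std::sqrt(rad));
    std::vector<double> terms(m);
    for (int r = 0; r < m; ++r) {
      double s = sigk * std::sqrt(2.0) * qx[r];
      double c = s * std::sqrt(2.0 * cs2);        // beta value at node r
      double e = alpha * c / sj;
      double A = Vnm - std::exp(xbarj * e) *
                 (V0 + std::exp(-e) * V1 + std::exp(-2.0 * e) * V2);
      // modified weights w_r e^{t_r^2}: the integrand keeps its own
      // Gaussian factor, so the Hermite weight function must be divided out
      terms[r] = std::log(qw[r]) + qx[r] * qx[r] -
                 alpha * c * sumdx + A - s * s;
    }
    lm[k + 1] = std::log(sigk * std::sqrt(2.0)) + bw::logsumexp(terms);
  }
  return lm;
}

// [[Rcpp::export]]
NumericVector cpp_marker_logmarg(double V0, double V1, double V2, double Vnm,
                                 double sumdx, double sj, double xbarj,
                                 double alpha, double sigmaG2,
                                 NumericVector Ck,
                                 NumericVector qx, NumericVector qw) {
  std::vector<double> lm = marker_logmarg(V0, V1, V2, Vnm, sumdx, sj, xbarj,
                                          alpha, sigmaG2, Ck, qx, qw);
  return NumericVector(lm.begin(), lm.end());
}

// ---- helpers ----------------------------------------------------------------
static void shuffle_R(std::vector<int>& v) { // Fisher-Yates with R's RNG
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

static double rinvgamma(double shape, double scale) {
  return scale / R::rgamma(shape, 1.0);
}

static std::vector<double> rdirichlet(const std::vector<double>& a) {
  std::vector<double> g(a.size());
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) { g[i] = R::rgamma(a[i], 1.0); s += g[i]; }
  for (size_t i = 0; i < a.size(); ++i) g[i] = (s > 0) ? g[i] / s : 1.0 / a.size();
  return g;
}

// ---- the sampler ------------------------------------------------------------
// [[Rcpp::export]]
List cpp_gibbs(NumericVector logy, IntegerVector d, NumericVector lr,
               NumericMatrix Z,
               List idx1, List idx2, List idxm,
               NumericVector xbar, NumericVector sd_, NumericVector sumdx,
               IntegerVector group, List Cks,
               List hyper, NumericVector qx, NumericVector qw,
               int n_iter, int burnin, int thin, int n_workers, int sync_rate,
               List init, List control) {
  const int N = logy.size(), M = xbar.size(), Q = Z.ncol();
  const int Phi = Cks.size();
  const double alpha0 = hyper["alpha0"], kappa0 = hyper["kappa0"];
  const double alpha_sigma = hyper["alpha_sigma"], beta_sigma = hyper["beta_sigma"];
  const double s2mu = hyper["sigma2_mu"], s2delta = hyper["sigma2_delta"];
  const double dirp = hyper["dirichlet_p"];
  const double mu_lo = control["mu_lo"], mu_hi = control["mu_hi"];
  const double alpha_lo = control["alpha_lo"], alpha_hi = control["alpha_hi"];
  const double delta_hw = control["delta_halfwidth"];
  const bool up_mu = control["update_mu"], up_alpha = control["update_alpha"];
  const bool up_delta = control["update_delta"], up_pi = control["update_pi"];
  const bool up_sigma = control["update_sigma"];
  const bool up_beta = control.containsElementNamed("update_beta") ?
                       (bool)control["update_beta"] : true;
  bool warned = false;

  // state
  double mu = init["mu"], alpha = init["alpha"];
  NumericVector sigma2G = clone(as<NumericVector>(init["sigma2G"]));
  List pi_init = init["pi"];
  std::vector<std::vector<double>> pi(Phi);
  for (int g = 0; g < Phi; ++g) {
    NumericVector p = pi_init[g];
    pi[g] = std::vector<double>(p.begin(), p.end());
  }
  std::vector<double> beta(M, 0.0), delta(Q, 0.0);
  std::vector<int> gamma(M, 0);

  double dtot = 0.0;
  for (int i = 0; i < N; ++i) dtot += d[i];
  std::vector<double> sumdz(Q, 0.0);
  for (int q = 0; q < Q; ++q)
    for (int i = 0; i < N; ++i) sumdz[q] += d[i] * Z(i, q);

  // residuals: true eps_i = eps[i] + eps_off for every i
  std::vector<double> eps(N), w(N), fcens(N);
  double eps_off = 0.0, wscale = 1.0, Vtot = 0.0;
  for (int i = 0; i < N; ++i) eps[i] = logy[i] - mu;

  auto refresh_fcens = [&]() {
    for (int i = 0; i < N; ++i)
      fcens[i] = std::isfinite(lr[i]) ? (1.0 - std::exp(alpha * lr[i])) : 1.0;
  };
  auto rebuild_w = [&]() { // fold offset, rebuild weights and total
    if (eps_off != 0.0) { for (int i = 0; i < N; ++i) eps[i] += eps_off; eps_off = 0.0; }
    wscale = 1.0; Vtot = 0.0;
    for (int i = 0; i < N; ++i) {
      w[i] = capexp(alpha * eps[i] - EULER_K, &warned) * fcens[i];
      Vtot += w[i];
    }
  };
  refresh_fcens();
  rebuild_w();

  // marker blocks: n_workers contiguous chunks
  std::vector<int> bstart(n_workers + 1);
  for (int t = 0; t <= n_workers; ++t)
    bstart[t] = (int)std::floor((double)t * M / n_workers);

  // output
  int S = (n_iter - burnin) / thin; if (S < 0) S = 0;
  NumericVector out_mu(S), out_alpha(S);
  NumericMatrix out_delta(S, std::max(Q, 1));
  NumericMatrix out_sigma(S, Phi);
  std::vector<NumericMatrix> out_pi;
  for (int g = 0; g < Phi; ++g)
    out_pi.push_back(NumericMatrix(S, ((NumericVector)Cks[g]).size() + 1));
  NumericMatrix out_beta(M, std::max(S, 1));
  IntegerMatrix out_gamma(M, std::max(S, 1));
  int srow = 0;

  std::vector<std::vector<double>> deps(n_workers, std::vector<double>(N, 0.0));
  std::vector<std::vector<int>> touched(n_workers);

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
    rebuild_w(); // fresh start-of-iteration rebuild kills accumulation drift

    // -- intercept --
    if (up_mu) {
      double W = std::exp(alpha * mu) * Vtot;
      auto lp = [&](double m_) {
        return -alpha * dtot * m_ - std::exp(-alpha * m_) * W -
               m_ * m_ / (2.0 * s2mu);
      };
      double c = 0.5;
      std::vector<double> ini = {std::max(mu - c, mu_lo + 1e-6), mu,
                                 std::min(mu + c, mu_hi - 1e-6)};
      bw::Ars a(lp, ini, mu_lo, mu_hi);
      double mu_new = a.draw();
      double dm = mu - mu_new; // eps gets + (mu_old - mu_new)
      for (int i = 0; i < N; ++i) eps[i] += dm;
      double f = std::exp(alpha * dm);
      for (int i = 0; i < N; ++i) w[i] *= f;
      Vtot *= f;
      mu = mu_new;
    }

    // -- covariates --
    if (up_delta && Q > 0) {
      std::vector<int> qord(Q);
      for (int q = 0; q < Q; ++q) qord[q] = q;
      shuffle_R(qord);
      for (int qi = 0; qi < Q; ++qi) {
        int q = qord[qi];
        std::vector<double> b(N), wb(N);
        for (int i = 0; i < N; ++i) {
          b[i] = alpha * Z(i, q);
          wb[i] = w[i] * std::exp(b[i] * delta[q]); // effect added back
        }
        auto lp = [&](double dq) {
          double s = 0.0;
          for (int i = 0; i < N; ++i) s += wb[i] * std::exp(-b[i] * dq);
          return -alpha * dq * sumdz[q] - s - dq * dq / (2.0 * s2delta);
        };
        double c = 0.5;
        std::vector<double> ini = {delta[q] - c, delta[q], delta[q] + c};
        bw::Ars a(lp, ini, -delta_hw, delta_hw);
        double dn = a.draw();
        for (int i = 0; i < N; ++i) {
          eps[i] -= Z(i, q) * (dn - delta[q]);
          w[i] = wb[i] * std::exp(-b[i] * dn);
        }
        delta[q] = dn;
        Vtot = 0.0; for (int i = 0; i < N; ++i) Vtot += w[i];
      }
    }

    // -- Weibull shape --
    if (up_alpha) {
      double sde = 0.0;
      for (int i = 0; i < N; ++i) sde += d[i] * eps[i];
      auto lp = [&](double a_) {
        double s = 0.0;
        for (int i = 0; i < N; ++i) {
          double t = capexp(a_ * eps[i] - EULER_K, &warned);
          double fc = std::isfinite(lr[i]) ? (1.0 - std::exp(a_ * lr[i])) : 1.0;
          s += t * fc;
        }
        return (alpha0 + dtot - 1.0) * std::log(a_) + a_ * (sde - kappa0) - s;
      };
      double c = 0.5;
      double a_lo = std::max(alpha_lo, 1e-8);
      std::vector<double> ini = {std::max(alpha - c, a_lo + 1e-6), alpha,
                                 std::min(alpha + c, alpha_hi - 1e-6)};
      bw::Ars a(lp, ini, a_lo, alpha_hi);
      alpha = a.draw();
      refresh_fcens();
      rebuild_w();
    }

    // -- marker loop: BSP windows over contiguous worker blocks --
    if (up_beta) {
    std::vector<std::vector<int>> perm(n_workers);
    int maxblk = 0;
    for (int t = 0; t < n_workers; ++t) {
      perm[t].resize(bstart[t + 1] - bstart[t]);
      for (size_t p = 0; p < perm[t].size(); ++p) perm[t][p] = bstart[t] + (int)p;
      shuffle_R(perm[t]);
      maxblk = std::max(maxblk, (int)perm[t].size());
    }
    int nwin = (maxblk + sync_rate - 1) / sync_rate;
    double deps_off_pending = 0.0;

    for (int win = 0; win < nwin; ++win) {
      for (int t = 0; t < n_workers; ++t) touched[t].clear();
      for (int t = 0; t < n_workers; ++t) {
        int p0 = win * sync_rate;
        int p1 = std::min(p0 + sync_rate, (int)perm[t].size());
        for (int p = p0; p < p1; ++p) {
          int j = perm[t][p];
          const IntegerVector i1 = idx1[j], i2 = idx2[j], im = idxm[j];
          double sj = sd_[j], xb = xbar[j];
          // partial sums against the window-start residual state
          double V1 = 0.0, V2 = 0.0, Vm = 0.0;
          for (int a_ = 0; a_ < i1.size(); ++a_) V1 += w[i1[a_]];
          for (int a_ = 0; a_ < i2.size(); ++a_) V2 += w[i2[a_]];
          for (int a_ = 0; a_ < im.size(); ++a_) Vm += w[im[a_]];
          V1 *= wscale; V2 *= wscale; Vm *= wscale;
          double Vall = wscale * Vtot;
          double V0 = Vall - V1 - V2 - Vm;
          double bold = beta[j];
          if (bold != 0.0) { // add own effect back (multiplicative form)
            double e = alpha * bold / sj;
            double g0 = std::exp(-xb * e);
            V0 *= g0; V1 *= g0 * std::exp(e); V2 *= g0 * std::exp(2.0 * e);
          }
          double Vnm = V0 + V1 + V2;
          int g = group[j];
          NumericVector Ck = Cks[g];
          int L = Ck.size();
          double sG2 = sigma2G[g];
          std::vector<double> lm = marker_logmarg(V0, V1, V2, Vnm, sumdx[j],
                                                  sj, xb, alpha, sG2, Ck, qx, qw);
          // categorical draw: inverse CDF on one uniform, order (spike, C asc)
          std::vector<double> lp(L + 1);
          double mx = -INFINITY;
          for (int k = 0; k <= L; ++k) {
            lp[k] = (pi[g][k] > 0 ? std::log(pi[g][k]) : -INFINITY) + lm[k];
            mx = std::max(mx, lp[k]);
          }
          double tot = 0.0;
          for (int k = 0; k <= L; ++k) { lp[k] = std::exp(lp[k] - mx); tot += lp[k]; }
          double u = unif_rand() * tot, acc = 0.0;
          int knew = 0;
          for (int k = 0; k <= L; ++k) { acc += lp[k]; if (u <= acc) { knew = k; break; } }

          double bnew = 0.0;
          if (knew > 0) {
            double cs2 = Ck[knew - 1] * sG2;
            double sdx = sumdx[j];
            auto lpb = [&](double b_) {
              double e = alpha * b_ / sj;
              double t_ = -std::exp(xb * e) *
                          (V0 + std::exp(-e) * V1 + std::exp(-2.0 * e) * V2);
              return -alpha * b_ * sdx + t_ - b_ * b_ / (2.0 * cs2);
            };
            double c = std::sqrt(cs2);
            // default limits: previous value +/- 2 sqrt(Ck sigmaG2); widened
            // geometrically while the conditional still carries mass at an
            // edge, so the interval always retains ~all of the posterior
            double lo = bold - 2.0 * c, hi = bold + 2.0 * c;
            double lmid = lpb(bold);
            for (int gr = 0; gr < 60 && lpb(hi) > lmid - 9.0; ++gr)
              hi = bold + 2.0 * (hi - bold);
            for (int gr = 0; gr < 60 && lpb(lo) > lmid - 9.0; ++gr)
              lo = bold + 2.0 * (lo - bold);
            double ic = std::min(c, 0.25 * (hi - lo));
            std::vector<double> ini = {bold - ic, bold, bold + ic};
            bw::Ars a(lpb, ini, lo, hi);
            bnew = a.draw();
          }
          gamma[j] = knew;
          beta[j] = bnew;
          double db = bnew - bold;
          if (db != 0.0) { // accumulate worker message
            double inv = db / sj;
            for (int a_ = 0; a_ < i1.size(); ++a_) deps[t][i1[a_]] -= inv;
            for (int a_ = 0; a_ < i2.size(); ++a_) deps[t][i2[a_]] -= 2.0 * inv;
            for (int a_ = 0; a_ < im.size(); ++a_) deps[t][im[a_]] -= xb * inv;
            // the +xbar*db/sj shared shift is carried as a scalar offset
            touched[t].insert(touched[t].end(), i1.begin(), i1.end());
            touched[t].insert(touched[t].end(), i2.begin(), i2.end());
            touched[t].insert(touched[t].end(), im.begin(), im.end());
            deps_off_pending += xb * inv;
          }
        }
      } // workers
      // synchronise: eps <- eps + sum_t delta_eps; refresh weights there
      if (deps_off_pending != 0.0) {
        eps_off += deps_off_pending;
        deps_off_pending = 0.0;
        wscale = std::exp(alpha * eps_off);
      }
      for (int t = 0; t < n_workers; ++t) {
        for (int i : touched[t]) {
          if (deps[t][i] != 0.0) {
            eps[i] += deps[t][i];
            deps[t][i] = 0.0;
            double wnew = capexp(alpha * eps[i] - EULER_K, &warned) * fcens[i];
            Vtot += wnew - w[i];
            w[i] = wnew;
          }
        }
      }
    } // windows
    } // up_beta

    // -- mixture proportions and group variances --
    // occupancy and scale sums per group
    std::vector<std::vector<double>> cnt(Phi);
    std::vector<double> ssq(Phi, 0.0);
    std::vector<int> min_(Phi, 0);
    for (int g = 0; g < Phi; ++g)
      cnt[g] = std::vector<double>(((NumericVector)Cks[g]).size() + 1, 0.0);
    for (int j = 0; j < M; ++j) {
      int g = group[j];
      cnt[g][gamma[j]] += 1.0;
      if (gamma[j] > 0) {
        NumericVector Ck = Cks[g];
        ssq[g] += beta[j] * beta[j] / Ck[gamma[j] - 1];
        min_[g] += 1;
      }
    }
    if (up_pi) {
      for (int g = 0; g < Phi; ++g) {
        std::vector<double> a(cnt[g].size());
        for (size_t k = 0; k < a.size(); ++k) a[k] = dirp + cnt[g][k];
        pi[g] = rdirichlet(a);
      }
    }
    if (up_sigma) {
      for (int g = 0; g < Phi; ++g)
        sigma2G[g] = rinvgamma(alpha_sigma + 0.5 * min_[g],
                               beta_sigma + 0.5 * ssq[g]);
    }

    // -- record --
    if (iter > burnin && (iter - burnin) % thin == 0 && srow < S) {
      out_mu[srow] = mu; out_alpha[srow] = alpha;
      for (int q = 0; q < Q; ++q) out_delta(srow, q) = delta[q];
      for (int g = 0; g < Phi; ++g) {
        out_sigma(srow, g) = sigma2G[g];
        for (size_t k = 0; k < pi[g].size(); ++k) out_pi[g](srow, k) = pi[g][k];
      }
      for (int j = 0; j < M; ++j) {
        out_beta(j, srow) = beta[j];
        out_gamma(j, srow) = gamma[j];
      }
      ++srow;
    }
  }

  if (warned)
    Rcpp::warning("exp() argument capped at 700 during sampling; early iterations may have overshot");

  List pis(Phi);
  for (int g = 0; g < Phi; ++g) pis[g] = out_pi[g];
  return List::create(_["mu"] = out_mu, _["alpha"] = out_alpha,
                      _["delta"] = out_delta, _["sigma2G"] = out_sigma,
                      _["pi"] = pis, _["beta"] = out_beta,
                      _["gamma"] = out_gamma, _["retained"] = srow);
}
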