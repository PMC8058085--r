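#ifndef BAYESW_ARS_H
#define BAYESW_ARS_H

#include <Rcpp.h>
#include <vector>
#include <functional>
#include <algorithm>
#include <cmath>

namespace bw {

// Derivative-free adaptive rejection sampling (Gilks 1992, derivative-free
// variant) for a log-concave target on a finite interval [lb, ub].
//
// The lower hull is the piecewise-linear interpolant (secants) of the
// log-density at the current abscissae; the upper hull on each inner interval
// is the minimum of the two neighbouring secants extended, and on the end
// intervals the single adjacent secant extended.  Proposals are drawn from
// the piecewise-exponential envelope; rejected proposals refine the envelope.
class Ars {
public:
  Ars(std::function<double(double)> logf,
      const std::vector<double>& init, double lb, double ub)
    : logf_(logf), lb_(lb), ub_(ub) {
    if (!(lb < ub)) Rcpp::stop("ars: invalid bounds");
    for (double v : init) {
      if (!std::isfinite(v)) continue;
      v = std::min(std::max(v, lb), ub);
      x_.push_back(v);
    }
    std::sort(x_.begin(), x_.end());
    x_.erase(std::unique(x_.begin(), x_.end(),
              [](double a, double b){ return std::fabs(a - b) < 1e-12; }),
             x_.end());
    // need at least 3 interior-ish points
    while (x_.size() < 3) {
      double lo = x_.empty() ? lb : x_.front();
      double hi = x_.empty() ? ub : x_.back();
      double mid = 0.5 * (lo + hi);
      double extra = (x_.size() < 2) ? lb + 0.25 * (ub - lb) : mid + 1e-6 * (ub - lb);
      x_.push_back(std::min(std::max(extra, lb), ub));
      std::sort(x_.begin(), x_.end());
      x_.erase(std::unique(x_.begin(), x_.end(),
                [](double a, double b){ return std::fabs(a - b) < 1e-12; }),
               x_.end());
    }
    h_.resize(x_.size());
    for (size_t i = 0; i < x_.size(); ++i) h_[i] = logf_(x_[i]);
  }

  // one exact draw from the normalised restriction of exp(logf) to [lb, ub]
  double draw() {
    for (int it = 0; it < 400; ++it) {
      build();
      double x = sample_envelope();
      double ux = upper_at(x);
      double lx = lower_at(x);
      double lw = std::log(unif_rand());
      if (lw <= lx - ux) return x;          // squeeze accept
      double hx = logf_(x);
      if (hx < lx - 1e-8)
        Rcpp::stop("ars: log-density is not concave (lower hull above target)");
      if (hx > ux + std::max(1e-6, 1e-9 * std::fabs(hx)))
        Rcpp::stop("ars: log-density is not concave (target above upper hull)");
      if (lw <= hx - ux) { insert(x, hx); return x; }
      insert(x, hx);
    }
    Rcpp::stop("ars: failed to accept after 400 proposals");
  }

private:
  std::function<double(double)> logf_;
  double lb_, ub_;
  std::vector<double> x_, h_;

  struct Seg { double xl, xr, a, yl; };    // y(x) = yl + a*(x - xl), x in [xl,xr]
  std::vector<Seg> segs_;

  double slope(size_t i) const {           // secant between points i, i+1
    return (h_[i + 1] - h_[i]) / (x_[i + 1] - x_[i]);
  }

  void push_seg(double xl, double xr, double a, double yl) {
    if (xr - xl > 1e-14) segs_.push_back({xl, xr, a, yl});
  }

  void build() {
    segs_.clear();
    size_t m = x_.size();
    // left tail [lb, x0]: extend first secant
    push_seg(lb_, x_[0], slope(0), h_[0] - slope(0) * (x_[0] - lb_));
    for (size_t i = 0; i + 1 < m; ++i) {
      bool has_l = (i >= 1), has_r = (i + 2 < m);
      double sl = has_l ? slope(i - 1) : 0.0;   // left secant extended right
      double sr = has_r ? slope(i + 1) : 0.0;   // right secant extended left
      double xl = x_[i], xr = x_[i + 1];
      if (has_l && has_r) {
        // intersection of  h_i + sl (x - x_i)  and  h_{i+1} + sr (x - x_{i+1})
        double den = sl - sr;
        double z;
        if (den <= 1e-14) z = 0.5 * (xl + xr);  // numerically parallel
        else z = (h_[i + 1] - h_[i] + sl * xl - sr * xr) / den;
        z = std::min(std::max(z, xl), xr);
        push_seg(xl, z, sl, h_[i]);
        push_seg(z, xr, sr, h_[i + 1] + sr * (z - xr));
      } else if (has_l) {
        push_seg(xl, xr, sl, h_[i]);
      } else { // has_r (m >= 3 guarantees one of the two)
        push_seg(xl, xr, sr, h_[i + 1] + sr * (xl - xr));
      }
    }
    // right tail [x_{m-1}, ub]: extend last secant
    push_seg(x_[m - 1], ub_, slope(m - 2), h_[m - 1]);
  }

  static double seg_logmass(const Seg& s) {
    double L = s.xr - s.xl, aL = s.a * L;
    // integral exp(yl + a t) dt on [0, L], evaluated in log space so that
    // steep segments (|a L| huge) cannot overflow
    if (std::fabs(aL) < 1e-10) return s.yl + std::log(L);
    if (s.a > 0)
      return s.yl + aL + std::log1p(-std::exp(-aL)) - std::log(s.a);
    return s.yl + std::log1p(-std::exp(aL)) - std::log(-s.a);
  }

  double sample_envelope() const {
    size_t K = segs_.size();
    std::vector<double> lm(K);
    double mx = -INFINITY;
    for (size_t k = 0; k < K; ++k) { lm[k] = seg_logmass(segs_[k]); mx = std::max(mx, lm[k]); }
    double tot = 0.0;
    for (size_t k = 0; k < K; ++k) { lm[k] = std::exp(lm[k] - mx); tot += lm[k]; }
    double u = unif_rand() * tot, acc = 0.0;
    size_t pick = K - 1;
    for (size_t k = 0; k < K; ++k) { acc += lm[k]; if (u <= acc) { pick = k; break; } }
    const Seg& s = segs_[pick];
    double L = s.xr - s.xl, v = unif_rand(), aL = s.a * L;
    if (std::fabs(aL) < 1e-10) return s.xl + v * L;
    // inverse CDF of the exponential tilt, overflow-safe at steep slopes:
    // t = log(1 + v (e^{aL} - 1)) / a
    double t;
    if (aL > 30)       t = L + std::log(v) / s.a;     // 1 + v(e^{aL}-1) ~ v e^{aL}
    else if (aL < -30) t = std::log1p(-v) / s.a;      // e^{aL} ~ 0
    else               t = std::log1p(v * std::expm1(aL)) / s.a;
    return std::min(std::max(s.xl + t, s.xl), s.xr);
  }

  double upper_at(double x) const {
    for (const Seg& s : segs_)
      if (x >= s.xl - 1e-12 && x <= s.xr + 1e-12)
        return s.yl + s.a * (x - s.xl);
    return -INFINITY; // unreachable
  }

  double lower_at(double x) const {
    if (x <= x_.front() || x >= x_.back()) return -INFINITY;
    size_t i = std::upper_bound(x_.begin(), x_.end(), x) - x_.begin() - 1;
    if (i + 1 >= x_.size()) return -INFINITY;
    return h_[i] + slope(i) * (x - x_[i]);
  }

  void insert(double x, double hx) {
    if (x_.size() >= 128) return; // envelope rich enough; keep memory bounded
    size_t i = std::lower_bound(x_.begin(), x_.end(), x) - x_.begin();
    if (i < x_.size() && std::fabs(x_[i] - x) < 1e-12) return;
    if (i > 0 && std::fabs(x_[i - 1] - x) < 1e-12) return;
    x_.insert(x_.begin() + i, x);
    h_.insert(h_.begin() + i, hx);
  }
};

inline double logsumexp(const std::vector<double>& v) {
  double mx = -INFINITY;
  for (double a : v) mx = std::max(mx, a);
  if (!std::isfinite(mx)) return mx;
  double s = 0.0;
  for (double a : v) s += std::exp(a - mx);
  return mx + std::log(s);
}

} // namespace bw

#endif
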