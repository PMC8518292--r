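#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Local extrema of x. Plateaus are handled by carrying the last non-zero
// slope sign forward, so a flat top counts once (at its left edge).
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& maxima,
                         std::vector<int>& minima) {
  maxima.clear();
  minima.clear();
  const int n = static_cast<int>(x.size());
  if (n < 3) return;
  int prev_sign = 0;
  for (int i = 0; i < n - 1; ++i) {
    double d = x[i + 1] - x[i];
    int s = (d > 0.0) - (d < 0.0);
    if (s == 0) continue;
    if (prev_sign > 0 && s < 0) maxima.push_back(i);
    if (prev_sign < 0 && s > 0) minima.push_back(i);
    prev_sign = s;
  }
}

// Natural cubic spline through (xs, ys), evaluated at 0..n-1.
// xs strictly increasing; second derivative zero at both end knots.
static std::vector<double> natural_spline_eval(const std::vector<double>& xs,
                                               const std::vector<double>& ys,
                                               int n) {
  const int m = static_cast<int>(xs.size());
  std::vector<double> out(n);
  if (m == 1) {
    std::fill(out.begin(), out.end(), ys[0]);
    return out;
  }
  if (m == 2) {
    double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int t = 0; t < n; ++t) out[t] = ys[0] + slope * (t - xs[0]);
    return out;
  }
  // Second derivatives M by the standard tridiagonal system (Thomas solve).
  std::vector<double> h(m - 1), alpha(m), l(m), mu(m), z(m), M(m);
  for (int i = 0; i < m - 1; ++i) h[i] = xs[i + 1] - xs[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 6.0 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (xs[i + 1] - xs[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  l[m - 1] = 1.0; z[m - 1] = 0.0; M[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  // Evaluate; queries are sorted (0..n-1) so walk the knot intervals once.
  int k = 0;
  for (int t = 0; t < n; ++t) {
    double xt = static_cast<double>(t);
    while (k < m - 2 && xs[k + 1] < xt) ++k;
    double hk = h[k];
    double a = (xs[k + 1] - xt) / hk;
    double b = (xt - xs[k]) / hk;
    out[t] = a * ys[k] + b * ys[k + 1] +
             ((a * a * a - a) * M[k] + (b * b * b - b) * M[k + 1]) * hk * hk / 6.0;
  }
  return out;
}

// Envelope knots with the two nearest extrema mirrored about each end.
static void mirrored_knots(const std::vector<int>& idx,
                           const std::vector<double>& x,
                           int n,
                           std::vector<double>& xs,
                           std::vector<double>& ys) {
  xs.clear(); ys.clear();
  const int m = static_cast<int>(idx.size());
  // left reflections, added in decreasing distance so xs stays increasing
  std::vector<std::pair<double, double> > left;
  for (int i = 0; i < m && static_cast<int>(left.size()) < 2; ++i)
    if (idx[i] > 0) left.push_back(std::make_pair(-static_cast<double>(idx[i]), x[idx[i]]));
  if (left.empty()) left.push_back(std::make_pair(-1.0, x[idx[0]]));
  for (int i = static_cast<int>(left.size()) - 1; i >= 0; --i) {
    xs.push_back(left[i].first);
    ys.push_back(left[i].second);
  }
  for (int i = 0; i < m; ++i) {
    xs.push_back(static_cast<double>(idx[i]));
    ys.push_back(x[idx[i]]);
  }
  int added = 0;
  for (int i = m - 1; i >= 0 && added < 2; --i) {
    if (idx[i] < n - 1) {
      xs.push_back(2.0 * (n - 1) - idx[i]);
      ys.push_back(x[idx[i]]);
      ++added;
    }
  }
  if (added == 0) {
    xs.push_back(static_cast<double>(n));
    ys.push_back(x[idx[m - 1]]);
  }
}

// true on success; false when there are not >= 2 maxima and >= 2 minima
static bool mean_envelope(const std::vector<double>& x,
                          std::vector<double>& upper,
                          std::vector<double>& lower,
                          std::vector<double>& mean) {
  const int n = static_cast<int>(x.size());
  std::vector<int> maxima, minima;
  find_extrema(x, maxima, minima);
  if (maxima.size() < 2 || minima.size() < 2) return false;
  std::vector<double> xs, ys;
  mirrored_knots(maxima, x, n, xs, ys);
  upper = natural_spline_eval(xs, ys, n);
  mirrored_knots(minima, x, n, xs, ys);
  lower = natural_spline_eval(xs, ys, n);
  mean.resize(n);
  for (int i = 0; i < n; ++i) mean[i] = 0.5 * (upper[i] + lower[i]);
  return true;
}

// [[Rcpp::export]]
List cpp_envelopes(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> upper, lower, mean;
  if (!mean_envelope(xv, upper, lower, mean))
    stop("signal has fewer than 2 maxima or 2 minima; envelopes are undefined");
  return List::create(_["upper"] = wrap(upper),
                      _["lower"] = wrap(lower),
                      _["mean"] = wrap(mean));
}

// One sifting pass: subtract the mean envelope until the Cauchy SD
// criterion sum((m_prev - m_cur)^2)/sum(m_prev^2) < sd_tol, or max_sift.
static bool sift_one(std::vector<double>& m, double sd_tol, int max_sift) {
  const int n = static_cast<int>(m.size());
  std::vector<double> upper, lower, mean;
  for (int it = 0; it < max_sift; ++it) {
    if (!mean_envelope(m, upper, lower, mean)) return it > 0;
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      num += mean[i] * mean[i]; // (m_prev - m_cur) == mean envelope
      den += m[i] * m[i];
      m[i] -= mean[i];
    }
    if (den > 0.0 && num / den < sd_tol) return true;
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_sift(NumericVector x, double sd_tol, int max_sift) {
  std::vector<double> m(x.begin(), x.end());
  std::vector<int> maxima, minima;
  find_extrema(m, maxima, minima);
  if (maxima.size() < 2 || minima.size() < 2)
    stop("signal has fewer than 2 maxima or 2 minima; cannot sift");
  sift_one(m, sd_tol, max_sift);
  return wrap(m);
}

// [[Rcpp::export]]
List cpp_emd(NumericVector x, int max_imfs, double sd_tol, int max_sift) {
  const int n = x.size();
  std::vector<double> residual(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> maxima, minima;
  while (static_cast<int>(imfs.size()) < max_imfs) {
    find_extrema(residual, maxima, minima);
    if (maxima.size() < 2 || minima.size() < 2) break;
    std::vector<double> imf(residual);
    sift_one(imf, sd_tol, max_sift);
    for (int i = 0; i < n; ++i) residual[i] -= imf[i];
    imfs.push_back(imf);
  }
  NumericMatrix out(n, static_cast<int>(imfs.size()));
  for (size_t k = 0; k < imfs.size(); ++k)
    for (int i = 0; i < n; ++i) out(i, static_cast<int>(k)) = imfs[k][i];
  return List::create(_["imfs"] = out, _["residual"] = wrap(residual));
}
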