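#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of a small scratch vector (modifies it)
static double med_of(std::vector<double>& v) {
  size_t n = v.size();
  if (n == 0) return NA_REAL;
  size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// Centered rolling median/MAD outlier rejection with edge-truncated windows.
// k = half window in samples; threshold in scaled-MAD units (scale 1.4826).
// NA samples are ignored within windows and passed through unflagged.
// [[Rcpp::export(name = ".hampel_cpp")]]
List hampel_cpp(NumericVector x, int k, double threshold) {
  const double scale = 1.4826;
  int n = x.size();
  NumericVector out = clone(x);
  LogicalVector flag(n, false);
  std::vector<double> win, dev;
  win.reserve(2 * k + 1);
  dev.reserve(2 * k + 1);
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(x[i])) continue;
    int lo = std::max(0, i - k), hi = std::min(n - 1, i + k);
    win.clear();
    for (int j = lo; j <= hi; ++j)
      if (!NumericVector::is_na(x[j])) win.push_back(x[j]);
    if (win.size() < 3) continue;
    dev = win;
    double m = med_of(dev);
    for (size_t j = 0; j < win.size(); ++j) dev[j] = std::fabs(win[j] - m);
    double s = scale * med_of(dev);
    if (std::fabs(x[i] - m) > threshold * s) {
      out[i] = m;
      flag[i] = true;
    }
  }
  return List::create(_["cleaned"] = out, _["outlier"] = flag);
}
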