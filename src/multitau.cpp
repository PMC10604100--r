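#include <Rcpp.h>
using namespace Rcpp;

// Multi-tau autocorrelator with m linearly spaced channels per octave and
// symmetric normalization: for lag tau (in bins of the current level),
//   G(tau) = <I(t) I(t+tau)> / (mean_left * mean_right) - 1
// with mean_left over t in [0, T-tau) and mean_right over t in [tau, T).
// After each octave the trace is binned by 2 and lags continue at double
// spacing, as in hardware correlators. Estimates at every level equal the
// direct correlation of the binned trace at the same lag.

static void level_corr(const std::vector<double>& x, int lag_from, int lag_to,
                       int level, double bin_scale,
                       std::vector<double>& lags, std::vector<double>& g) {
  int n = (int) x.size();
  for (int lag = lag_from; lag <= lag_to; lag++) {
    if (lag >= n) return;
    double s = 0, sl = 0, sr = 0;
    int m = n - lag;
    for (int t = 0; t < m; t++) {
      s += x[t] * x[t + lag];
      sl += x[t];
      sr += x[t + lag];
    }
    double ml = sl / m, mr = sr / m;
    if (ml <= 0 || mr <= 0) continue;
    lags.push_back(lag * bin_scale);
    g.push_back(s / m / (ml * mr) - 1.0);
  }
}

// [[Rcpp::export(name = ".cpp_multitau")]]
List cpp_multitau(NumericVector counts, double bin_width, int m, int max_level) {
  std::vector<double> x(counts.begin(), counts.end());
  std::vector<double> lags, g;
  // level 0: lags 1 .. 2m-1 at native binning
  level_corr(x, 1, 2 * m - 1, 0, bin_width, lags, g);
  double scale = bin_width;
  for (int lev = 1; lev <= max_level; lev++) {
    // bin by 2
    int n2 = (int) x.size() / 2;
    if (n2 < 2 * m) break;
    std::vector<double> y(n2);
    for (int i = 0; i < n2; i++) y[i] = 0.5 * (x[2 * i] + x[2 * i + 1]);
    x.swap(y);
    scale *= 2;
    level_corr(x, m, 2 * m - 1, lev, scale, lags, g);
  }
  return List::create(_["lag"] = wrap(lags), _["g"] = wrap(g));
}
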