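#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Classical normalized Lomb-Scargle power at the given angular frequencies.
// t: sample times, y: values (not yet centred), omega: 2*pi*f.
// Normalization: P(w) = 1/(2*s2) * [ (sum y cos)^2 / sum cos^2 +
//                                    (sum y sin)^2 / sum sin^2 ]
// with the phase constant tau per frequency and s2 the sample variance
// (denominator n-1).
// [[Rcpp::export(name = ".lombPower")]]
NumericVector lombPower(NumericVector t, NumericVector y,
                        NumericVector omega) {
  const int n = t.size();
  const int m = omega.size();
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += y[i];
  mean /= n;
  double s2 = 0.0;
  std::vector<double> yc(n);
  for (int i = 0; i < n; ++i) {
    yc[i] = y[i] - mean;
    s2 += yc[i] * yc[i];
  }
  s2 /= (n - 1);
  NumericVector p(m);
  if (s2 <= 0.0) {
    std::fill(p.begin(), p.end(), 0.0);
    return p;
  }
  for (int j = 0; j < m; ++j) {
    const double w = omega[j];
    double s2w = 0.0, c2w = 0.0;
    for (int i = 0; i < n; ++i) {
      s2w += std::sin(2.0 * w * t[i]);
      c2w += std::cos(2.0 * w * t[i]);
    }
    const double tau = std::atan2(s2w, c2w) / (2.0 * w);
    double ycsum = 0.0, yssum = 0.0, ccsum = 0.0, sssum = 0.0;
    for (int i = 0; i < n; ++i) {
      const double arg = w * (t[i] - tau);
      const double c = std::cos(arg);
      const double s = std::sin(arg);
      ycsum += yc[i] * c;
      yssum += yc[i] * s;
      ccsum += c * c;
      sssum += s * s;
    }
    double pw = 0.0;
    if (ccsum > 0.0) pw += ycsum * ycsum / ccsum;
    if (sssum > 0.0) pw += yssum * yssum / sssum;
    p[j] = pw / (2.0 * s2);
  }
  return p;
}
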