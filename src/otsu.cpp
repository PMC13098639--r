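#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive multilevel Otsu on a histogram: maximizes the between-class
// variance sum(w_c * (mu_c - mu)^2) over all ordered threshold tuples.
// Supports 1..3 thresholds; deterministic tie-break (strict improvement
// keeps the lowest tuple in lexicographic scan order).

// [[Rcpp::export]]
IntegerVector multi_otsu_cpp(NumericVector hist, int n_thresholds) {
  const int B = hist.size();
  std::vector<double> P(B + 1, 0.0), S(B + 1, 0.0);
  for (int i = 0; i < B; ++i) {
    P[i + 1] = P[i] + hist[i];
    S[i + 1] = S[i] + hist[i] * i;
  }
  const double Ptot = P[B];
  if (Ptot <= 0.0) stop("empty histogram");

  // class over bins [a, b) ; contribution w * mu^2
  auto cls = [&](int a, int b) -> double {
    double w = P[b] - P[a];
    if (w <= 0.0) return 0.0;
    double m = (S[b] - S[a]) / w;
    return w * m * m;
  };

  double best = -1.0;
  IntegerVector th(n_thresholds);
  if (n_thresholds == 1) {
    for (int t1 = 1; t1 < B; ++t1) {
      double v = cls(0, t1) + cls(t1, B);
      if (v > best) { best = v; th[0] = t1; }
    }
  } else if (n_thresholds == 2) {
    for (int t1 = 1; t1 < B - 1; ++t1)
      for (int t2 = t1 + 1; t2 < B; ++t2) {
        double v = cls(0, t1) + cls(t1, t2) + cls(t2, B);
        if (v > best) { best = v; th[0] = t1; th[1] = t2; }
      }
  } else if (n_thresholds == 3) {
    for (int t1 = 1; t1 < B - 2; ++t1) {
      double c0 = cls(0, t1);
      for (int t2 = t1 + 1; t2 < B - 1; ++t2) {
        double c1 = c0 + cls(t1, t2);
        for (int t3 = t2 + 1; t3 < B; ++t3) {
          double v = c1 + cls(t2, t3) + cls(t3, B);
          if (v > best) { best = v; th[0] = t1; th[1] = t2; th[2] = t3; }
        }
      }
    }
  } else {
    stop("n_thresholds must be 1, 2 or 3");
  }
  return th;  // bin indices: class boundary at bin th (0-based lower edge)
}
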