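#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Largest integer j >= 0 with P[X <= j | lambda] <= gamma, or -1 when even
// j = 0 exceeds the bound. qpois gives the smallest j with F(j) >= gamma;
// step down until the inequality holds in the <= direction.
static double cap_for(double gamma, double lambda) {
  if (gamma >= 1.0) return R_PosInf;
  if (lambda <= 0.0) return -1.0;
  double j = R::qpois(gamma, lambda, 1, 0);
  while (j >= 0.0 && R::ppois(j, lambda, 1, 0) > gamma) j -= 1.0;
  return j;
}

// [[Rcpp::export(name = ".robust_scan_cpp")]]
NumericVector robust_scan_cpp(NumericVector lambda_hat, int stride,
                              double gamma) {
  int n = lambda_hat.size();
  NumericVector out(n);
  std::unordered_map<double, double> memo;
  for (int i = 0; i < n; ++i) {
    double lh = lambda_hat[i];
    if (i < stride) {  // no non-overlapping predecessor window yet
      out[i] = lh;
      continue;
    }
    double pred = lambda_hat[i - stride];
    if (pred <= 0.0) {  // rule only applies for a positive predecessor
      out[i] = lh;
      continue;
    }
    double cap;
    std::unordered_map<double, double>::iterator it = memo.find(pred);
    if (it == memo.end()) {
      cap = cap_for(gamma, pred);
      memo[pred] = cap;
    } else {
      cap = it->second;
    }
    out[i] = (cap < 0.0) ? 0.0 : std::min(lh, cap);
  }
  return out;
}

// [[Rcpp::export(name = ".pois_cap_cpp")]]
double pois_cap_cpp(double gamma, double lambda) {
  return cap_for(gamma, lambda);
}
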