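#include <Rcpp.h>
using namespace Rcpp;

// Topographic prominence of candidate summits (1-based positions) on x:
// height above the higher of the two saddles separating the summit from
// the nearest higher terrain (or the array end). Candidates that cannot
// reach min_prom even against the global minimum return 0 immediately.
// [[Rcpp::export(name = ".summit_prominence_cpp")]]
NumericVector summit_prominence_cpp(NumericVector x, IntegerVector pos,
                                    double min_prom) {
  int n = x.size();
  double gmin = R_PosInf;
  for (int i = 0; i < n; ++i) if (x[i] < gmin) gmin = x[i];
  NumericVector out(pos.size());
  for (int k = 0; k < pos.size(); ++k) {
    int p = pos[k] - 1;
    double h = x[p];
    if (h - gmin < min_prom) { out[k] = 0.0; continue; }
    double minL = h, minR = h;
    for (int i = p - 1; i >= 0; --i) {
      if (x[i] > h) break;
      if (x[i] < minL) minL = x[i];
    }
    for (int i = p + 1; i < n; ++i) {
      if (x[i] > h) break;
      if (x[i] < minR) minR = x[i];
    }
    out[k] = h - (minL > minR ? minL : minR);
  }
  return out;
}
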