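#include <Rcpp.h>
using namespace Rcpp;

// Window scores of a PWM over an integer-encoded sequence.
// codes: 1..4 = A,C,G,T; anything else (N) makes the window unmatchable.
// w: L x 4 log-odds weight matrix. Returns length(codes) - L + 1 scores,
// -Inf for windows containing a non-ACGT code.
// [[Rcpp::export]]
NumericVector scan_codes(IntegerVector codes, NumericMatrix w) {
  const int n = codes.size();
  const int L = w.nrow();
  const int m = n - L + 1;
  if (m < 1) return NumericVector(0);
  NumericVector out(m);
  for (int o = 0; o < m; ++o) {
    double s = 0.0;
    bool ok = true;
    for (int i = 0; i < L; ++i) {
      const int c = codes[o + i];
      if (c < 1 || c > 4) { ok = false; break; }
      s += w(i, c - 1);
    }
    out[o] = ok ? s : R_NegInf;
  }
  return out;
}
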