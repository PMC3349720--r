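#include <Rcpp.h>
using namespace Rcpp;

// Sequential bounded jitter for pause frames, in angular units around the
// pause anchor. Each step moves in the direction sign[i] by a random
// fraction of the remaining headroom to the confinement bound, so the
// realized per-frame angular step always has the requested sign, never
// vanishes, and the offset stays strictly inside [-bound, bound].
// `reset` marks the first transition of each pause (offset restarts at 0).
// [[Rcpp::export]]
NumericVector pause_offsets_cpp(IntegerVector sign, NumericVector u,
                                LogicalVector reset, double bound) {
  int n = sign.size();
  NumericVector out(n);
  double off = 0.0;
  for (int i = 0; i < n; i++) {
    if (reset[i]) off = 0.0;
    double s = (double)sign[i];
    double headroom = bound - s * off;   // > 0 since |off| < bound
    off += s * u[i] * 0.5 * headroom;
    out[i] = off;
  }
  return out;
}
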