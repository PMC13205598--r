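#include <Rcpp.h>
using namespace Rcpp;

// Minimum mixed-type distance from each query row to any reference row.
//
// Continuous columns are pre-normalized by the real column range; the
// per-column distance is |x - y| (capped at 1), with both-missing = 0 and
// one-missing = 1. Categorical/boolean columns are integer-coded (NA = its
// own code upstream) with 0/1 mismatch. The row distance is the mean over
// columns. Used by the zero-knowledge membership-inference attacker, where
// the attacker score is the negative of this distance.

// [[Rcpp::export]]
NumericVector min_mixed_distance(NumericMatrix qc, NumericMatrix rc,
                                 IntegerMatrix qd, IntegerMatrix rd) {
  const int nq = std::max(qc.nrow(), qd.nrow());
  const int nr = std::max(rc.nrow(), rd.nrow());
  const int pc = qc.ncol();
  const int pd = qd.ncol();
  const double ncols = pc + pd;
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nr; ++j) {
      double acc = 0.0;
      for (int k = 0; k < pc; ++k) {
        double a = qc(i, k), b = rc(j, k);
        bool na_a = ISNAN(a), na_b = ISNAN(b);
        if (na_a && na_b) continue;            // both missing: distance 0
        if (na_a || na_b) { acc += 1.0; }
        else {
          double d = std::fabs(a - b);
          acc += d > 1.0 ? 1.0 : d;
        }
        if (acc >= best * ncols) break;        // cannot improve
      }
      if (acc < best * ncols) {
        for (int k = 0; k < pd; ++k) {
          if (qd(i, k) != rd(j, k)) acc += 1.0;
          if (acc >= best * ncols) break;
        }
      }
      double dist = acc / ncols;
      if (dist < best) best = dist;
      if (best == 0.0) break;
    }
    out[i] = best;
  }
  return out;
}
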