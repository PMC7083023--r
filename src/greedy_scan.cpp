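#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Greedy left-to-right submolecule grouping within pre-sorted groups.
// grp: integer group id (one per barcode x chromosome), non-decreasing;
// start/end: fragment coordinates sorted by start within each group.
// A fragment joins the open submolecule iff its gap to the submolecule's
// current right end is <= T, or its start is within Q of the submolecule's
// leftmost (anchor) start; otherwise the submolecule closes and a new one
// opens. Returns a submolecule id per fragment.
// [[Rcpp::export]]
IntegerVector greedy_submolecules(IntegerVector grp, NumericVector start,
                                  NumericVector end, double gapT, double anchorQ) {
  int n = grp.size();
  IntegerVector out(n);
  int cur = 0;
  double right = 0, anchor = 0;
  int prev_grp = INT_MIN;
  for (int i = 0; i < n; ++i) {
    if (grp[i] != prev_grp) {
      ++cur; prev_grp = grp[i]; anchor = start[i]; right = end[i];
    } else if (start[i] - right <= gapT || start[i] - anchor <= anchorQ) {
      if (end[i] > right) right = end[i];
    } else {
      ++cur; anchor = start[i]; right = end[i];
    }
    out[i] = cur;
  }
  return out;
}
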