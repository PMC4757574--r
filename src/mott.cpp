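#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Modified-Mott quality trimming.
//
// Per-base score s(i) = limit - 10^(-Q_i/10); the retained subread is the
// contiguous segment maximizing the score sum (empty when every segment sum
// is <= 0).  Ties are broken toward the earliest end, then the earliest
// start (the earliest minimal prefix gives the longest segment for a fixed
// end).  Qualities arrive Phred+33 encoded.
//
// Returns an n x 2 integer matrix of 1-based inclusive [start, end] bounds;
// start = 0 and end = -1 flag an empty (fully trimmed) read.

// [[Rcpp::export(name = ".mott_bounds")]]
IntegerMatrix mott_bounds(CharacterVector quality, double limit) {
  const int n = quality.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(quality, i);
    const char *q = CHAR(s);
    const int L = LENGTH(s);
    double best = 0.0, prefix = 0.0, min_prefix = 0.0;
    int best_start = 0, best_end = -1, min_idx = 0;
    for (int j = 0; j < L; ++j) {
      const int Q = static_cast<int>(q[j]) - 33;
      prefix += limit - std::pow(10.0, -Q / 10.0);
      const double cand = prefix - min_prefix;
      if (cand > best) {
        best = cand;
        best_start = min_idx;
        best_end = j;
      }
      if (prefix < min_prefix) {
        min_prefix = prefix;
        min_idx = j + 1;
      }
    }
    if (best_end < 0) {
      out(i, 0) = 0;
      out(i, 1) = -1;
    } else {
      out(i, 0) = best_start + 1;
      out(i, 1) = best_end + 1;
    }
  }
  return out;
}
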