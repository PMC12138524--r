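#include <Rcpp.h>
using namespace Rcpp;

// Minimum stack-energy over all ungapped antiparallel offsets and maximal
// complementary runs of >= min_run Watson-Crick pairs. `a` is the first
// sequence as integers 1..4 (A,C,G,U); `rc` is the reverse complement of
// the second, same encoding; `stack` is the 16-entry nearest-neighbor
// table indexed by (x-1)*4 + (y-1) for the top-strand dinucleotide 5'-xy-3'.
// [[Rcpp::export]]
double duplex_energy_kernel(IntegerVector a, IntegerVector rc,
                            NumericVector stack, int min_run) {
  int na = a.size(), nb = rc.size();
  double best = 0.0;
  for (int k = 1 - nb; k <= na - 1; ++k) {
    int i1 = std::max(0, k), i2 = std::min(na, nb + k);
    if (i2 - i1 < min_run) continue;
    int runlen = 0;
    double rune = 0.0;
    for (int i = i1; i < i2; ++i) {
      bool m = a[i] == rc[i - k];
      if (m) {
        if (runlen >= 1) rune += stack[(a[i - 1] - 1) * 4 + (a[i] - 1)];
        ++runlen;
      }
      if (!m || i == i2 - 1) {
        if (runlen >= min_run && rune < best) best = rune;
        runlen = 0;
        rune = 0.0;
      }
    }
  }
  return best;
}
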