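#include <Rcpp.h>
using namespace Rcpp;

// Pair-count table over dinucleotide codes.
//
// codes[i] is the dinucleotide code (1..16) starting at position i, or 0 where
// either base is ambiguous.  Returns a 256 x max_spacing matrix whose entry
// [a + 16*(b-1), d] counts ordered pairs of positions (i, i+d) with
// codes[i] == a and codes[i+d] == b.  Any degenerate pattern's spacing
// histogram is a weighted sum over the 256 rows, so the table is computed once
// per sequence and reused across all patterns and motif sets.
// [[Rcpp::export]]
IntegerMatrix dinuc_pair_counts(IntegerVector codes, int max_spacing) {
  const int n = codes.size();
  IntegerMatrix out(256, max_spacing);
  const int* c = codes.begin();
  for (int d = 1; d <= max_spacing; ++d) {
    int* col = out.begin() + (R_xlen_t)(d - 1) * 256;
    const int lim = n - d;
    for (int i = 0; i < lim; ++i) {
      const int a = c[i], b = c[i + d];
      if (a > 0 && b > 0) col[(a - 1) + 16 * (b - 1)] += 1;
    }
  }
  return out;
}

// All ordered pairs (i < j) of sorted positions with pos[j] - pos[i] <=
// max_spacing, in discovery order (i ascending, then j ascending).  Returns
// the start-to-start distances; this ordering defines the round-robin subset
// assignment used for bootstrapping.
// [[Rcpp::export]]
IntegerVector pair_spacings(IntegerVector pos, int max_spacing) {
  const int n = pos.size();
  std::vector<int> d;
  for (int i = 0; i < n; ++i) {
    const int pi = pos[i];
    for (int j = i + 1; j < n && pos[j] - pi <= max_spacing; ++j)
      d.push_back(pos[j] - pi);
  }
  return wrap(d);
}

// Sequential emission from an order-3 Markov chain with per-base context
// classes (codon position 1/2/3 or intergenic).
//
// cum:  (n_class * 64) x 4 cumulative transition probabilities; row index is
//       class*64 + 16*b1 + 4*b2 + b3 with bases coded 0..3 (A,C,G,T) and
//       (b1,b2,b3) the three preceding bases.
// cls:  0-based context class per emitted base.
// u:    uniform(0,1) draws, one per emitted base (R's RNG, for
//       reproducibility under set.seed()).
// init: the three seed bases (codes 0..3).
// [[Rcpp::export]]
IntegerVector emit_markov(int n, IntegerVector init, NumericMatrix cum,
                          IntegerVector cls, NumericVector u) {
  IntegerVector out(n);
  int b1 = init[0], b2 = init[1], b3 = init[2];
  for (int i = 0; i < n; ++i) {
    const int row = cls[i] * 64 + 16 * b1 + 4 * b2 + b3;
    const double uu = u[i];
    int b = 0;
    while (b < 3 && uu > cum(row, b)) ++b;
    out[i] = b;
    b1 = b2; b2 = b3; b3 = b;
  }
  return out;
}
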