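#include <Rcpp.h>
using namespace Rcpp;

// Gotoh local alignment (affine gaps). Sequences arrive as 1-based indices
// into the substitution matrix; a gap of length L costs open + L * extend,
// matching the BLAST convention for (gapopen, gapextend).
// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(IntegerVector a, IntegerVector b,
                    NumericMatrix subst, double gap_open,
                    double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  const double NEG = -1e18;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;      // H[i-1][j-1]
    double F = NEG;         // gap in b (vertical), along row i
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - gap_extend, H[j] - gap_open - gap_extend);
      F = std::max(F - gap_extend, H[j - 1] - gap_open - gap_extend);
      double h = diag + subst(a[i - 1] - 1, b[j - 1] - 1);
      h = std::max(h, std::max(E[j], F));
      h = std::max(h, 0.0);
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}
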