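#include <Rcpp.h>
using namespace Rcpp;

// Template match counts for Sample Entropy, Richman-Moorman convention.
//
// For each m in 1..m_max, counts unordered template pairs (i < j) with
// i, j in {0, ..., N - m - 1} (the common index range that makes the
// A^{m+1}/B^m ratio a conditional probability):
//   B[m]: all m components within r (Chebyshev distance <= r)
//   A[m]: all m + 1 components within r
// Self-matches are excluded by construction (i < j). One O(N^2) pass
// computes the maximal prefix-match length per pair and feeds every m.
//
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m_max, double r) {
  const int n = x.size();
  if (m_max < 1) stop("m_max must be >= 1");
  if (r <= 0) stop("r must be > 0");
  std::vector<double> A(m_max + 1, 0.0), B(m_max + 1, 0.0);

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n - 1; ++j) {
      // maximal prefix length p: |x[i+k] - x[j+k]| <= r for all k < p
      int p = 0;
      const int p_cap = std::min(m_max + 1, n - j);
      while (p < p_cap && std::abs(x[i + p] - x[j + p]) <= r) ++p;
      if (p == 0) continue;
      // pair (i, j) is in range for template length m iff j <= n - m - 1
      const int m_hi = std::min({p, m_max, n - 1 - j});
      for (int m = 1; m <= m_hi; ++m) {
        B[m] += 1.0;
        if (p >= m + 1) A[m] += 1.0;
      }
    }
  }

  NumericVector a_out(m_max), b_out(m_max);
  for (int m = 1; m <= m_max; ++m) {
    a_out[m - 1] = A[m];
    b_out[m - 1] = B[m];
  }
  return List::create(_["m"] = seq_len(m_max), _["A"] = a_out, _["B"] = b_out);
}
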