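#include <Rcpp.h>
using namespace Rcpp;

// Pairwise global alignment (Needleman-Wunsch, linear gap penalty).
// GBS tags share an anchored 5' start (the cut-site remnant) but differ in
// length at the 3' end, so trailing gaps in either sequence can be left
// unpenalised (free_end = true). Traceback ties are resolved
// deterministically: diagonal, then gap in b (consume a), then gap in a.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 2.0, double mismatch = -1.0,
                  double gap = -3.0, bool free_end = true) {
  const int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) H(i, 0) = H(i - 1, 0) + gap;
  for (int j = 1; j <= m; ++j) H(0, j) = H(0, j - 1) + gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up = H(i - 1, j) + gap;     // gap in b
      double left = H(i, j - 1) + gap;   // gap in a
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      H(i, j) = best;
    }
  }
  // terminal cell: full corner, or best cell on the last row/column when
  // trailing gaps are free
  int ti = n, tj = m;
  double score = H(n, m);
  if (free_end) {
    for (int i = 0; i <= n; ++i)
      if (H(i, m) > score) { score = H(i, m); ti = i; tj = m; }
    for (int j = 0; j <= m; ++j)
      if (H(n, j) > score) { score = H(n, j); ti = n; tj = j; }
  }
  std::string ra, rb;
  // trailing free gaps
  for (int i = n; i > ti; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > tj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  int i = ti, j = tj;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        H(i, j) == H(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch)) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && H(i, j) == H(i - 1, j) + gap) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score,
                      _["a"] = ra, _["b"] = rb);
}

// Hamming distance between equal-length strings (helper for the
// cut-site-anchored tag placement used by the synthetic-data aligner).
// [[Rcpp::export]]
IntegerVector hamming_cpp(CharacterVector a, CharacterVector b) {
  const int n = a.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string x = as<std::string>(a[k]), y = as<std::string>(b[k]);
    int L = std::min(x.size(), y.size());
    int d = std::abs((int)x.size() - (int)y.size());
    for (int i = 0; i < L; ++i) if (x[i] != y[i]) ++d;
    out[k] = d;
  }
  return out;
}
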