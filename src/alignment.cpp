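#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty. Returns the
// best-scoring local alignment with 1-based inclusive end coordinates on
// both sequences, the aligned column count, identical-column count and
// gap-column count. Scores are doubles so fractional gap penalties work.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b, double match = 1.0,
              double mismatch = -2.0, double gap = -2.5) {
  int n = a.size(), m = b.size();
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0); // 1 diag 2 up 3 left
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sub = H[(i - 1) * (m + 1) + j - 1] +
                   (a[i - 1] == b[j - 1] ? match : mismatch);
      double up = H[(i - 1) * (m + 1) + j] + gap;
      double left = H[i * (m + 1) + j - 1] + gap;
      double v = 0.0;
      unsigned char t = 0;
      if (sub > v) { v = sub; t = 1; }
      if (up > v) { v = up; t = 2; }
      if (left > v) { v = left; t = 3; }
      H[i * (m + 1) + j] = v;
      tb[i * (m + 1) + j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, cols = 0, ident = 0, gaps = 0;
  while (i > 0 && j > 0 && tb[i * (m + 1) + j] != 0) {
    unsigned char t = tb[i * (m + 1) + j];
    ++cols;
    if (t == 1) {
      if (a[i - 1] == b[j - 1]) ++ident;
      --i; --j;
    } else if (t == 2) { ++gaps; --i; }
    else { ++gaps; --j; }
  }
  return List::create(
    _["score"] = best,
    _["a_start"] = best > 0 ? i + 1 : NA_INTEGER,
    _["a_end"] = best > 0 ? bi : NA_INTEGER,
    _["b_start"] = best > 0 ? j + 1 : NA_INTEGER,
    _["b_end"] = best > 0 ? bj : NA_INTEGER,
    _["align_length"] = cols,
    _["n_ident"] = ident,
    _["n_gaps"] = gaps);
}

static inline bool can_pair(char x, char y) {
  // Watson-Crick plus G:U wobble, DNA alphabet
  return (x == 'A' && y == 'T') || (x == 'T' && y == 'A') ||
         (x == 'G' && y == 'C') || (x == 'C' && y == 'G') ||
         (x == 'G' && y == 'T') || (x == 'T' && y == 'G');
}

// Nussinov base-pair maximization with a minimum hairpin loop length
// (default 3 unpaired nt between the two bases of a pair). Returns the
// maximum number of nested base pairs.
// [[Rcpp::export(name = ".nussinov_pairs")]]
int nussinov_pairs(std::string s, int min_loop = 3) {
  int n = s.size();
  if (n < 2) return 0;
  std::vector<int> M(n * n, 0);
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[(i + 1) * n + j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(s[i], s[k])) continue;
        int left = (k - i - 1 >= 1) ? M[(i + 1) * n + k - 1] : 0;
        int right = (k < j) ? M[(k + 1) * n + j] : 0;
        int v = 1 + left + right;
        if (v > best) best = v;
      }
      M[i * n + j] = best;
    }
  }
  return M[0 * n + n - 1];
}
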