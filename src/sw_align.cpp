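#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment score with +1 match, -1 mismatch and a
// linear gap penalty of 2 per gap symbol.  The DP matrix H has an extra
// zero-initialised first row and column; every cell is floored at zero so
// alignments can restart anywhere.  Returns the maximum over H.
static int sw_score_one(const std::string &a, const std::string &b,
                        int match, int mismatch, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int up = prev[j] - gap;
      int left = cur[j - 1] - gap;
      int v = sub;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0) v = 0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

//' @noRd
// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(std::string a, std::string b,
                 int match = 1, int mismatch = -1, int gap = 2) {
  if (a.empty() || b.empty())
    stop("sequences must be non-empty");
  return sw_score_one(a, b, match, mismatch, gap);
}

// All-pairs Smith-Waterman scores for a vector of sequences (upper triangle
// computed once, mirrored).  Self-scores fill the diagonal.
//' @noRd
// [[Rcpp::export(name = ".sw_score_matrix_cpp")]]
IntegerMatrix sw_score_matrix_cpp(CharacterVector seqs,
                                  int match = 1, int mismatch = -1,
                                  int gap = 2) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    if (s[i].empty()) stop("sequences must be non-empty");
  }
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      int v = sw_score_one(s[i], s[j], match, mismatch, gap);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
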