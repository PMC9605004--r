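#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh three-state DP).
// Sequences arrive as 1-based integer codes into the substitution matrix S.
// A length-1 gap costs gap_open + gap_extend, matching the BLAST convention.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
int sw_score_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                 int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);  // E: gap in b (vertical)
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;
    int diag = 0;   // H[i-1][j-1]
    int F = NEG;    // gap in a (horizontal), rolls along the row
    for (int j = 1; j <= m; ++j) {
      const int up = H[j];  // H[i-1][j], not yet overwritten
      E[j] = std::max(up - gap_open - gap_extend, E[j] - gap_extend);
      F = std::max(H[j - 1] - gap_open - gap_extend, F - gap_extend);
      int h = diag + S(ai, b[j - 1] - 1);
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = up;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full DP with kept matrices and traceback; returns score, spans and the
// aligned residue-index paths (0 = gap).
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                  int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int w = m + 1;
  std::vector<int> H((n + 1) * w, 0), E((n + 1) * w, NEG), F((n + 1) * w, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int id = i * w + j;
      E[id] = std::max(H[id - 1] - gap_open - gap_extend, E[id - 1] - gap_extend);
      F[id] = std::max(H[id - w] - gap_open - gap_extend, F[id - w] - gap_extend);
      int h = H[id - w - 1] + S(ai, b[j - 1] - 1);
      if (E[id] > h) h = E[id];
      if (F[id] > h) h = F[id];
      if (h < 0) h = 0;
      H[id] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> pa, pb;
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    const int id = i * w + j;
    if (state == 'H') {
      if (H[id] == 0) break;
      if (H[id] == E[id]) { state = 'E'; continue; }
      if (H[id] == F[id]) { state = 'F'; continue; }
      pa.push_back(a[i - 1]); pb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 'E') {           // gap in a, consumes b[j]
      pa.push_back(0); pb.push_back(b[j - 1]);
      if (E[id] == H[id - 1] - gap_open - gap_extend) state = 'H';
      --j;
    } else {                             // gap in b, consumes a[i]
      pa.push_back(a[i - 1]); pb.push_back(0);
      if (F[id] == H[id - w] - gap_open - gap_extend) state = 'H';
      --i;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = best,
                      _["a_start"] = (best > 0) ? i + 1 : NA_INTEGER,
                      _["a_end"] = (best > 0) ? bi : NA_INTEGER,
                      _["b_start"] = (best > 0) ? j + 1 : NA_INTEGER,
                      _["b_end"] = (best > 0) ? bj : NA_INTEGER,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}
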