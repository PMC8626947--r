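#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Overlap (free-end-gap) alignment with linear gap costs and full traceback.
// Scoring: match +1, mismatch -1, gap -2; terminal gaps on either sequence
// are free.  Returns the statistics of the non-terminal-gap region of the
// optimal path: matched columns, total columns, and the number of bases of
// each sequence consumed inside that region.
// [[Rcpp::export(name = ".align_overlap")]]
List align_overlap(std::string a, std::string b,
                   int match = 1, int mismatch = -1, int gap = -2) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  if (n == 0 || m == 0) stop("align_overlap: empty sequence");
  if ((double) (n + 1) * (double) (m + 1) > 4e8)
    stop("align_overlap: sequences too long for full DP");

  // DP matrices: scores for the current/previous row, full traceback.
  // Moves: 0 = stop (free-gap boundary), 1 = diagonal, 2 = up (gap in b),
  // 3 = left (gap in a).
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);  // free leading gaps
  std::vector<uint8_t> tb((size_t) (n + 1) * (m + 1), 0);
  const char *pa = a.data(), *pb = b.data();

  int best = 0; int bi = 0, bj = 0;  // end anywhere on last row/column

  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    const char ca = pa[i - 1];
    uint8_t *tbrow = &tb[(size_t) i * (m + 1)];
    const int *pv = prev.data();
    int *cv = cur.data();
    for (int j = 1; j <= m; ++j) {
      int s = pv[j - 1] + (ca == pb[j - 1] ? match : mismatch);
      uint8_t mv = 1;
      const int sup = pv[j] + gap;
      if (sup > s) { s = sup; mv = 2; }
      const int sleft = cv[j - 1] + gap;
      if (sleft > s) { s = sleft; mv = 3; }
      cv[j] = s;
      tbrow[j] = mv;
    }
    if (cur[m] >= best) { best = cur[m]; bi = i; bj = m; }
    std::swap(prev, cur);
  }
  // prev now holds row n
  for (int j = 1; j <= m; ++j)
    if (prev[j] >= best) { best = prev[j]; bi = n; bj = j; }

  // Traceback from (bi, bj) until a free-gap boundary (row 0 or column 0).
  int i = bi, j = bj;
  int matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    uint8_t mv = tb[(size_t) i * (m + 1) + j];
    if (mv == 1) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (mv == 2) {
      --i;
    } else {
      --j;
    }
    ++cols;
  }
  return List::create(
    _["score"] = best,
    _["matches"] = matches,
    _["columns"] = cols,
    _["a_aligned"] = bi - i,
    _["b_aligned"] = bj - j,
    _["a_start"] = i,     // 0-based start of aligned region on a
    _["b_start"] = j);
}

// Per-base depth from half-open intervals, for cross-checking interval
// arithmetic done elsewhere; kept tiny on purpose.
// [[Rcpp::export(name = ".depth_from_intervals")]]
IntegerVector depth_from_intervals(IntegerVector start, IntegerVector end,
                                   int len) {
  if (len < 0) stop("negative length");
  IntegerVector d(len);
  for (int k = 0; k < start.size(); ++k) {
    int s = start[k], e = end[k];
    if (s < 0 || e > len || s >= e)
      stop("alignment interval outside contig bounds");
    for (int i = s; i < e; ++i) d[i] += 1;
  }
  return d;
}
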