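#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Needleman-Wunsch global alignment with affine gap penalties.
//
// Scoring: substitution scores from `sub` (square matrix); a gap run of
// length L scores gap_open + (L - 1) * gap_extend (both arguments are
// negative scores, not positive costs). End gaps are penalized (true global
// alignment).
//
// Tie-breaking during traceback is deterministic: match/mismatch is
// preferred over a gap in `a`, which is preferred over a gap in `b`.
//
// States: 0 = M (a[i] aligned to b[j]); 1 = GA (gap in a, consumes b[j]);
// 2 = GB (gap in b, consumes a[i]).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend, bool score_only) {
  const int n = a.size();
  const int m = b.size();
  // Score layers, (n+1) x (m+1), row-major index i * (m+1) + j.
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> GA((n + 1) * (m + 1), NEG_INF);
  std::vector<double> GB((n + 1) * (m + 1), NEG_INF);
  const int W = m + 1;

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j)
    GA[j] = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i)
    GB[i * W] = gap_open + (i - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;  // 1-based codes from R
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1] - 1;
      const double s = sub(ai, bj);
      const int d = (i - 1) * W + (j - 1);
      double best = M[d];
      if (GA[d] > best) best = GA[d];
      if (GB[d] > best) best = GB[d];
      M[i * W + j] = best + s;

      // GA: gap in a at column consuming b[j]
      const int up = i * W + (j - 1);
      double ga = M[up] + gap_open;
      if (GA[up] + gap_extend > ga) ga = GA[up] + gap_extend;
      if (GB[up] + gap_open > ga) ga = GB[up] + gap_open;
      GA[i * W + j] = ga;

      // GB: gap in b at column consuming a[i]
      const int le = (i - 1) * W + j;
      double gb = M[le] + gap_open;
      if (GA[le] + gap_open > gb) gb = GA[le] + gap_open;
      if (GB[le] + gap_extend > gb) gb = GB[le] + gap_extend;
      GB[i * W + j] = gb;
    }
  }

  const int endi = n * W + m;
  double score = M[endi];
  int state = 0;
  if (GA[endi] > score) { score = GA[endi]; state = 1; }
  if (GB[endi] > score) { score = GB[endi]; state = 2; }

  if (score_only) {
    return List::create(_["score"] = score);
  }

  // Traceback; record states in reverse order.
  std::vector<int> path;
  path.reserve(n + m);
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) state = 1;
    else if (j == 0) state = 2;
    path.push_back(state);
    if (state == 0) {
      const double v = M[i * W + j];
      const double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      const int d = (i - 1) * W + (j - 1);
      if (std::abs(M[d] + s - v) < eps) state = 0;
      else if (std::abs(GA[d] + s - v) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      const double v = GA[i * W + j];
      const int up = i * W + (j - 1);
      if (std::abs(M[up] + gap_open - v) < eps) state = 0;
      else if (std::abs(GA[up] + gap_extend - v) < eps) state = 1;
      else state = 2;
      --j;
    } else {
      const double v = GB[i * W + j];
      const int le = (i - 1) * W + j;
      if (std::abs(M[le] + gap_open - v) < eps) state = 0;
      else if (std::abs(GA[le] + gap_open - v) < eps) state = 1;
      else state = 2;
      --i;
    }
  }

  const int L = path.size();
  IntegerVector states(L);
  for (int k = 0; k < L; ++k) states[k] = path[L - 1 - k];
  return List::create(_["score"] = score, _["states"] = states);
}
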