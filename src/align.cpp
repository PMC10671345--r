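#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh three-state affine-gap alignment over integer-coded residues.
//
// Cost model: a gap run of length L costs open + extend * L (the first gapped
// column is charged open + extend). States: M = residue/residue column,
// X = query residue over a gap (gap in subject), Y = gap in query.
//
// Ties are resolved lexicographically on (score, alignment length): among
// co-optimal paths the longer alignment is kept; traceback preference at
// remaining ties is M > X > Y. For local alignment the end cell is the
// highest-scoring M cell, ties by longer length, then smaller query end,
// then smaller subject end.
//
// min_diag (only meaningful for self-comparison): cells with j - i < min_diag
// are forbidden, which masks the trivial main diagonal when a protein is
// aligned against itself for tandem-repeat discovery.

static const double NEG = -1e30;

struct Cell { double s; int len; };

static inline bool better(double s1, int l1, double s2, int l2) {
  // is (s1,l1) strictly better than (s2,l2)?
  if (s1 > s2 + 1e-9) return true;
  if (s1 < s2 - 1e-9) return false;
  return l1 > l2;
}

// [[Rcpp::export(name = ".cpp_pair_align")]]
List cpp_pair_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend,
                    bool local, int min_diag = NA_INTEGER) {
  const int m = a.size(), n = b.size();
  const bool mask = (min_diag != NA_INTEGER);
  const double ge = gap_extend, gi = gap_open + gap_extend; // gap init cost

  std::vector<double> M((m + 1) * (n + 1), NEG), X(M), Y(M);
  std::vector<int> LM((m + 1) * (n + 1), 0), LX(LM), LY(LM);
  // predecessor codes: 0 none/start, 1 M, 2 X, 3 Y
  std::vector<unsigned char> PM(M.size(), 0), PX(M.size(), 0), PY(M.size(), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  M[at(0, 0)] = 0.0;
  if (!local) {
    for (int i = 1; i <= m; ++i) { X[at(i, 0)] = -(gap_open + ge * i); LX[at(i, 0)] = i; PX[at(i, 0)] = (i == 1) ? 1 : 2; }
    for (int j = 1; j <= n; ++j) { Y[at(0, j)] = -(gap_open + ge * j); LY[at(0, j)] = j; PY[at(0, j)] = (j == 1) ? 1 : 3; }
  } else {
    for (int i = 0; i <= m; ++i) M[at(i, 0)] = 0.0;
    for (int j = 0; j <= n; ++j) M[at(0, j)] = 0.0;
  }

  double best = local ? 0.0 : NEG;
  int bestLen = -1, bi = -1, bj = -1;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int c = at(i, j), d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1);
      if (mask && (j - i) < min_diag) continue; // forbidden cell stays NEG

      // M state (for local alignment a fresh start is the baseline, so at
      // equal score-and-length the shorter restart path wins at the borders)
      double s = sub(a[i - 1], b[j - 1]);
      double ms; int ml; unsigned char mp;
      if (local) { ms = 0.0; ml = 0; mp = 0; } else { ms = NEG; ml = 0; mp = 0; }
      if (better(M[d], LM[d], ms, ml)) { ms = M[d]; ml = LM[d]; mp = 1; }
      if (better(X[d], LX[d], ms, ml)) { ms = X[d]; ml = LX[d]; mp = 2; }
      if (better(Y[d], LY[d], ms, ml)) { ms = Y[d]; ml = LY[d]; mp = 3; }
      if (ms > NEG / 2) { M[c] = ms + s; LM[c] = ml + 1; PM[c] = mp; }

      // X state: consume query (gap in subject)
      double xs = M[u] - gi; int xl = LM[u]; unsigned char xp = 1;
      if (better(X[u] - ge, LX[u], xs, xl)) { xs = X[u] - ge; xl = LX[u]; xp = 2; }
      if (better(Y[u] - gi, LY[u], xs, xl)) { xs = Y[u] - gi; xl = LY[u]; xp = 3; }
      if (xs > NEG / 2) { X[c] = xs; LX[c] = xl + 1; PX[c] = xp; }

      // Y state: consume subject (gap in query)
      double ys = M[l] - gi; int yl = LM[l]; unsigned char yp = 1;
      if (better(X[l] - gi, LX[l], ys, yl)) { ys = X[l] - gi; yl = LX[l]; yp = 2; }
      if (better(Y[l] - ge, LY[l], ys, yl)) { ys = Y[l] - ge; yl = LY[l]; yp = 3; }
      if (ys > NEG / 2) { Y[c] = ys; LY[c] = yl + 1; PY[c] = yp; }

      if (local && M[c] > NEG / 2) {
        if (better(M[c], LM[c], best, bestLen)) { best = M[c]; bestLen = LM[c]; bi = i; bj = j; }
      }
    }
  }

  int state = 1; // 1 M, 2 X, 3 Y
  if (!local) {
    const int c = at(m, n);
    best = M[c]; bestLen = LM[c]; state = 1;
    if (better(X[c], LX[c], best, bestLen)) { best = X[c]; bestLen = LX[c]; state = 2; }
    if (better(Y[c], LY[c], best, bestLen)) { best = Y[c]; bestLen = LY[c]; state = 3; }
    bi = m; bj = n;
  } else if (bi < 0) {
    // no positive-scoring pair anywhere
    return List::create(_["score"] = 0.0, _["qidx"] = IntegerVector(0),
                        _["sidx"] = IntegerVector(0));
  }

  // traceback
  std::vector<int> qi, si;
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    unsigned char p;
    if (state == 1) {
      p = PM[at(i, j)];
      if (local && p == 0 && LM[at(i, j)] == 0) break;
      qi.push_back(i); si.push_back(j); --i; --j;
      if (local && p == 0) break;
    } else if (state == 2) {
      p = PX[at(i, j)];
      qi.push_back(i); si.push_back(0); --i;
    } else {
      p = PY[at(i, j)];
      qi.push_back(0); si.push_back(j); --j;
    }
    if (p == 0) break;
    state = p;
    if (!local && i == 0 && j == 0) break;
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(si.begin(), si.end());

  return List::create(_["score"] = best,
                      _["qidx"] = IntegerVector(qi.begin(), qi.end()),
                      _["sidx"] = IntegerVector(si.begin(), si.end()));
}
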