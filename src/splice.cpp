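#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Spliced local alignment of a CDS against a genomic region (est2genome
// style). Three ordinary column classes (match/mismatch, affine short
// indels) plus an intron move that consumes genome only, is admitted solely
// between GT..AG termini with length >= min_intron, and costs a fixed
// penalty. Introns must be flanked by aligned (match-state) exon columns.
//
// Sequences are 0..3 coded (A,C,G,T); any other residue is coded 4 and
// always mismatches. Local in both sequences (Smith-Waterman floor).

static const int NEG = -1000000000;

// [[Rcpp::export(name = ".cpp_splice_align")]]
List cpp_splice_align(IntegerVector q, IntegerVector g,
                      int match, int mismatch,
                      int gap_open, int gap_extend,
                      int intron_penalty, int min_intron) {
  const int m = q.size(), n = g.size();
  const int gi = gap_open + gap_extend, ge = gap_extend;
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  const size_t sz = (size_t)(m + 1) * (n + 1);

  std::vector<int> M(sz, NEG), X(sz, NEG), Y(sz, NEG), J(sz, NEG);
  std::vector<int> JD(sz, 0);                 // donor start (1-based in g) per J cell
  std::vector<unsigned char> PM(sz, 0), PX(sz, 0), PY(sz, 0);
  // pred codes: 0 restart, 1 M, 2 X, 3 Y, 4 J

  // splice signals (1-based positions in g)
  std::vector<char> donor(n + 2, 0), acceptor(n + 2, 0);
  for (int j = 1; j < n; ++j) {
    if (g[j - 1] == 2 && g[j] == 3) donor[j] = 1;    // GT at j, j+1
    if (g[j - 1] == 0 && g[j] == 2) acceptor[j + 1] = 1; // AG ending at j+1
  }

  for (int j = 0; j <= n; ++j) M[at(0, j)] = 0;
  for (int i = 0; i <= m; ++i) M[at(i, 0)] = 0;

  int best = 0, bi = -1, bj = -1;

  for (int i = 1; i <= m; ++i) {
    int run_max = NEG, run_arg = 0;
    for (int j = 1; j <= n; ++j) {
      const size_t c = at(i, j), d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1);

      // intron bookkeeping for row i (uses M of *this* row at donor-1, which
      // is safe because donors admitted at j' <= j - min_intron + 1 were
      // finalized earlier in this row sweep)
      int p = j - min_intron + 1; // newly eligible donor start for intron ending at j
      if (p >= 1 && donor[p] && M[at(i, p - 1)] > NEG / 2) {
        if (M[at(i, p - 1)] > run_max) { run_max = M[at(i, p - 1)]; run_arg = p; }
      }
      if (acceptor[j] && run_max > NEG / 2) {
        J[c] = run_max - intron_penalty;
        JD[c] = run_arg;
      }

      // M
      int s = (q[i - 1] == g[j - 1] && q[i - 1] < 4) ? match : mismatch;
      int ms = 0; unsigned char mp = 0; // local restart baseline
      if (M[d] > ms) { ms = M[d]; mp = 1; }
      if (X[d] > ms) { ms = X[d]; mp = 2; }
      if (Y[d] > ms) { ms = Y[d]; mp = 3; }
      if (J[d] > ms) { ms = J[d]; mp = 4; }
      M[c] = ms + s; PM[c] = mp;

      // X: consume query (insertion relative to genome)
      int xs = NEG; unsigned char xp = 0;
      if (M[u] > NEG / 2 && M[u] - gi > xs) { xs = M[u] - gi; xp = 1; }
      if (X[u] > NEG / 2 && X[u] - ge > xs) { xs = X[u] - ge; xp = 2; }
      if (Y[u] > NEG / 2 && Y[u] - gi > xs) { xs = Y[u] - gi; xp = 3; }
      if (xs > NEG / 2) { X[c] = xs; PX[c] = xp; }

      // Y: consume genome (short deletion in query)
      int ys = NEG; unsigned char yp = 0;
      if (M[l] > NEG / 2 && M[l] - gi > ys) { ys = M[l] - gi; yp = 1; }
      if (X[l] > NEG / 2 && X[l] - gi > ys) { ys = X[l] - gi; yp = 2; }
      if (Y[l] > NEG / 2 && Y[l] - ge > ys) { ys = Y[l] - ge; yp = 3; }
      if (ys > NEG / 2) { Y[c] = ys; PY[c] = yp; }

      if (M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }

  if (bi < 0)
    return List::create(_["score"] = 0, _["exon_start"] = IntegerVector(0),
                        _["exon_end"] = IntegerVector(0),
                        _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
                        _["n_mismatch"] = 0);

  // traceback
  int i = bi, j = bj, state = 1;
  int qs = bi, qe = bi, n_mis = 0;
  std::vector<std::pair<int,int> > introns; // (start, end) 1-based in g
  int exon_right = bj;
  std::vector<int> ex_s, ex_e;
  bool done = false;
  while (!done && (i > 0 || j > 0)) {
    if (state == 1) {
      unsigned char p = PM[at(i, j)];
      if (q[i - 1] != g[j - 1] || q[i - 1] >= 4) ++n_mis;
      qs = i;
      if (p == 4) {
        // an intron ended at j-1; exon boundary here
        size_t jc = at(i - 1, j - 1);
        int dstart = JD[jc];
        ex_s.push_back(j); ex_e.push_back(exon_right);
        introns.push_back(std::make_pair(dstart, j - 1));
        exon_right = dstart - 1;
        --i; j = dstart - 1;
        state = 1; // J came from an M cell at (i, dstart-1)
        continue;
      }
      --i; --j;
      if (p == 0) { done = true; ex_s.push_back(j + 1); ex_e.push_back(exon_right); }
      else state = p;
    } else if (state == 2) {
      unsigned char p = PX[at(i, j)];
      --i; state = p;
    } else { // 3
      unsigned char p = PY[at(i, j)];
      --j; state = p;
    }
  }
  if (!done) { ex_s.push_back(j + 1); ex_e.push_back(exon_right); }
  std::reverse(ex_s.begin(), ex_s.end());
  std::reverse(ex_e.begin(), ex_e.end());

  return List::create(_["score"] = best,
                      _["exon_start"] = IntegerVector(ex_s.begin(), ex_s.end()),
                      _["exon_end"] = IntegerVector(ex_e.begin(), ex_e.end()),
                      _["q_start"] = qs, _["q_end"] = qe,
                      _["n_mismatch"] = n_mis);
}
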