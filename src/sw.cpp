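#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman over integer-encoded peptides.
//
// Besides the optimal local score, the number of positive-scoring aligned
// residue pairs is maximized lexicographically among all score-optimal
// alignments, so the derived similarity value does not depend on arbitrary
// traceback tie-breaking. A gap of length L costs gap_open + L * gap_ext.
//
// States per cell: M (ends in an aligned pair), X (gap in subject),
// Y (gap in query). Alignments never end in a gap.

struct Cell {
  int s;   // score
  int p;   // positive pairs on the best-scoring path
  int qs;  // 1-based alignment start in query
  int ss;  // 1-based alignment start in subject
};

static inline bool better(const Cell& a, const Cell& b) {
  return a.s > b.s || (a.s == b.s && a.p > b.p);
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector query, IntegerVector subject,
              IntegerMatrix submat, int gap_open, int gap_ext) {
  const int n = query.size(), m = subject.size();
  const int NEG = -1000000;
  const Cell none = {NEG, 0, 0, 0};

  std::vector<Cell> Mprev(m + 1, none), Mcur(m + 1, none);
  std::vector<Cell> Xprev(m + 1, none), Xcur(m + 1, none);
  std::vector<Cell> Yprev(m + 1, none), Ycur(m + 1, none);

  Cell best = {0, 0, 0, 0};
  int best_qe = 0, best_se = 0;

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = Xcur[0] = Ycur[0] = none;
    for (int j = 1; j <= m; ++j) {
      const int sub = submat(query[i - 1], subject[j - 1]);

      // M: extend the best of {fresh start, M/X/Y at (i-1, j-1)}
      Cell pred = {0, 0, i, j};  // fresh local start at (i, j)
      if (better(Mprev[j - 1], pred)) pred = Mprev[j - 1];
      if (better(Xprev[j - 1], pred)) pred = Xprev[j - 1];
      if (better(Yprev[j - 1], pred)) pred = Yprev[j - 1];
      Cell mc = {pred.s + sub, pred.p + (sub > 0 ? 1 : 0), pred.qs, pred.ss};
      Mcur[j] = mc;

      // X: gap in subject (vertical)
      Cell xo = {Mprev[j].s - gap_open - gap_ext, Mprev[j].p, Mprev[j].qs, Mprev[j].ss};
      Cell xe = {Xprev[j].s - gap_ext, Xprev[j].p, Xprev[j].qs, Xprev[j].ss};
      Xcur[j] = better(xo, xe) ? xo : xe;

      // Y: gap in query (horizontal)
      Cell yo = {Mcur[j - 1].s - gap_open - gap_ext, Mcur[j - 1].p, Mcur[j - 1].qs, Mcur[j - 1].ss};
      Cell ye = {Ycur[j - 1].s - gap_ext, Ycur[j - 1].p, Ycur[j - 1].qs, Ycur[j - 1].ss};
      Ycur[j] = better(yo, ye) ? yo : ye;

      if (better(Mcur[j], best)) {
        best = Mcur[j];
        best_qe = i;
        best_se = j;
      }
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  if (best.s <= 0) {
    return List::create(_["score"] = 0, _["positives"] = 0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);
  }
  return List::create(_["score"] = best.s, _["positives"] = best.p,
                      _["q_start"] = best.qs, _["q_end"] = best_qe,
                      _["s_start"] = best.ss, _["s_end"] = best_se);
}
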