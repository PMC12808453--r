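#include <Rcpp.h>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) with full traceback.
//
// Gap convention follows EMBOSS needle/water: a gap of length L costs
// gapOpen + (L - 1) * gapExt, i.e. the first gapped residue pays the opening
// penalty.  End gaps are penalized in global mode (true Needleman-Wunsch).
//
// Tie-breaking is deterministic: the match state (diagonal) is preferred over
// a gap consuming `a` (up), which is preferred over a gap consuming `b`
// (left), both per cell and when choosing gap-state predecessors.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".alignAffineCpp")]]
List alignAffineCpp(IntegerVector ai, IntegerVector bi, NumericMatrix sub,
                    double gapOpen, double gapExt, bool local) {
  const int n = ai.size(), m = bi.size();
  // state 0 = M (diagonal), 1 = Ia (consume a against gap, "up"),
  // 2 = Ib (consume b against gap, "left"); -1 marks a path start.
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ia((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ib((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbIa((n + 1) * (m + 1), -1);
  std::vector<signed char> tbIb((n + 1) * (m + 1), -1);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      Ia[idx(i, 0)] = -(gapOpen + (i - 1) * gapExt);
      tbIa[idx(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Ib[idx(0, j)] = -(gapOpen + (j - 1) * gapExt);
      tbIb[idx(0, j)] = (j == 1) ? 0 : 2;
    }
  } else {
    for (int i = 1; i <= n; ++i) M[idx(i, 0)] = 0.0;
    for (int j = 1; j <= m; ++j) M[idx(0, j)] = 0.0;
  }

  double best = 0.0;
  int besti = local ? 0 : n, bestj = local ? 0 : m;
  signed char beststate = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(ai[i - 1] - 1, bi[j - 1] - 1);
      // M: diagonal step from the best state at (i-1, j-1)
      {
        double vM = M[idx(i - 1, j - 1)], vIa = Ia[idx(i - 1, j - 1)],
               vIb = Ib[idx(i - 1, j - 1)];
        double v = vM; signed char f = 0;
        if (vIa > v) { v = vIa; f = 1; }
        if (vIb > v) { v = vIb; f = 2; }
        double val = (v == NEG_INF) ? NEG_INF : v + s;
        if (local && val <= 0.0) { val = 0.0; f = -1; }
        M[idx(i, j)] = val;
        tbM[idx(i, j)] = f;
      }
      // Ia: consume a[i-1] against a gap
      {
        double vO = M[idx(i - 1, j)] - gapOpen;
        double vE = Ia[idx(i - 1, j)] - gapExt;
        double vB = Ib[idx(i - 1, j)] - gapOpen;
        double v = vO; signed char f = 0;
        if (vE > v) { v = vE; f = 1; }
        if (vB > v) { v = vB; f = 2; }
        Ia[idx(i, j)] = v;
        tbIa[idx(i, j)] = f;
      }
      // Ib: consume b[j-1] against a gap
      {
        double vO = M[idx(i, j - 1)] - gapOpen;
        double vA = Ia[idx(i, j - 1)] - gapOpen;
        double vE = Ib[idx(i, j - 1)] - gapExt;
        double v = vO; signed char f = 0;
        if (vA > v) { v = vA; f = 1; }
        if (vE > v) { v = vE; f = 2; }
        Ib[idx(i, j)] = v;
        tbIb[idx(i, j)] = f;
      }
      if (local && M[idx(i, j)] > best) {
        best = M[idx(i, j)];
        besti = i; bestj = j;
      }
    }
  }

  if (!local) {
    double vM = M[idx(n, m)], vIa = Ia[idx(n, m)], vIb = Ib[idx(n, m)];
    best = vM; beststate = 0;
    if (vIa > best) { best = vIa; beststate = 1; }
    if (vIb > best) { best = vIb; beststate = 2; }
  }

  // Traceback: record per-column operations, 1 = consume residue, 0 = gap.
  std::vector<int> consA, consB;
  int i = besti, j = bestj;
  signed char st = beststate;
  while (i > 0 || j > 0) {
    if (st == 0) {
      signed char f = tbM[idx(i, j)];
      if (local && f == -1) break; // local path start (score reset)
      consA.push_back(1); consB.push_back(1);
      --i; --j;
      st = f;
    } else if (st == 1) {
      signed char f = tbIa[idx(i, j)];
      consA.push_back(1); consB.push_back(0);
      --i;
      st = f;
    } else {
      signed char f = tbIb[idx(i, j)];
      consA.push_back(0); consB.push_back(1);
      --j;
      st = f;
    }
    if (local && st == 0 && tbM[idx(i, j)] == -1 && M[idx(i, j)] == 0.0)
      break;
  }
  std::reverse(consA.begin(), consA.end());
  std::reverse(consB.begin(), consB.end());

  return List::create(_["score"] = best,
                      _["consumeA"] = IntegerVector(consA.begin(), consA.end()),
                      _["consumeB"] = IntegerVector(consB.begin(), consB.end()),
                      _["startA"] = i, _["startB"] = j);
}
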