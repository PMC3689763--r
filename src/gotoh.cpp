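// Affine-gap global alignment (Gotoh) with a deterministic lexicographic
// objective: maximise score, then the number of identical columns, then
// minimise alignment length.  A gap of length L costs open + (L-1)*ext
// (the first gapped column pays `open`, each further column `ext`).
// End gaps are penalised like internal gaps.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double NEG = -1e18;

static inline bool better(double s1, int i1, int l1,
                          double s2, int i2, int l2) {
  if (s1 > s2 + 1e-9) return true;
  if (s1 < s2 - 1e-9) return false;
  if (i1 != i2) return i1 > i2;
  return l1 < l2;
}

// [[Rcpp::export(name = ".gotohAlign")]]
List gotohAlign(IntegerVector a, IntegerVector b, NumericMatrix sub,
                double gapOpen, double gapExt, bool traceback) {
  const int m = a.size(), n = b.size();
  const int W = n + 1;
  auto idx = [W](int i, int j) { return i * W + j; };

  // state 0 = M (residue/residue), 1 = X (a vs gap), 2 = Y (gap vs b)
  std::vector<double> S[3];
  std::vector<int> ID[3], LEN[3];
  std::vector<signed char> TB[3];
  for (int s = 0; s < 3; ++s) {
    S[s].assign((m + 1) * W, NEG);
    ID[s].assign((m + 1) * W, 0);
    LEN[s].assign((m + 1) * W, 0);
    TB[s].assign((m + 1) * W, -1);
  }
  S[0][idx(0, 0)] = 0.0;

  for (int i = 0; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      if (i == 0 && j == 0) continue;
      const int here = idx(i, j);
      // M: align a[i-1] with b[j-1]
      if (i > 0 && j > 0) {
        const int prev = idx(i - 1, j - 1);
        const double sc = sub(a[i - 1] - 1, b[j - 1] - 1);
        const int eq = (a[i - 1] == b[j - 1]) ? 1 : 0;
        for (int k = 0; k < 3; ++k) {
          if (S[k][prev] <= NEG / 2) continue;
          double s = S[k][prev] + sc;
          int id = ID[k][prev] + eq, ln = LEN[k][prev] + 1;
          if (better(s, id, ln, S[0][here], ID[0][here], LEN[0][here])) {
            S[0][here] = s; ID[0][here] = id; LEN[0][here] = ln;
            TB[0][here] = (signed char)k;
          }
        }
      }
      // X: a[i-1] against a gap
      if (i > 0) {
        const int prev = idx(i - 1, j);
        const double cost[3] = { gapOpen, gapExt, gapOpen };
        for (int k = 0; k < 3; ++k) {
          if (S[k][prev] <= NEG / 2) continue;
          double s = S[k][prev] - cost[k];
          int id = ID[k][prev], ln = LEN[k][prev] + 1;
          if (better(s, id, ln, S[1][here], ID[1][here], LEN[1][here])) {
            S[1][here] = s; ID[1][here] = id; LEN[1][here] = ln;
            TB[1][here] = (signed char)k;
          }
        }
      }
      // Y: a gap against b[j-1]
      if (j > 0) {
        const int prev = idx(i, j - 1);
        const double cost[3] = { gapOpen, gapOpen, gapExt };
        for (int k = 0; k < 3; ++k) {
          if (S[k][prev] <= NEG / 2) continue;
          double s = S[k][prev] - cost[k];
          int id = ID[k][prev], ln = LEN[k][prev] + 1;
          if (better(s, id, ln, S[2][here], ID[2][here], LEN[2][here])) {
            S[2][here] = s; ID[2][here] = id; LEN[2][here] = ln;
            TB[2][here] = (signed char)k;
          }
        }
      }
    }
  }

  const int endc = idx(m, n);
  int bestState = 0;
  for (int k = 1; k < 3; ++k)
    if (better(S[k][endc], ID[k][endc], LEN[k][endc],
               S[bestState][endc], ID[bestState][endc], LEN[bestState][endc]))
      bestState = k;

  List out = List::create(
    _["score"] = S[bestState][endc],
    _["identical"] = ID[bestState][endc],
    _["length"] = LEN[bestState][endc]);

  if (traceback) {
    std::vector<int> colA, colB;  // 0 = gap, else 1-based sequence position
    int i = m, j = n, st = bestState;
    while (i > 0 || j > 0) {
      int prevState = TB[st][idx(i, j)];
      if (st == 0) { colA.push_back(i); colB.push_back(j); --i; --j; }
      else if (st == 1) { colA.push_back(i); colB.push_back(0); --i; }
      else { colA.push_back(0); colB.push_back(j); --j; }
      st = prevState;
    }
    std::reverse(colA.begin(), colA.end());
    std::reverse(colB.begin(), colB.end());
    out["colA"] = wrap(colA);
    out["colB"] = wrap(colB);
  }
  return out;
}
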