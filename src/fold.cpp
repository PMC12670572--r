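#include <Rcpp.h>
using namespace Rcpp;

// Base codes: A=0, C=1, G=2, U=3; anything else is unpairable.
static inline int code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'U': return 3;
  }
  return -1;
}

// Per-pair energy stand-in: GC = -3, AU = -2, GU = -1, 0 = not pairable.
static inline int pair_energy(int a, int b, bool allow_gu) {
  if (a < 0 || b < 0) return 0;
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2;
  if (allow_gu && ((a == 2 && b == 3) || (a == 3 && b == 2))) return -1;
  return 0;
}

// Base-pair maximization over pseudoknot-free structures with hairpin
// loops of at least min_hairpin unpaired bases.  Among structures with
// the maximal number of pairs the one with the lowest total pair energy
// is chosen; remaining ties are broken deterministically by pairing each
// 3' base with its smallest admissible 5' partner during traceback.
// Returns a 1-based partner vector (0 = unpaired).
// [[Rcpp::export]]
IntegerVector nussinov_fold(std::string seq, int min_hairpin, bool allow_gu) {
  int n = (int) seq.size();
  IntegerVector pt(n, 0);
  if (n < min_hairpin + 2) return pt;
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = code(seq[i]);

  // N[i][j]: max pairs on [i..j]; E[i][j]: min energy among maximizers.
  std::vector< std::vector<int> > N(n, std::vector<int>(n, 0));
  std::vector< std::vector<int> > E(n, std::vector<int>(n, 0));
  for (int len = min_hairpin + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int bestN = N[i][j - 1], bestE = E[i][j - 1];
      for (int k = i; k <= j - min_hairpin - 1; ++k) {
        int e = pair_energy(s[k], s[j], allow_gu);
        if (e == 0) continue;
        int np = (k > i ? N[i][k - 1] : 0) + N[k + 1][j - 1] + 1;
        int en = (k > i ? E[i][k - 1] : 0) + E[k + 1][j - 1] + e;
        if (np > bestN || (np == bestN && en < bestE)) {
          bestN = np;
          bestE = en;
        }
      }
      N[i][j] = bestN;
      E[i][j] = bestE;
    }
  }

  std::vector< std::pair<int, int> > st;
  st.push_back(std::make_pair(0, n - 1));
  while (!st.empty()) {
    int i = st.back().first, j = st.back().second;
    st.pop_back();
    if (j - i < min_hairpin + 1) continue;
    if (N[i][j] == 0) continue;
    bool paired = false;
    for (int k = i; k <= j - min_hairpin - 1 && !paired; ++k) {
      int e = pair_energy(s[k], s[j], allow_gu);
      if (e == 0) continue;
      int np = (k > i ? N[i][k - 1] : 0) + N[k + 1][j - 1] + 1;
      int en = (k > i ? E[i][k - 1] : 0) + E[k + 1][j - 1] + e;
      if (np == N[i][j] && en == E[i][j]) {
        pt[k] = j + 1;
        pt[j] = k + 1;
        if (k > i) st.push_back(std::make_pair(i, k - 1));
        st.push_back(std::make_pair(k + 1, j - 1));
        paired = true;
      }
    }
    if (!paired) st.push_back(std::make_pair(i, j - 1));
  }
  return pt;
}
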