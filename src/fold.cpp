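#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Built-in local folding model: nested structures only (no pseudoknots),
// pairs GC/AU/GU with stabilities 3/2/1, minimum hairpin loop of 3
// unpaired bases. Energy = -(3*#GC + 2*#AU + 1*#GU); optimum by a
// Nussinov-style interval dynamic program, O(n^3) per window.

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': case 'T': return 3;
    default:  return -1;
  }
}

static inline int pairScore(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3; // GC
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2; // AU
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1; // GU
  return 0;
}

static void fillDP(const std::vector<int>& s, int minLoop,
                   std::vector<std::vector<int> >& M) {
  int n = (int) s.size();
  M.assign(n, std::vector<int>(n, 0));
  for (int len = minLoop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];                       // i unpaired
      for (int k = i + minLoop + 1; k <= j; ++k) {  // i paired with k
        int sc = pairScore(s[i], s[k]);
        if (sc == 0) continue;
        int cand = sc;
        if (k - 1 > i + 1 || k - 1 == i + 1) cand += M[i + 1][k - 1];
        if (k + 1 <= j) cand += M[k + 1][j];
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }
}

static std::vector<int> encode(const std::string& seq, int idx) {
  std::vector<int> s(seq.size());
  for (size_t p = 0; p < seq.size(); ++p) {
    int c = baseCode(seq[p]);
    if (c < 0)
      stop("invalid character '%s' in sequence %d (alphabet is A,C,G,U/T)",
           std::string(1, seq[p]).c_str(), idx + 1);
    s[p] = c;
  }
  return s;
}

// [[Rcpp::export(name = ".foldMFEBatch")]]
NumericVector foldMFEBatch(CharacterVector windows, int minLoop = 3) {
  int m = windows.size();
  NumericVector out(m);
  std::vector<std::vector<int> > M;
  for (int w = 0; w < m; ++w) {
    if (CharacterVector::is_na(windows[w])) { out[w] = NA_REAL; continue; }
    std::string seq = as<std::string>(windows[w]);
    if (seq.size() < (size_t)(minLoop + 2)) { out[w] = 0.0; continue; }
    std::vector<int> s = encode(seq, w);
    fillDP(s, minLoop, M);
    out[w] = -(double) M[0][seq.size() - 1];
  }
  return out;
}

static void traceback(const std::vector<int>& s, int minLoop,
                      const std::vector<std::vector<int> >& M,
                      int i, int j, std::string& db) {
  if (j - i < minLoop + 1) return;
  if (M[i][j] == M[i + 1][j]) { traceback(s, minLoop, M, i + 1, j, db); return; }
  for (int k = i + minLoop + 1; k <= j; ++k) {
    int sc = pairScore(s[i], s[k]);
    if (sc == 0) continue;
    int cand = sc;
    if (k - 1 >= i + 1) cand += M[i + 1][k - 1];
    if (k + 1 <= j) cand += M[k + 1][j];
    if (cand == M[i][j]) {
      db[i] = '('; db[k] = ')';
      traceback(s, minLoop, M, i + 1, k - 1, db);
      if (k + 1 <= j) traceback(s, minLoop, M, k + 1, j, db);
      return;
    }
  }
}

// [[Rcpp::export(name = ".foldStructureOne")]]
List foldStructureOne(std::string seq, int minLoop = 3) {
  if (seq.size() < (size_t)(minLoop + 2))
    return List::create(_["energy"] = 0.0,
                        _["structure"] = std::string(seq.size(), '.'));
  std::vector<int> s = encode(seq, 0);
  std::vector<std::vector<int> > M;
  fillDP(s, minLoop, M);
  std::string db(seq.size(), '.');
  traceback(s, minLoop, M, 0, (int) seq.size() - 1, db);
  return List::create(_["energy"] = -(double) M[0][seq.size() - 1],
                      _["structure"] = db);
}
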