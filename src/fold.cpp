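#include "quasirep.h"

using namespace Rcpp;

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Base-pair maximization (Nussinov-style) with minimum hairpin size 3 and a
// deterministic traceback: at ties, pairing position i is preferred over
// leaving it unpaired, with the leftmost admissible partner.  This is the
// engine-free fallback folding used in tests; it is not thermodynamic.
std::string nussinov_fold(const std::string& seq) {
  check_alphabet(seq);
  int n = (int) seq.size();
  std::string db(n, '.');
  if (n < 5) return db;
  // M[i][j] flattened, j >= i
  std::vector<int> M((size_t) n * n, 0);
  auto at = [&](int i, int j) -> int& { return M[(size_t) i * n + j]; };
  for (int len = 5; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = at(i + 1, j);
      for (int k = i + 4; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int v = 1 + (k - 1 >= i + 1 ? at(i + 1, k - 1) : 0) +
                (k + 1 <= j ? at(k + 1, j) : 0);
        if (v > best) best = v;
      }
      at(i, j) = best;
    }
  }
  // iterative traceback
  std::vector<std::pair<int,int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < 4) continue;
    int target = at(i, j);
    int kbest = -1;
    for (int k = i + 4; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int v = 1 + (k - 1 >= i + 1 ? at(i + 1, k - 1) : 0) +
              (k + 1 <= j ? at(k + 1, j) : 0);
      if (v == target) { kbest = k; break; }
    }
    if (kbest >= 0) {
      db[i] = '(';
      db[kbest] = ')';
      if (kbest - 1 >= i + 1) stack.push_back(std::make_pair(i + 1, kbest - 1));
      if (kbest + 1 <= j) stack.push_back(std::make_pair(kbest + 1, j));
    } else {
      stack.push_back(std::make_pair(i + 1, j));
    }
  }
  return db;
}

// [[Rcpp::export]]
CharacterVector cpp_nussinov(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = nussinov_fold(as<std::string>(seqs[i]));
  return out;
}
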