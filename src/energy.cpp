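#include "quasirep.h"

using namespace Rcpp;

EnergyParams20 ep_from_sexp(NumericVector ep20) {
  EnergyParams20 ep;
  ep.gc = (int) ep20[0];
  ep.au = (int) ep20[1];
  ep.gu = (int) ep20[2];
  ep.other = (int) ep20[3];
  ep.tail_thr = (int) ep20[4];
  return ep;
}

void check_alphabet(const std::string& s) {
  for (char c : s) {
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
      stop("sequence contains a non-RNA symbol: '%s'", std::string(1, c));
  }
}

int pair_contrib20(char a, char b, const EnergyParams20& ep) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return ep.gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return ep.au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return ep.gu;
  return ep.other;
}

// Ungapped sliding alignment of a 5' tail against a 3' tail, both given
// 5'->3' and paired antiparallel: position i of t5 pairs with position
// (n2 - 1 - i - off) of t3.  Minimum total over all offsets with >= 1
// overlapping position; never positive (0 means no binding).
int gmin20(const std::string& t5, const std::string& t3, const EnergyParams20& ep) {
  int n1 = (int) t5.size(), n2 = (int) t3.size();
  if (n1 == 0 || n2 == 0) return 0;
  int best = 0;
  for (int off = -(n1 - 1); off <= n2 - 1; ++off) {
    int s = 0;
    for (int i = 0; i < n1; ++i) {
      int j = n2 - 1 - i - off;
      if (j >= 0 && j < n2) s += pair_contrib20(t5[i], t3[j], ep);
    }
    if (s < best) best = s;
  }
  return best;
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': c = 'U'; break;
    case 'U': c = 'A'; break;
    case 'G': c = 'C'; break;
    case 'C': c = 'G'; break;
    default: stop("sequence contains a non-RNA symbol: '%s'", std::string(1, c));
    }
  }
  return r;
}

bool tail_present20(const std::string& tail, const EnergyParams20& ep) {
  if (tail.empty()) return false;
  return gmin20(tail, revcomp_str(tail), ep) <= ep.tail_thr;
}

int hamming(const std::string& a, const std::string& b) {
  if (a.size() != b.size()) stop("Hamming distance needs equal-length sequences");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}

// [[Rcpp::export]]
IntegerVector cpp_gmin(CharacterVector t5, CharacterVector t3, NumericVector ep20) {
  EnergyParams20 ep = ep_from_sexp(ep20);
  R_xlen_t n = t5.size();
  if (t3.size() != n) stop("tail vectors must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(t5[i]), b = as<std::string>(t3[i]);
    check_alphabet(a); check_alphabet(b);
    out[i] = gmin20(a, b, ep);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_tail_present(CharacterVector tails, NumericVector ep20) {
  EnergyParams20 ep = ep_from_sexp(ep20);
  LogicalVector out(tails.size());
  for (R_xlen_t i = 0; i < tails.size(); ++i) {
    std::string t = as<std::string>(tails[i]);
    check_alphabet(t);
    out[i] = tail_present20(t, ep);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("vectors must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = hamming(as<std::string>(a[i]), as<std::string>(b[i]));
  return out;
}

// Genotype Hamming distance: minimum over strand pairings (a sequence and
// its reverse complement are the same genotype).
// [[Rcpp::export]]
IntegerVector cpp_genotype_hd(CharacterVector seqs, std::string ref) {
  check_alphabet(ref);
  std::string rref = revcomp_str(ref);
  IntegerVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = std::min(hamming(s, ref), hamming(s, rref));
  }
  return out;
}

// All pairs at genotype Hamming distance exactly 1 (edge list, 1-based).
// [[Rcpp::export]]
IntegerMatrix cpp_hd1_edges(CharacterVector seqs) {
  int n = (int) seqs.size();
  std::vector<std::string> s(n), r(n);
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    r[i] = revcomp_str(s[i]);
  }
  std::vector<std::pair<int,int>> edges;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = std::min(hamming(s[i], s[j]), hamming(s[i], r[j]));
      if (d == 1) edges.push_back(std::make_pair(i + 1, j + 1));
    }
  }
  IntegerMatrix out((int) edges.size(), 2);
  for (size_t k = 0; k < edges.size(); ++k) {
    out(k, 0) = edges[k].first;
    out(k, 1) = edges[k].second;
  }
  return out;
}
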