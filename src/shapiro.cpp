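#include "quasirep.h"

using namespace Rcpp;

// pair table; -1 for unpaired; stop() on unbalanced input
static std::vector<int> pair_table(const std::string& db) {
  std::vector<int> p(db.size(), -1), st;
  for (size_t i = 0; i < db.size(); ++i) {
    char c = db[i];
    if (c == '(') st.push_back((int) i);
    else if (c == ')') {
      if (st.empty()) stop("unbalanced dot-bracket structure");
      int j = st.back(); st.pop_back();
      p[i] = j; p[j] = (int) i;
    } else if (c != '.') {
      stop("invalid character in dot-bracket structure: '%s'", std::string(1, c));
    }
  }
  if (!st.empty()) stop("unbalanced dot-bracket structure");
  return p;
}

// Coarse-grained (Shapiro-style) structure string with node labels
// H (hairpin), S (maximal stem), B (bulge), I (interior loop), M (multiloop);
// exterior unpaired regions are excluded and no exterior node is emitted.
// Each node renders as "(" + children + label + ")".
static std::string render_helix(const std::vector<int>& p, int i);

static std::string render_loop(const std::vector<int>& p, int a, int b) {
  std::vector<int> branches;
  int k = a + 1;
  while (k < b) {
    if (p[k] < 0) { ++k; }
    else { branches.push_back(k); k = p[k] + 1; }
  }
  if (branches.empty()) return "(H)";
  if (branches.size() == 1) {
    int i2 = branches[0], j2 = p[i2];
    int left = i2 - (a + 1), right = (b - 1) - j2;
    const char* lab = (left > 0 && right > 0) ? "I" : "B";
    return "(" + render_helix(p, i2) + lab + ")";
  }
  std::string s = "(";
  for (int br : branches) s += render_helix(p, br);
  return s + "M)";
}

static std::string render_helix(const std::vector<int>& p, int i) {
  int a = i, b = p[i];
  while (a + 1 < b - 1 && p[a + 1] == b - 1) { ++a; --b; }
  return "(" + render_loop(p, a, b) + "S)";
}

std::string coarse_shapiro_str(const std::string& db) {
  std::vector<int> p = pair_table(db);
  std::string out;
  int k = 0, n = (int) db.size();
  while (k < n) {
    if (p[k] < 0) { ++k; }
    else { out += render_helix(p, k); k = p[k] + 1; }
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_coarse_shapiro(CharacterVector dbs) {
  CharacterVector out(dbs.size());
  for (R_xlen_t i = 0; i < dbs.size(); ++i)
    out[i] = coarse_shapiro_str(as<std::string>(dbs[i]));
  return out;
}

StrandInfo strand_info_from(const std::string& seq, const std::string& db,
                            const EnergyParams20& ep) {
  if (seq.size() != db.size()) stop("sequence and structure differ in length");
  StrandInfo si;
  int n = (int) seq.size();
  int i = 0;
  while (i < n && db[i] == '.') ++i;
  int j = n;
  while (j > 0 && db[j - 1] == '.') --j;
  if (i >= n) {
    // open chain: the whole molecule is an exterior single strand and acts
    // as both a 5' and a 3' dangling end
    si.t5 = seq; si.t3 = seq;
  } else {
    si.t5 = seq.substr(0, i);
    si.t3 = seq.substr(j);
  }
  si.has5 = tail_present20(si.t5, ep);
  si.has3 = tail_present20(si.t3, ep);
  si.cat = (coarse_shapiro_str(db) == "((((H)S)((H)S)M)S)");
  return si;
}

int classify_bits6(bool p5, bool pc, bool p3, bool m5, bool mc, bool m3) {
  bool viable = p3 && m3;
  // per-strand role: replicase-capable, staller-like, or inert
  int nR = (int)(p5 && pc) + (int)(m5 && mc);
  int nS = (int)(p5 && !pc) + (int)(m5 && !mc);
  if (viable) return nR >= 1 ? UNIT : PARASITE;
  if (nR >= 1 && nS == 0) return HELPER;
  if (nS >= 1 && nR == 0) return STALLER;
  if (nR >= 1 && nS >= 1) return HYBRID;
  return JUNK;
}

// [[Rcpp::export]]
IntegerVector cpp_classify_bits(LogicalMatrix bits) {
  if (bits.ncol() != 6) stop("bits must have 6 columns");
  IntegerVector out(bits.nrow());
  for (int i = 0; i < bits.nrow(); ++i)
    out[i] = classify_bits6(bits(i, 0), bits(i, 1), bits(i, 2),
                            bits(i, 3), bits(i, 4), bits(i, 5));
  return out;
}

// [[Rcpp::export]]
List cpp_strand_info(CharacterVector seqs, CharacterVector dbs, NumericVector ep20) {
  EnergyParams20 ep = ep_from_sexp(ep20);
  R_xlen_t n = seqs.size();
  if (dbs.size() != n) stop("seqs and structures must have equal length");
  CharacterVector t5(n), t3(n);
  LogicalVector has5(n), has3(n), cat(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    check_alphabet(s);
    StrandInfo si = strand_info_from(s, as<std::string>(dbs[i]), ep);
    t5[i] = si.t5; t3[i] = si.t3;
    has5[i] = si.has5; has3[i] = si.has3; cat[i] = si.cat;
  }
  return List::create(_["tail5"] = t5, _["tail3"] = t3,
                      _["has5"] = has5, _["has3"] = has3,
                      _["catalytic"] = cat);
}
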