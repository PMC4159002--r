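#ifndef QUASIREP_H
#define QUASIREP_H

#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>

// Energies are handled internally as integer multiples of 0.05 ("twentieths")
// so that threshold comparisons (e.g. G <= -0.75) are exact.
struct EnergyParams20 {
  int gc, au, gu, other, tail_thr;
};

EnergyParams20 ep_from_sexp(Rcpp::NumericVector ep20);

int pair_contrib20(char a, char b, const EnergyParams20& ep);
int gmin20(const std::string& t5, const std::string& t3, const EnergyParams20& ep);
std::string revcomp_str(const std::string& s);
bool tail_present20(const std::string& tail, const EnergyParams20& ep);
void check_alphabet(const std::string& s);

std::string nussinov_fold(const std::string& seq);
std::string coarse_shapiro_str(const std::string& db);

// Per-strand structural annotation.
struct StrandInfo {
  std::string t5, t3;
  bool has5, has3, cat;
};

StrandInfo strand_info_from(const std::string& seq, const std::string& db,
                            const EnergyParams20& ep);

// Functional classes, in fixed order.
enum FuncClass { UNIT = 0, PARASITE = 1, HELPER = 2, STALLER = 3, JUNK = 4, HYBRID = 5 };

int classify_bits6(bool p5, bool pc, bool p3, bool m5, bool mc, bool m3);

int hamming(const std::string& a, const std::string& b);

#endif
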