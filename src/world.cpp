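#include "quasirep.h"
#include <deque>

using namespace Rcpp;

// Spatial Monte Carlo engine.  One Monte Carlo step visits all cells in a
// fresh random permutation; a non-empty cell runs, in order: (1) complex
// formation / dissociation, (2) replication, (3) diffusion, (4) decay.
// Complex-level phases (dissociation, replication, rigid diffusion) are
// attempted only when the visited cell holds the 5'-presenting member, so
// a complex is handled once per sweep; per-molecule decay runs for every
// molecule.  All randomness flows through R's RNG (set.seed() at R level).

struct SimParamsC {
  int W = 64, H = 64;
  double kappa = 1.0, d = 0.03, no_move = 0.1;
  double mu = 0.0, eps = 5e-4;
  int mu_mode = 0;  // 0 constant, 1 evolvable (+draws), 2 evolvable (unbiased)
  EnergyParams20 ep;
  bool check = false;
};

struct Mol {
  int cell = -1;
  int sidx = -1;      // strand-info index
  double mu = 0.0;
  int partner = -1;   // slot of complex partner, -1 if free
  bool presents5 = false;
  double k1 = 0.0;    // realized association probability of the complex
  int id = 0, parent = 0;
  long birth = 0;
  bool alive = false;
  bool inert = false; // class-to-junk intervention: tails ignored for binding
};

struct World {
  SimParamsC P;
  std::vector<int> grid;           // cell -> slot or -1
  std::deque<Mol> mols;  // deque: stable references across place()
  std::vector<int> freeslots;
  long step_no = 0;
  int next_id = 1;
  long fold_calls = 0;
  int engine = 0;                  // 0 internal fallback, 1 R callback
  RObject fold_cb;
  std::unordered_map<std::string, int> smap;
  std::vector<std::string> sseq;
  std::vector<StrandInfo> sinfo;
  std::vector<int> sclass;         // genotype class per strand entry
  int remove_mask = 0, junk_mask = 0;
  // birth log for ancestry reconstruction
  std::vector<int> log_id, log_parent;
  std::vector<double> log_birth;

  int ncells() const { return P.W * P.H; }

  std::string fold(const std::string& seq) {
    ++fold_calls;
    if (engine == 1) {
      Function f(fold_cb);
      return as<std::string>(f(seq));
    }
    return nussinov_fold(seq);
  }

  // strand-info index for a sequence, folding (and classifying the genotype)
  // at most once per unique strand
  int strand_idx(const std::string& seq) {
    auto it = smap.find(seq);
    if (it != smap.end()) return it->second;
    std::string rc = revcomp_str(seq);
    StrandInfo a = strand_info_from(seq, fold(seq), P.ep);
    int ia = (int) sseq.size();
    smap[seq] = ia; sseq.push_back(seq); sinfo.push_back(a);
    sclass.push_back(-1);
    int ib;
    auto it2 = smap.find(rc);
    if (it2 != smap.end()) ib = it2->second;
    else {
      StrandInfo b = strand_info_from(rc, fold(rc), P.ep);
      ib = (int) sseq.size();
      smap[rc] = ib; sseq.push_back(rc); sinfo.push_back(b);
      sclass.push_back(-1);
    }
    int cls = classify_bits6(sinfo[ia].has5, sinfo[ia].cat, sinfo[ia].has3,
                             sinfo[ib].has5, sinfo[ib].cat, sinfo[ib].has3);
    sclass[ia] = cls; sclass[ib] = cls;
    return ia;
  }

  int place(const std::string& seq, int cell, double mu, int parent) {
    if (grid[cell] >= 0) stop("cell already occupied");
    int slot;
    if (!freeslots.empty()) { slot = freeslots.back(); freeslots.pop_back(); }
    else { slot = (int) mols.size(); mols.push_back(Mol()); }
    Mol& m = mols[slot];
    m = Mol();
    m.cell = cell; m.sidx = strand_idx(seq); m.mu = mu;
    m.id = next_id++; m.parent = parent; m.birth = step_no; m.alive = true;
    m.inert = (junk_mask >> sclass[m.sidx]) & 1;
    grid[cell] = slot;
    log_id.push_back(m.id); log_parent.push_back(parent);
    log_birth.push_back((double) step_no);
    return slot;
  }

  void kill(int slot) {
    Mol& m = mols[slot];
    if (!m.alive) return;
    if (m.partner >= 0) {
      mols[m.partner].partner = -1;
      mols[m.partner].presents5 = false;
    }
    grid[m.cell] = -1;
    m.alive = false;
    m.partner = -1;
    freeslots.push_back(slot);
  }

  int wrap_cell(int x, int y) const {
    x = ((x % P.W) + P.W) % P.W;
    y = ((y % P.H) + P.H) % P.H;
    return y * P.W + x;
  }

  void moore(int cell, int* out) const {
    int x = cell % P.W, y = cell / P.W, k = 0;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0) continue;
        out[k++] = wrap_cell(x + dx, y + dy);
      }
  }

  double pbind(const Mol& a, const Mol& b) const {
    // a presents its 5' tail against b's 3' tail
    if (a.inert || b.inert) return 0.0;
    int g = gmin20(sinfo[a.sidx].t5, sinfo[b.sidx].t3, P.ep);
    return 1.0 - std::exp(g / 20.0);
  }

  std::string mutate_copy(const std::string& tmpl, double mu, int& nsub) {
    std::string child = revcomp_str(tmpl);
    nsub = 0;
    static const char* NT = "ACGU";
    for (char& c : child) {
      if (unif_rand() < mu) {
        char alt[3]; int na = 0;
        for (int k = 0; k < 4; ++k) if (NT[k] != c) alt[na++] = NT[k];
        c = alt[(int) (unif_rand() * 3.0) % 3];
        ++nsub;
      }
    }
    return child;
  }

  void step() {
    int N = ncells();
    std::vector<int> perm(N);
    for (int i = 0; i < N; ++i) perm[i] = i;
    for (int i = N - 1; i > 0; --i) {
      int j = (int) (unif_rand() * (i + 1)); if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    int nb[8], nb2[8];
    for (int ci = 0; ci < N; ++ci) {
      int cell = perm[ci];
      int slot = grid[cell];
      if (slot < 0) continue;
      Mol& m = mols[slot];
      if (!m.alive) continue;

      // (1) complex formation / dissociation
      if (m.partner < 0) {
        moore(m.cell, nb);
        int cand[8], nc = 0;
        for (int k = 0; k < 8; ++k) {
          int s2 = grid[nb[k]];
          if (s2 >= 0 && mols[s2].partner < 0) cand[nc++] = s2;
        }
        if (nc > 0) {
          int s2 = cand[(int) (unif_rand() * nc) % nc];
          Mol& o = mols[s2];
          double pxy = pbind(m, o), pyx = pbind(o, m);
          double k1xy = pxy, k1yx = pyx;
          if (pxy + pyx > 1.0) {
            k1xy = pxy / (pxy + pyx);
            k1yx = pyx / (pxy + pyx);
          }
          double u = unif_rand();
          if (u < k1xy) {
            m.partner = s2; o.partner = slot;
            m.presents5 = true; o.presents5 = false;
            m.k1 = o.k1 = k1xy;
          } else if (u < k1xy + k1yx) {
            m.partner = s2; o.partner = slot;
            m.presents5 = false; o.presents5 = true;
            m.k1 = o.k1 = k1yx;
          }
        }
      } else if (m.presents5) {
        if (unif_rand() < 1.0 - m.k1) {
          mols[m.partner].partner = -1;
          mols[m.partner].presents5 = false;
          m.partner = -1; m.presents5 = false;
        }
      }

      // (2) replication: the 5'-presenting member must be catalytic; the
      // 3'-presenting member is the template; empty space must be adjacent
      if (m.partner >= 0 && m.presents5 && sinfo[m.sidx].cat && !m.inert) {
        Mol& t = mols[m.partner];
        if (unif_rand() < P.kappa) {
          moore(m.cell, nb); moore(t.cell, nb2);
          int empt[16], ne = 0;
          for (int k = 0; k < 8; ++k) {
            if (grid[nb[k]] < 0 && nb[k] != t.cell) {
              bool seen = false;
              for (int q = 0; q < ne; ++q) if (empt[q] == nb[k]) seen = true;
              if (!seen) empt[ne++] = nb[k];
            }
          }
          for (int k = 0; k < 8; ++k) {
            if (grid[nb2[k]] < 0 && nb2[k] != m.cell) {
              bool seen = false;
              for (int q = 0; q < ne; ++q) if (empt[q] == nb2[k]) seen = true;
              if (!seen) empt[ne++] = nb2[k];
            }
          }
          if (ne > 0) {
            int target = empt[(int) (unif_rand() * ne) % ne];
            double tmu = (P.mu_mode == 0) ? P.mu : t.mu;
            int nsub = 0;
            std::string child = mutate_copy(sseq[t.sidx], tmu, nsub);
            double cmu = tmu;
            if (P.mu_mode > 0 && nsub >= 1) {
              double draw = (P.mu_mode == 1) ? unif_rand() * P.eps
                                             : (unif_rand() * 2.0 - 1.0) * P.eps;
              cmu = std::min(1.0, std::max(0.0, tmu + draw));
            }
            place(child, target, cmu, t.id);
            // complex breaks after replication
            t.partner = -1; t.presents5 = false;
            m.partner = -1; m.presents5 = false;
          }
        }
      }

      // (3) diffusion (one random-walk step)
      if (m.alive) {
        if (m.partner < 0) {
          moore(m.cell, nb);
          int target = nb[(int) (unif_rand() * 8) % 8];
          if (grid[target] < 0) {
            grid[m.cell] = -1;
            m.cell = target;
            grid[target] = slot;
          }
        } else if (m.presents5 && unif_rand() < 1.0 - P.no_move) {
          Mol& o = mols[m.partner];
          int dirs[8][2] = {{-1,-1},{0,-1},{1,-1},{-1,0},{1,0},{-1,1},{0,1},{1,1}};
          int di = (int) (unif_rand() * 8) % 8;
          int mx = m.cell % P.W, my = m.cell / P.W;
          int ox = o.cell % P.W, oy = o.cell / P.W;
          int tm = wrap_cell(mx + dirs[di][0], my + dirs[di][1]);
          int to = wrap_cell(ox + dirs[di][0], oy + dirs[di][1]);
          bool ok_m = (grid[tm] < 0) || tm == o.cell || tm == m.cell;
          bool ok_o = (grid[to] < 0) || to == m.cell || to == o.cell;
          if (ok_m && ok_o) {
            grid[m.cell] = -1; grid[o.cell] = -1;
            m.cell = tm; o.cell = to;
            grid[tm] = slot; grid[to] = m.partner;
          }
        }
      }

      // (4) decay
      if (m.alive && unif_rand() < P.d) kill(slot);
    }

    if (remove_mask) {
      for (int s = 0; s < (int) mols.size(); ++s)
        if (mols[s].alive && ((remove_mask >> sclass[mols[s].sidx]) & 1))
          kill(s);
    }
    ++step_no;
    if (P.check) check_invariants();
  }

  void check_invariants() const {
    int nocc = 0;
    for (int c = 0; c < ncells(); ++c) {
      int s = grid[c];
      if (s < 0) continue;
      ++nocc;
      if (!mols[s].alive || mols[s].cell != c)
        stop("occupancy invariant violated at cell %d", c);
    }
    int nalive = 0;
    for (const Mol& m : mols) {
      if (!m.alive) continue;
      ++nalive;
      if (m.partner >= 0) {
        const Mol& o = mols[m.partner];
        if (!o.alive || o.partner < 0 || &mols[o.partner] != &m)
          stop("complex pairing invariant violated");
        int dx = std::abs(m.cell % P.W - o.cell % P.W);
        int dy = std::abs(m.cell / P.W - o.cell / P.W);
        dx = std::min(dx, P.W - dx); dy = std::min(dy, P.H - dy);
        if (dx > 1 || dy > 1) stop("complex partners not adjacent");
        if (m.presents5 == o.presents5) stop("complex orientation invariant violated");
      }
    }
    if (nalive != nocc) stop("grid/molecule bookkeeping mismatch");
  }
};

static World* get_world(SEXP xp) {
  Rcpp::XPtr<World> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_world_new(int width, int height, double kappa, double d,
                   double no_move_prob, double mu, double mu_step,
                   int mu_mode, NumericVector ep20, bool check_invariants) {
  World* w = new World();
  w->P.W = width; w->P.H = height;
  w->P.kappa = kappa; w->P.d = d; w->P.no_move = no_move_prob;
  w->P.mu = mu; w->P.eps = mu_step; w->P.mu_mode = mu_mode;
  w->P.ep = ep_from_sexp(ep20);
  w->P.check = check_invariants;
  w->grid.assign(w->ncells(), -1);
  Rcpp::XPtr<World> xp(w, true);
  return xp;
}

// [[Rcpp::export]]
void cpp_world_engine(SEXP xp, int engine, Function cb) {
  World* w = get_world(xp);
  w->engine = engine;
  w->fold_cb = cb;
}

// [[Rcpp::export]]
void cpp_world_place(SEXP xp, CharacterVector seqs, IntegerVector cells,
                     NumericVector mus) {
  World* w = get_world(xp);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    check_alphabet(s);
    w->place(s, cells[i], mus[i], 0);
  }
}

// [[Rcpp::export]]
void cpp_world_step(SEXP xp, int n) {
  World* w = get_world(xp);
  for (int i = 0; i < n; ++i) w->step();
}

// [[Rcpp::export]]
void cpp_world_intervention(SEXP xp, int remove_mask, int junk_mask) {
  World* w = get_world(xp);
  w->remove_mask |= remove_mask;
  w->junk_mask |= junk_mask;
  // apply to current residents immediately
  for (int s = 0; s < (int) w->mols.size(); ++s) {
    Mol& m = w->mols[s];
    if (!m.alive) continue;
    if ((w->remove_mask >> w->sclass[m.sidx]) & 1) w->kill(s);
    else m.inert = (w->junk_mask >> w->sclass[m.sidx]) & 1;
  }
}

// [[Rcpp::export]]
List cpp_world_state(SEXP xp) {
  World* w = get_world(xp);
  int n = 0;
  for (const Mol& m : w->mols) if (m.alive) ++n;
  CharacterVector seq(n);
  IntegerVector x(n), y(n), id(n), parent(n), birth(n), cls(n), partner(n);
  NumericVector mu(n);
  LogicalVector presents5(n), inert(n);
  int k = 0;
  for (const Mol& m : w->mols) {
    if (!m.alive) continue;
    seq[k] = w->sseq[m.sidx];
    x[k] = m.cell % w->P.W; y[k] = m.cell / w->P.W;
    id[k] = m.id; parent[k] = m.parent; birth[k] = (int) m.birth;
    cls[k] = w->sclass[m.sidx];
    partner[k] = m.partner >= 0 ? w->mols[m.partner].id : NA_INTEGER;
    mu[k] = (w->P.mu_mode == 0) ? w->P.mu : m.mu;
    presents5[k] = m.presents5;
    inert[k] = m.inert;
    ++k;
  }
  return List::create(_["sequence"] = seq, _["x"] = x, _["y"] = y,
                      _["id"] = id, _["parent"] = parent, _["birth"] = birth,
                      _["class_code"] = cls, _["partner_id"] = partner,
                      _["mu"] = mu, _["presents5"] = presents5,
                      _["inert"] = inert);
}

// [[Rcpp::export]]
IntegerVector cpp_world_counts(SEXP xp) {
  World* w = get_world(xp);
  IntegerVector out(8);  // 6 classes, n complexed, n total
  for (const Mol& m : w->mols) {
    if (!m.alive) continue;
    out[w->sclass[m.sidx]]++;
    if (m.partner >= 0) out[6]++;
    out[7]++;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_world_snapshot(SEXP xp) {
  World* w = get_world(xp);
  static const char CODE[6] = {'U', 'P', 'H', 'S', 'J', 'Y'};
  CharacterVector rows(w->P.H);
  for (int y = 0; y < w->P.H; ++y) {
    std::string r(w->P.W, '.');
    for (int x = 0; x < w->P.W; ++x) {
      int s = w->grid[y * w->P.W + x];
      if (s >= 0) r[x] = CODE[w->sclass[w->mols[s].sidx]];
    }
    rows[y] = r;
  }
  return rows;
}

// [[Rcpp::export]]
List cpp_world_ancestry(SEXP xp) {
  World* w = get_world(xp);
  return List::create(_["id"] = IntegerVector(w->log_id.begin(), w->log_id.end()),
                      _["parent"] = IntegerVector(w->log_parent.begin(), w->log_parent.end()),
                      _["birth"] = NumericVector(w->log_birth.begin(), w->log_birth.end()));
}

// [[Rcpp::export]]
List cpp_world_info(SEXP xp) {
  World* w = get_world(xp);
  return List::create(_["step"] = (double) w->step_no,
                      _["fold_calls"] = (double) w->fold_calls,
                      _["unique_strands"] = (int) w->sseq.size());
}

// [[Rcpp::export]]
void cpp_world_check(SEXP xp) {
  get_world(xp)->check_invariants();
}
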