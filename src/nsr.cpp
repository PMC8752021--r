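// Monte-Carlo RNA-pool simulator on a toroidal grid.
//
// Each room holds precursors (raw material), free nucleotides (counts per
// base) and RNA molecules (base strings over A/U/C/G, optionally carrying a
// nascent complementary strand with a contiguous filled prefix). A molecule
// containing the NSR motif catalyzes nucleotide synthesis in its room.
// Material is conserved exactly: precursors + free nucleotides + all strand
// residues stays equal to the ledger total between inoculations.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include "sampling.h"

using namespace Rcpp;

namespace {

const char BASES[4] = {'A', 'U', 'C', 'G'};

inline int base_index(char b) {
  switch (b) {
    case 'A': return 0;
    case 'U': return 1;
    case 'C': return 2;
    default:  return 3;
  }
}

inline char complement_base(char b) {
  switch (b) {
    case 'A': return 'U';
    case 'U': return 'A';
    case 'C': return 'G';
    default:  return 'C';
  }
}

struct Molecule {
  std::string seq;
  std::string nascent;  // filled prefix of the complementary strand
};

struct Room {
  long precursors = 0;
  long free_nt[4] = {0, 0, 0, 0};
  std::vector<Molecule> mols;
  long free_total() const {
    return free_nt[0] + free_nt[1] + free_nt[2] + free_nt[3];
  }
};

struct NSRWorld {
  int side = 0;
  long long ledger = 0;  // conserved material total (updated by inoculation)
  long long step = 0;    // 0-based step counter
  std::string nsr_motif, ctrl_motif;
  double duplex_separation = 0.5;
  bool knockout = false;
  std::vector<Room> rooms;

  int n_rooms() const { return side * side; }

  int neighbor(int idx, int dir) const {
    // von Neumann neighborhood on the torus
    int r = idx / side, c = idx % side;
    switch (dir) {
      case 0: r = (r + 1) % side; break;
      case 1: r = (r + side - 1) % side; break;
      case 2: c = (c + 1) % side; break;
      default: c = (c + side - 1) % side; break;
    }
    return r * side + c;
  }

  bool is_nsr(const Molecule& m) const {
    return m.seq.find(nsr_motif) != std::string::npos;
  }
  bool is_ctrl(const Molecule& m) const {
    return m.seq.find(ctrl_motif) != std::string::npos;
  }
  bool room_has_functional_nsr(const Room& room) const {
    if (knockout) return false;
    for (const Molecule& m : room.mols)
      if (m.nascent.empty() && is_nsr(m)) return true;
    return false;
  }

  long long material() const {
    long long tot = 0;
    for (const Room& room : rooms) {
      tot += room.precursors + room.free_total();
      for (const Molecule& m : room.mols)
        tot += (long long)m.seq.size() + (long long)m.nascent.size();
    }
    return tot;
  }

  void count(long& nsr, long& ctrl, long& nmol) const {
    nsr = ctrl = nmol = 0;
    for (const Room& room : rooms) {
      nmol += (long)room.mols.size();
      for (const Molecule& m : room.mols) {
        if (!m.nascent.empty()) continue;  // count single-stranded only
        if (is_nsr(m)) ++nsr;
        if (is_ctrl(m)) ++ctrl;
      }
    }
  }

  void inoculate(const std::string& motif, int copies) {
    for (int i = 0; i < copies; ++i) {
      Molecule m;
      m.seq = motif;
      rooms[rand_index(n_rooms())].mols.push_back(m);
    }
    ledger += (long long)copies * (long long)motif.size();
  }

  void do_step(const double* p);
};

// parameter order: PNF PNFR PND PRL PBB PAT PFP PMV
enum { PNF, PNFR, PND, PRL, PBB, PAT, PFP, PMV };

void NSRWorld::do_step(const double* p) {
  const int R = n_rooms();

  // (1) nucleotide formation: enzymatic rate in rooms with a functional NSR
  for (int ri = 0; ri < R; ++ri) {
    Room& room = rooms[ri];
    if (room.precursors == 0) continue;
    double rate = room_has_functional_nsr(room) ? p[PNFR] : p[PNF];
    int k = rbinom_inv((int)room.precursors, rate);
    room.precursors -= k;
    for (int j = 0; j < k; ++j) room.free_nt[rand_index(4)]++;
  }

  // (2) free-nucleotide decay back to precursor
  if (p[PND] > 0) {
    for (int ri = 0; ri < R; ++ri) {
      Room& room = rooms[ri];
      for (int b = 0; b < 4; ++b) {
        if (room.free_nt[b] == 0) continue;
        int k = rbinom_inv((int)room.free_nt[b], p[PND]);
        room.free_nt[b] -= k;
        room.precursors += k;
      }
    }
  }

  // (3) random ligation: single-stranded molecules and free nucleotides
  // (length-1) are paired disjointly once per room; a pair concatenates
  // with probability PRL
  if (p[PRL] > 0) {
    for (int ri = 0; ri < R; ++ri) {
      Room& room = rooms[ri];
      std::vector<int> ss;  // indices of single-stranded molecules
      for (int mi = 0; mi < (int)room.mols.size(); ++mi)
        if (room.mols[mi].nascent.empty()) ss.push_back(mi);
      long singles = room.free_total();
      long m = (long)ss.size() + singles;
      long pairs = m / 2;
      if (pairs == 0) continue;
      int k = rbinom_inv((int)pairs, p[PRL]);
      if (k == 0) continue;

      // materialize items: molecule indices, then singleton bases
      std::vector<int> items;  // >=0: index into ss; -1-b: free base b
      items.reserve(m);
      for (int i = 0; i < (int)ss.size(); ++i) items.push_back(i);
      for (int b = 0; b < 4; ++b)
        for (long j = 0; j < room.free_nt[b]; ++j) items.push_back(-1 - b);
      for (long i = (long)items.size() - 1; i > 0; --i)
        std::swap(items[i], items[rand_index((int)i + 1)]);

      std::vector<bool> consumed(room.mols.size(), false);
      std::vector<Molecule> made;
      for (int pair_i = 0; pair_i < k; ++pair_i) {
        int a = items[2 * pair_i], b = items[2 * pair_i + 1];
        std::string sa = (a >= 0) ? room.mols[ss[a]].seq
                                  : std::string(1, BASES[-1 - a]);
        std::string sb = (b >= 0) ? room.mols[ss[b]].seq
                                  : std::string(1, BASES[-1 - b]);
        if (a >= 0) consumed[ss[a]] = true; else room.free_nt[-1 - a]--;
        if (b >= 0) consumed[ss[b]] = true; else room.free_nt[-1 - b]--;
        Molecule nm;
        nm.seq = sa + sb;
        made.push_back(nm);
      }
      std::vector<Molecule> keep;
      keep.reserve(room.mols.size() + made.size());
      for (int mi = 0; mi < (int)room.mols.size(); ++mi)
        if (!consumed[mi]) keep.push_back(std::move(room.mols[mi]));
      for (Molecule& nm : made) keep.push_back(std::move(nm));
      room.mols.swap(keep);
    }
  }

  // (4) bond breaking in single-stranded molecules (duplexes protected)
  if (p[PBB] > 0) {
    for (int ri = 0; ri < R; ++ri) {
      Room& room = rooms[ri];
      int n0 = (int)room.mols.size();
      std::vector<Molecule> frags;
      std::vector<bool> gone(n0, false);
      for (int mi = 0; mi < n0; ++mi) {
        Molecule& m = room.mols[mi];
        if (!m.nascent.empty()) continue;
        int bonds = (int)m.seq.size() - 1;
        if (bonds < 1) continue;
        int k = rbinom_inv(bonds, p[PBB]);
        if (k == 0) continue;
        // choose k distinct bond positions in 1..bonds
        std::vector<int> cut;
        while ((int)cut.size() < k) {
          int pos = 1 + rand_index(bonds);
          if (std::find(cut.begin(), cut.end(), pos) == cut.end())
            cut.push_back(pos);
        }
        std::sort(cut.begin(), cut.end());
        gone[mi] = true;
        size_t from = 0;
        cut.push_back((int)m.seq.size());
        for (int c : cut) {
          std::string piece = m.seq.substr(from, c - from);
          from = c;
          if (piece.size() == 1) {
            room.free_nt[base_index(piece[0])]++;
          } else {
            Molecule fm;
            fm.seq = piece;
            frags.push_back(fm);
          }
        }
      }
      if (frags.empty() && std::none_of(gone.begin(), gone.end(),
                                        [](bool g) { return g; }))
        continue;
      std::vector<Molecule> keep;
      for (int mi = 0; mi < n0; ++mi)
        if (!gone[mi]) keep.push_back(std::move(room.mols[mi]));
      for (Molecule& fm : frags) keep.push_back(std::move(fm));
      room.mols.swap(keep);
    }
  }

  // (5) template-directed synthesis: one attachment attempt per molecule
  // per step; complete nascent strands detach with duplex_separation
  for (int ri = 0; ri < R; ++ri) {
    Room& room = rooms[ri];
    int n0 = (int)room.mols.size();
    std::vector<Molecule> detached;
    for (int mi = 0; mi < n0; ++mi) {
      Molecule& m = room.mols[mi];
      if (m.nascent.size() < m.seq.size()) {
        if (p[PAT] > 0 && unif_rand() < p[PAT] && room.free_total() > 0) {
          char want = complement_base(m.seq[m.nascent.size()]);
          char attach;
          if (p[PFP] > 0 && unif_rand() < p[PFP]) {
            // false pairing: a uniformly random non-complementary base
            char others[3];
            int no = 0;
            for (int b = 0; b < 4; ++b)
              if (BASES[b] != want) others[no++] = BASES[b];
            attach = others[rand_index(3)];
          } else {
            attach = want;
          }
          int bi = base_index(attach);
          if (room.free_nt[bi] > 0) {
            room.free_nt[bi]--;
            m.nascent.push_back(attach);
          }
        }
      }
      if (!m.nascent.empty() && m.nascent.size() == m.seq.size() &&
          unif_rand() < duplex_separation) {
        Molecule nm;
        nm.seq.assign(m.nascent.rbegin(), m.nascent.rend());
        m.nascent.clear();
        detached.push_back(nm);  // appended after the loop, not revisited
      }
    }
    for (Molecule& nm : detached) room.mols.push_back(std::move(nm));
  }

  // (6) movement to a uniformly random von Neumann neighbor room
  if (p[PMV] > 0) {
    std::vector<std::pair<int, Molecule> > moving;
    for (int ri = 0; ri < R; ++ri) {
      Room& room = rooms[ri];
      std::vector<Molecule> stay;
      stay.reserve(room.mols.size());
      for (Molecule& m : room.mols) {
        if (unif_rand() < p[PMV])
          moving.push_back(std::make_pair(neighbor(ri, rand_index(4)),
                                          std::move(m)));
        else
          stay.push_back(std::move(m));
      }
      room.mols.swap(stay);
    }
    for (auto& mv : moving) rooms[mv.first].mols.push_back(std::move(mv.second));
  }

  ++step;
}

NSRWorld* get_world(SEXP ptr) {
  Rcpp::XPtr<NSRWorld> xp(ptr);
  return xp.get();
}

double param_or_die(const NumericVector& p, const char* nm) {
  if (!p.containsElementNamed(nm))
    stop(std::string("missing NSR parameter ") + nm);
  return as<double>(p[nm]);
}

void unpack_params(const NumericVector& params, double* out) {
  const char* nms[8] = {"PNF", "PNFR", "PND", "PRL", "PBB", "PAT", "PFP", "PMV"};
  for (int i = 0; i < 8; ++i) {
    out[i] = param_or_die(params, nms[i]);
    if (out[i] < 0 || out[i] > 1 || !std::isfinite(out[i]))
      stop(std::string("NSR parameter ") + nms[i] + " must lie in [0, 1]");
  }
}

}  // namespace

// [[Rcpp::export(name = ".nsr_world_create")]]
SEXP nsr_world_create(int side, double total_material, std::string nsr_motif,
                      std::string ctrl_motif, double duplex_separation,
                      bool knockout) {
  if (side < 2) stop("grid_side must be >= 2");
  if (total_material < 1) stop("total_material must be >= 1");
  if (nsr_motif == ctrl_motif || nsr_motif.size() != ctrl_motif.size())
    stop("nsr_motif and ctrl_motif must differ and have equal length");
  NSRWorld* w = new NSRWorld();
  w->side = side;
  w->nsr_motif = nsr_motif;
  w->ctrl_motif = ctrl_motif;
  w->duplex_separation = duplex_separation;
  w->knockout = knockout;
  w->rooms.resize(w->n_rooms());
  // all material starts as precursors, split as evenly as possible
  long long total = (long long)total_material;
  long long per = total / w->n_rooms();
  long long extra = total % w->n_rooms();
  for (int i = 0; i < w->n_rooms(); ++i)
    w->rooms[i].precursors = per + (i < extra ? 1 : 0);
  w->ledger = total;
  return Rcpp::XPtr<NSRWorld>(w, true);
}

// [[Rcpp::export(name = ".nsr_world_inoculate")]]
void nsr_world_inoculate(SEXP ptr, std::string species, int copies) {
  if (copies < 1) stop("copies must be >= 1");
  NSRWorld* w = get_world(ptr);
  if (species == "nsr") w->inoculate(w->nsr_motif, copies);
  else if (species == "ctrl") w->inoculate(w->ctrl_motif, copies);
  else stop("unknown species '" + species + "' (use 'nsr' or 'ctrl')");
}

// [[Rcpp::export(name = ".nsr_world_step")]]
void nsr_world_step(SEXP ptr, NumericVector params, int n) {
  NSRWorld* w = get_world(ptr);
  double p[8];
  unpack_params(params, p);
  for (int i = 0; i < n; ++i) w->do_step(p);
}

// [[Rcpp::export(name = ".nsr_world_counts")]]
List nsr_world_counts(SEXP ptr) {
  NSRWorld* w = get_world(ptr);
  long nsr, ctrl, nmol;
  w->count(nsr, ctrl, nmol);
  long long freet = 0, prec = 0;
  for (const Room& room : w->rooms) {
    freet += room.free_total();
    prec += room.precursors;
  }
  return List::create(
      _["step"] = (double)w->step, _["nsr"] = (double)nsr,
      _["ctrl"] = (double)ctrl, _["molecules"] = (double)nmol,
      _["free_nucleotides"] = (double)freet, _["precursors"] = (double)prec,
      _["material"] = (double)w->material(), _["ledger"] = (double)w->ledger);
}

// [[Rcpp::export(name = ".nsr_world_run")]]
DataFrame nsr_world_run(SEXP ptr, NumericVector params, int n_steps,
                        IntegerVector inoc_step, CharacterVector inoc_species,
                        IntegerVector inoc_copies, int record_every) {
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (record_every < 1) stop("record_every must be >= 1");
  NSRWorld* w = get_world(ptr);
  double p[8];
  unpack_params(params, p);
  long long last = w->step + n_steps;
  for (int i = 0; i < inoc_step.size(); ++i)
    if (inoc_step[i] >= last || (long long)inoc_step[i] < w->step)
      stop("inoculation scheduled at step %d, outside the run window",
           inoc_step[i]);

  std::vector<double> c_step, c_nsr, c_ctrl, c_mol, c_free, c_prec, c_mat;
  while (w->step < last) {
    for (int i = 0; i < inoc_step.size(); ++i) {
      if ((long long)inoc_step[i] == w->step) {
        std::string sp = as<std::string>(inoc_species[i]);
        if (sp == "nsr") w->inoculate(w->nsr_motif, inoc_copies[i]);
        else if (sp == "ctrl") w->inoculate(w->ctrl_motif, inoc_copies[i]);
        else stop("unknown species '" + sp + "'");
      }
    }
    w->do_step(p);
    if (w->step % record_every == 0 || w->step == last) {
      long nsr, ctrl, nmol;
      w->count(nsr, ctrl, nmol);
      long long freet = 0, prec = 0;
      for (const Room& room : w->rooms) {
        freet += room.free_total();
        prec += room.precursors;
      }
      c_step.push_back((double)w->step);
      c_nsr.push_back((double)nsr);
      c_ctrl.push_back((double)ctrl);
      c_mol.push_back((double)nmol);
      c_free.push_back((double)freet);
      c_prec.push_back((double)prec);
      c_mat.push_back((double)w->material());
    }
  }
  return DataFrame::create(
      _["step"] = c_step, _["nsr_count"] = c_nsr, _["ctrl_count"] = c_ctrl,
      _["molecule_count"] = c_mol, _["free_nucleotides"] = c_free,
      _["precursors"] = c_prec, _["material"] = c_mat);
}

// [[Rcpp::export(name = ".nsr_world_snapshot")]]
List nsr_world_snapshot(SEXP ptr) {
  NSRWorld* w = get_world(ptr);
  int R = w->n_rooms();
  IntegerVector room_id(R), prec(R), fA(R), fU(R), fC(R), fG(R);
  for (int i = 0; i < R; ++i) {
    room_id[i] = i;
    prec[i] = (int)w->rooms[i].precursors;
    fA[i] = (int)w->rooms[i].free_nt[0];
    fU[i] = (int)w->rooms[i].free_nt[1];
    fC[i] = (int)w->rooms[i].free_nt[2];
    fG[i] = (int)w->rooms[i].free_nt[3];
  }
  std::vector<int> mroom;
  std::vector<std::string> mseq, mnas;
  for (int i = 0; i < R; ++i)
    for (const Molecule& m : w->rooms[i].mols) {
      mroom.push_back(i);
      mseq.push_back(m.seq);
      mnas.push_back(m.nascent);
    }
  return List::create(
      _["rooms"] = DataFrame::create(_["room"] = room_id,
                                     _["precursors"] = prec, _["fA"] = fA,
                                     _["fU"] = fU, _["fC"] = fC, _["fG"] = fG),
      _["molecules"] = DataFrame::create(
          _["room"] = wrap(mroom), _["sequence"] = wrap(mseq),
          _["nascent"] = wrap(mnas), _["stringsAsFactors"] = false),
      _["step"] = (double)w->step, _["ledger"] = (double)w->ledger);
}

// [[Rcpp::export(name = ".nsr_world_restore")]]
SEXP nsr_world_restore(int side, std::string nsr_motif, std::string ctrl_motif,
                       double duplex_separation, bool knockout,
                       IntegerVector precursors, IntegerVector fA,
                       IntegerVector fU, IntegerVector fC, IntegerVector fG,
                       IntegerVector mol_room, CharacterVector mol_seq,
                       CharacterVector mol_nascent, double step,
                       double ledger) {
  if (side < 2) stop("grid_side must be >= 2");
  NSRWorld* w = new NSRWorld();
  w->side = side;
  w->nsr_motif = nsr_motif;
  w->ctrl_motif = ctrl_motif;
  w->duplex_separation = duplex_separation;
  w->knockout = knockout;
  w->rooms.resize(w->n_rooms());
  if (precursors.size() != w->n_rooms()) stop("room table has wrong length");
  for (int i = 0; i < w->n_rooms(); ++i) {
    w->rooms[i].precursors = precursors[i];
    w->rooms[i].free_nt[0] = fA[i];
    w->rooms[i].free_nt[1] = fU[i];
    w->rooms[i].free_nt[2] = fC[i];
    w->rooms[i].free_nt[3] = fG[i];
  }
  for (int i = 0; i < mol_room.size(); ++i) {
    Molecule m;
    m.seq = as<std::string>(mol_seq[i]);
    m.nascent = as<std::string>(mol_nascent[i]);
    if (m.nascent.size() > m.seq.size())
      stop("nascent strand longer than its template");
    w->rooms[mol_room[i]].mols.push_back(m);
  }
  w->step = (long long)step;
  w->ledger = (long long)ledger;
  if (w->material() != w->ledger)
    stop("restored state violates material conservation");
  return Rcpp::XPtr<NSRWorld>(w, true);
}
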