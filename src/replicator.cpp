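// Lattice replicator simulator with three trans-acting activity classes.
//
// A replicator is a count vector of monomers devoted to replicase activity
// (A), fidelity activity (B), metabolic activity (C) and neutral filler
// (N); its length L is the total. Activities follow a saturating curve
// beta * l/(l+gamma) * exp(-alpha*L) (alpha fixed at 0 for class C) and act
// in trans: a replicator is copied at a rate set by the activities of its
// Moore neighbors, creating the tension between helping neighbors and
// being copied oneself that limited dispersal is meant to resolve.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "sampling.h"

using namespace Rcpp;

namespace {

struct Rep {
  int l[4] = {0, 0, 0, 0};  // A, B, C, N
  int len() const { return l[0] + l[1] + l[2] + l[3]; }
  bool alive() const { return len() > 0; }
};

struct RepConfig {
  int side = 30;
  double occupancy = 0.5;
  int initial_length = 5;
  double decay = 0.07;          // d: per-replicator removal probability
  double dispersal = 0.01;      // D: per-replicator swap probability
  double eps0 = 0.05;           // base per-monomer copy error rate
  double indel_fraction = 0.2;  // fraction of errors that are indels
  double claim_scale = 0.2;     // K: weight-to-probability scale
  double copy_cost_scale = 25;  // length scale of the copy-speed penalty
};

struct RepWorld {
  RepConfig cfg;
  long long step = 0;
  std::vector<Rep> grid;

  int n_sites() const { return cfg.side * cfg.side; }

  int moore(int idx, int k) const {
    // k in 0..7, offsets excluding (0,0)
    static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    int s = cfg.side;
    int r = (idx / s + dr[k] + s) % s;
    int c = (idx % s + dc[k] + s) % s;
    return r * s + c;
  }
  int von_neumann(int idx, int k) const {
    static const int dr[4] = {-1, 1, 0, 0};
    static const int dc[4] = {0, 0, -1, 1};
    int s = cfg.side;
    int r = (idx / s + dr[k] + s) % s;
    int c = (idx % s + dc[k] + s) % s;
    return r * s + c;
  }

  void do_step(const double* p);
};

// parameter order: alpha_A beta_A gamma_A alpha_B beta_B gamma_B beta_C gamma_C
enum { A_A, B_A, G_A, A_B, B_B, G_B, B_C, G_C };

inline double activity_fn(double l, double L, double alpha, double beta,
                          double gamma) {
  if (l <= 0) return 0.0;
  return beta * (l / (l + gamma)) * std::exp(-alpha * L);
}

void RepWorld::do_step(const double* p) {
  const int N = n_sites();
  const std::vector<Rep> snap = grid;  // state at the start of replication

  // per-replicator activities and neighbor sums from the snapshot
  std::vector<double> aA(N, 0), aB(N, 0), aC(N, 0);
  for (int i = 0; i < N; ++i) {
    if (!snap[i].alive()) continue;
    double L = snap[i].len();
    aA[i] = activity_fn(snap[i].l[0], L, p[A_A], p[B_A], p[G_A]);
    aB[i] = activity_fn(snap[i].l[1], L, p[A_B], p[B_B], p[G_B]);
    aC[i] = activity_fn(snap[i].l[2], L, 0.0, p[B_C], p[G_C]);
  }
  std::vector<double> weight(N, 0), eps_eff(N, 0);
  for (int i = 0; i < N; ++i) {
    if (!snap[i].alive()) continue;
    // replicase acts strictly in trans (a molecule cannot copy itself,
    // so it depends on its neighbors' replicase activity); metabolic
    // products fuel the carrier's own replication (cis); proofreading
    // benefits the copy in progress (cis) and neighbors (trans)
    double sA = 0, sB = aB[i];
    for (int k = 0; k < 8; ++k) {
      int j = moore(i, k);
      sA += aA[j];
      sB += aB[j];
    }
    double L = snap[i].len();
    // replication needs a replicase in reach and own metabolic activity;
    // longer templates copy more slowly
    weight[i] = sA * aC[i] / (1.0 + L / cfg.copy_cost_scale);
    eps_eff[i] = cfg.eps0 / (1.0 + sB);
  }

  // (1) replication lottery at each empty site
  for (int i = 0; i < N; ++i) {
    if (snap[i].alive()) continue;
    double tot = 0;
    int nb[8];
    int nn = 0;
    for (int k = 0; k < 8; ++k) {
      int j = moore(i, k);
      if (snap[j].alive() && weight[j] > 0) {
        nb[nn++] = j;
        tot += weight[j];
      }
    }
    if (tot <= 0) continue;
    double claim = tot / cfg.claim_scale;
    if (claim < 1.0 && unif_rand() >= claim) continue;
    // winner proportional to weight
    double u = unif_rand() * tot;
    int win = nb[nn - 1];
    double acc = 0;
    for (int k = 0; k < nn; ++k) {
      acc += weight[nb[k]];
      if (u < acc) { win = nb[k]; break; }
    }
    // copy with per-monomer errors at the parent's effective rate
    const Rep& par = snap[win];
    double eps = eps_eff[win];
    Rep child;
    for (int c = 0; c < 4; ++c) {
      for (int m = 0; m < par.l[c]; ++m) {
        if (eps > 0 && unif_rand() < eps) {
          if (unif_rand() < cfg.indel_fraction) {
            if (unif_rand() < 0.5) {
              // insertion: faithful copy plus one random-class monomer
              child.l[c]++;
              child.l[rand_index(4)]++;
            }
            // deletion: monomer skipped
          } else {
            child.l[rand_index(4)]++;  // substitution to a random class
          }
        } else {
          child.l[c]++;
        }
      }
    }
    if (!child.alive()) child.l[3] = 1;  // length never drops below 1
    grid[i] = child;
  }

  // (2) decay
  if (cfg.decay > 0) {
    for (int i = 0; i < N; ++i)
      if (grid[i].alive() && unif_rand() < cfg.decay) grid[i] = Rep();
  }

  // (3) dispersal: swap with a random von Neumann neighbor
  if (cfg.dispersal > 0) {
    for (int i = 0; i < N; ++i) {
      if (!grid[i].alive()) continue;
      if (unif_rand() < cfg.dispersal) {
        int j = von_neumann(i, rand_index(4));
        std::swap(grid[i], grid[j]);
      }
    }
  }

  ++step;
}

RepWorld* get_world(SEXP ptr) {
  Rcpp::XPtr<RepWorld> xp(ptr);
  return xp.get();
}

void unpack_params(const NumericVector& params, double* out) {
  const char* nms[8] = {"alpha_A", "beta_A", "gamma_A", "alpha_B",
                        "beta_B", "gamma_B", "beta_C", "gamma_C"};
  for (int i = 0; i < 8; ++i) {
    if (!params.containsElementNamed(nms[i]))
      stop(std::string("missing replicator parameter ") + nms[i]);
    out[i] = as<double>(params[nms[i]]);
    if (!std::isfinite(out[i]) || out[i] <= 0)
      stop(std::string("replicator parameter ") + nms[i] +
           " must be positive");
  }
}

void summarize(const RepWorld* w, double fallback, double& pop, double& mlen,
               double& mA, double& mB, double& mC, const double* p) {
  long n = 0;
  double slen = 0, sA = 0, sB = 0, sC = 0;
  for (const Rep& r : w->grid) {
    if (!r.alive()) continue;
    ++n;
    double L = r.len();
    slen += L;
    sA += activity_fn(r.l[0], L, p[A_A], p[B_A], p[G_A]);
    sB += activity_fn(r.l[1], L, p[A_B], p[B_B], p[G_B]);
    sC += activity_fn(r.l[2], L, 0.0, p[B_C], p[G_C]);
  }
  pop = (double)n;
  if (n == 0) {
    mlen = fallback;
    mA = mB = mC = 0;
  } else {
    mlen = slen / n;
    mA = sA / n;
    mB = sB / n;
    mC = sC / n;
  }
}

}  // namespace

// [[Rcpp::export(name = ".rep_activity")]]
double rep_activity(double l, double L, double alpha, double beta,
                    double gamma) {
  return activity_fn(l, L, alpha, beta, gamma);
}

// [[Rcpp::export(name = ".rep_world_create")]]
SEXP rep_world_create(int side, double occupancy, int initial_length,
                      double decay, double dispersal, double eps0,
                      double indel_fraction, double claim_scale,
                      double copy_cost_scale, bool random_composition) {
  if (side < 3) stop("lattice_side must be >= 3");
  if (initial_length < 1) stop("initial_length must be >= 1");
  RepWorld* w = new RepWorld();
  w->cfg.side = side;
  w->cfg.occupancy = occupancy;
  w->cfg.initial_length = initial_length;
  w->cfg.decay = decay;
  w->cfg.dispersal = dispersal;
  w->cfg.eps0 = eps0;
  w->cfg.indel_fraction = indel_fraction;
  w->cfg.claim_scale = claim_scale;
  w->cfg.copy_cost_scale = copy_cost_scale;
  w->grid.resize(w->n_sites());
  for (int i = 0; i < w->n_sites(); ++i) {
    if (unif_rand() < occupancy) {
      Rep r;
      if (random_composition) {
        for (int m = 0; m < initial_length; ++m) r.l[rand_index(4)]++;
      } else {
        // deterministic founder: one monomer of each activity class,
        // remainder neutral
        r.l[0] = r.l[1] = r.l[2] = 1;
        r.l[3] = initial_length - 3;
        if (r.l[3] < 0) { r.l[0] = initial_length; r.l[1] = r.l[2] = r.l[3] = 0; }
      }
      w->grid[i] = r;
    }
  }
  return Rcpp::XPtr<RepWorld>(w, true);
}

// [[Rcpp::export(name = ".rep_world_step")]]
void rep_world_step(SEXP ptr, NumericVector params, int n) {
  RepWorld* w = get_world(ptr);
  double p[8];
  unpack_params(params, p);
  for (int i = 0; i < n; ++i) w->do_step(p);
}

// [[Rcpp::export(name = ".rep_world_counts")]]
List rep_world_counts(SEXP ptr, NumericVector params, double fallback) {
  RepWorld* w = get_world(ptr);
  double p[8];
  unpack_params(params, p);
  double pop, mlen, mA, mB, mC;
  summarize(w, fallback, pop, mlen, mA, mB, mC, p);
  return List::create(_["step"] = (double)w->step, _["population"] = pop,
                      _["mean_length"] = mlen, _["mean_aA"] = mA,
                      _["mean_aB"] = mB, _["mean_aC"] = mC);
}

// [[Rcpp::export(name = ".rep_world_run")]]
DataFrame rep_world_run(SEXP ptr, NumericVector params, int n_steps,
                        int record_every, double fallback) {
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (record_every < 1) stop("record_every must be >= 1");
  RepWorld* w = get_world(ptr);
  double p[8];
  unpack_params(params, p);
  long long last = w->step + n_steps;
  std::vector<double> c_step, c_pop, c_len, c_a, c_b, c_c;
  while (w->step < last) {
    w->do_step(p);
    if (w->step % record_every == 0 || w->step == last) {
      double pop, mlen, mA, mB, mC;
      summarize(w, fallback, pop, mlen, mA, mB, mC, p);
      c_step.push_back((double)w->step);
      c_pop.push_back(pop);
      c_len.push_back(mlen);
      c_a.push_back(mA);
      c_b.push_back(mB);
      c_c.push_back(mC);
    }
  }
  return DataFrame::create(_["step"] = c_step, _["population"] = c_pop,
                           _["mean_length"] = c_len, _["mean_aA"] = c_a,
                           _["mean_aB"] = c_b, _["mean_aC"] = c_c);
}

// [[Rcpp::export(name = ".rep_world_snapshot")]]
DataFrame rep_world_snapshot(SEXP ptr) {
  RepWorld* w = get_world(ptr);
  std::vector<int> site, lA, lB, lC, lN;
  for (int i = 0; i < w->n_sites(); ++i) {
    if (!w->grid[i].alive()) continue;
    site.push_back(i);
    lA.push_back(w->grid[i].l[0]);
    lB.push_back(w->grid[i].l[1]);
    lC.push_back(w->grid[i].l[2]);
    lN.push_back(w->grid[i].l[3]);
  }
  return DataFrame::create(_["site"] = wrap(site), _["l_A"] = wrap(lA),
                           _["l_B"] = wrap(lB), _["l_C"] = wrap(lC),
                           _["l_N"] = wrap(lN));
}

// [[Rcpp::export(name = ".rep_world_restore")]]
SEXP rep_world_restore(int side, double occupancy, int initial_length,
                       double decay, double dispersal, double eps0,
                       double indel_fraction, double claim_scale,
                       double copy_cost_scale, IntegerVector site,
                       IntegerVector lA, IntegerVector lB, IntegerVector lC,
                       IntegerVector lN, double step) {
  if (side < 3) stop("lattice_side must be >= 3");
  RepWorld* w = new RepWorld();
  w->cfg.side = side;
  w->cfg.occupancy = occupancy;
  w->cfg.initial_length = initial_length;
  w->cfg.decay = decay;
  w->cfg.dispersal = dispersal;
  w->cfg.eps0 = eps0;
  w->cfg.indel_fraction = indel_fraction;
  w->cfg.claim_scale = claim_scale;
  w->cfg.copy_cost_scale = copy_cost_scale;
  w->grid.resize(w->n_sites());
  for (int i = 0; i < site.size(); ++i) {
    if (site[i] < 0 || site[i] >= w->n_sites()) stop("site index out of range");
    Rep r;
    r.l[0] = lA[i];
    r.l[1] = lB[i];
    r.l[2] = lC[i];
    r.l[3] = lN[i];
    if (!r.alive()) stop("replicator length must be >= 1");
    w->grid[site[i]] = r;
  }
  w->step = (long long)step;
  return Rcpp::XPtr<RepWorld>(w, true);
}
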