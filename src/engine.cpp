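#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-keyed RNG.
//
// Every stochastic ingredient (topology regrowth, prenatal damage, the
// marking/repair draws of each species in each pair) draws from its own
// splitmix64 stream whose state is derived by hashing
// (master_seed, pair_id, species_index, purpose).  Streams are therefore
// independent of iteration order, and a species' draw sequence depends only
// on its own state history -- this is what makes a C_A = 0 pair member
// bitwise identical to a solo run with the same keys.
// ---------------------------------------------------------------------------

static inline uint64_t sm64_next(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  double unif() {  // uniform on [0, 1) with 53-bit resolution
    return (double)(sm64_next(s) >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) {  // uniform integer on {0, ..., n-1}
    return (int)(sm64_next(s) % (uint64_t)n);
  }
};

static uint64_t key_seed(uint64_t master, uint64_t pair_id,
                         uint64_t species, uint64_t purpose) {
  uint64_t s = master ^ 0xA5A5A5A55A5A5A5AULL;
  sm64_next(s);
  s ^= pair_id * 0x9E3779B97F4A7C15ULL;
  sm64_next(s);
  s ^= species * 0xC2B2AE3D27D4EB4FULL;
  sm64_next(s);
  s ^= purpose * 0x165667B19E3779F9ULL;
  return sm64_next(s);
}

enum Purpose { PUR_TOPO = 0, PUR_PRENATAL = 1, PUR_DYNAMICS = 2 };

// node status / cause codes
static const uint8_t FUNCTIONAL = 0, DYSFUNCTIONAL = 1;
static const uint8_t CAUSE_NONE = 0, CAUSE_INTRINSIC = 1, CAUSE_COAGEING = 2;

// ---------------------------------------------------------------------------
// Network growth: 2-node mutually dependent seed, then each new node k picks
// one uniform existing dependee (k depends on u) and one uniform existing
// dependent (v depends on k).  Self-edges impossible; parallel edges cannot
// arise because the new node carries at most one edge in each direction.
// ---------------------------------------------------------------------------

struct Topology {
  int n;
  std::vector<int> ptr;  // CSR over dependees: ptr[i]..ptr[i+1]
  std::vector<int> idx;
};

static void grow_adj(int n, uint64_t seed,
                     std::vector< std::vector<int> > &dep,
                     std::vector< std::vector<int> > &dpt) {
  Rng rng(seed);
  dep.assign(n, std::vector<int>());
  dpt.assign(n, std::vector<int>());
  dep[0].push_back(1); dep[1].push_back(0);
  dpt[0].push_back(1); dpt[1].push_back(0);
  for (int k = 2; k < n; ++k) {
    int u = rng.below(k);          // k depends on u
    dep[k].push_back(u);
    dpt[u].push_back(k);
    int v = rng.below(k);          // v depends on k
    dep[v].push_back(k);
    dpt[k].push_back(v);
  }
}

static Topology grow_topology(int n, uint64_t seed) {
  std::vector< std::vector<int> > dep, dpt;
  grow_adj(n, seed, dep, dpt);
  Topology t;
  t.n = n;
  t.ptr.assign(n + 1, 0);
  for (int i = 0; i < n; ++i) t.ptr[i + 1] = t.ptr[i] + (int)dep[i].size();
  t.idx.reserve(t.ptr[n]);
  for (int i = 0; i < n; ++i)
    for (size_t j = 0; j < dep[i].size(); ++j) t.idx.push_back(dep[i][j]);
  return t;
}

// [[Rcpp::export(name = ".grow_network_cpp")]]
List grow_network_cpp(int n_nodes, double seed) {
  std::vector< std::vector<int> > dep, dpt;
  grow_adj(n_nodes, (uint64_t)seed, dep, dpt);
  List dl(n_nodes), pl(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    dl[i] = IntegerVector(dep[i].begin(), dep[i].end());
    pl[i] = IntegerVector(dpt[i].begin(), dpt[i].end());
  }
  return List::create(_["dependees"] = dl, _["dependents"] = pl);
}

// ---------------------------------------------------------------------------
// Damage propagation: synchronous sweeps to the fixed point at which no
// functional node has strictly more than half of its dependees dysfunctional.
// A propagated failure inherits the majority cause among its dysfunctional
// dependees; an exact half-and-half split is tagged intrinsic.
// ---------------------------------------------------------------------------

struct Species {
  int n;
  double d, r, C, f0, phiT;
  const Topology *topo;
  std::vector<uint8_t> status, cause;
  int f, ns, nc;
  bool dead, censored;
  int death_time;          // step index (>=1), or -1
  uint8_t death_cause;     // CAUSE_* at collapse
  Rng rng;

  Species() : rng(0) {}

  void recount() {
    f = ns = nc = 0;
    for (int i = 0; i < n; ++i) {
      if (status[i] == FUNCTIONAL) ++f;
      else if (cause[i] == CAUSE_COAGEING) ++nc;
      else ++ns;
    }
  }
};

static void propagate(const Topology &topo, std::vector<uint8_t> &status,
                      std::vector<uint8_t> &cause) {
  const int n = topo.n;
  std::vector<int> newly;
  std::vector<uint8_t> newcause;
  for (;;) {
    newly.clear(); newcause.clear();
    for (int i = 0; i < n; ++i) {
      if (status[i] != FUNCTIONAL) continue;
      int lo = topo.ptr[i], hi = topo.ptr[i + 1], ndep = hi - lo;
      if (ndep == 0) continue;
      int bad = 0, ci = 0, cc = 0;
      for (int j = lo; j < hi; ++j) {
        int v = topo.idx[j];
        if (status[v] == DYSFUNCTIONAL) {
          ++bad;
          if (cause[v] == CAUSE_COAGEING) ++cc; else ++ci;
        }
      }
      if (2 * bad > ndep) {
        newly.push_back(i);
        newcause.push_back(cc > ci ? CAUSE_COAGEING : CAUSE_INTRINSIC);
      }
    }
    if (newly.empty()) break;
    for (size_t k = 0; k < newly.size(); ++k) {
      status[newly[k]] = DYSFUNCTIONAL;
      cause[newly[k]] = newcause[k];
    }
  }
}

// [[Rcpp::export(name = ".propagate_cpp")]]
List propagate_cpp(IntegerVector dep_ptr, IntegerVector dep_idx,
                   IntegerVector status, IntegerVector cause) {
  Topology topo;
  topo.n = status.size();
  topo.ptr.assign(dep_ptr.begin(), dep_ptr.end());
  topo.idx.assign(dep_idx.begin(), dep_idx.end());
  std::vector<uint8_t> st(status.begin(), status.end());
  std::vector<uint8_t> cz(cause.begin(), cause.end());
  propagate(topo, st, cz);
  return List::create(_["status"] = IntegerVector(st.begin(), st.end()),
                      _["cause"] = IntegerVector(cz.begin(), cz.end()));
}

// Prenatal damage: exactly round((1 - f0) * n) uniformly chosen nodes start
// dysfunctional, tagged intrinsic (partial Fisher-Yates draw).
static void apply_prenatal(Species &S, Rng &rng) {
  S.status.assign(S.n, FUNCTIONAL);
  S.cause.assign(S.n, CAUSE_NONE);
  int k = (int)std::floor((1.0 - S.f0) * S.n + 0.5);
  if (k > 0) {
    std::vector<int> ids(S.n);
    for (int i = 0; i < S.n; ++i) ids[i] = i;
    for (int j = 0; j < k; ++j) {
      int pick = j + rng.below(S.n - j);
      std::swap(ids[j], ids[pick]);
      S.status[ids[j]] = DYSFUNCTIONAL;
      S.cause[ids[j]] = CAUSE_INTRINSIC;
    }
  }
  S.recount();
}

// [[Rcpp::export(name = ".prenatal_cpp")]]
List prenatal_cpp(int n_nodes, double f0, double seed) {
  Species S;
  S.n = n_nodes; S.f0 = f0;
  Rng rng((uint64_t)seed);
  apply_prenatal(S, rng);
  return List::create(_["status"] = IntegerVector(S.status.begin(), S.status.end()),
                      _["cause"] = IntegerVector(S.cause.begin(), S.cause.end()));
}

static void repair_round(Species &S) {
  if (S.r <= 0.0) return;
  for (int i = 0; i < S.n; ++i) {
    if (S.status[i] == DYSFUNCTIONAL && S.rng.unif() < S.r) {
      S.status[i] = FUNCTIONAL;
      S.cause[i] = CAUSE_NONE;
    }
  }
}

// One species' full update for a time step: intrinsic round (mark with
// probability d, propagate, repair) then co-ageing round (mark with
// probability alpha = C * f_opp / N_opp, propagate, repair).
static void update_species(Species &S, double f_opp_frac, int &n_clipped) {
  // round one: intrinsic
  if (S.d > 0.0) {
    for (int i = 0; i < S.n; ++i)
      if (S.status[i] == FUNCTIONAL && S.rng.unif() < S.d) {
        S.status[i] = DYSFUNCTIONAL;
        S.cause[i] = CAUSE_INTRINSIC;
      }
  }
  propagate(*S.topo, S.status, S.cause);
  repair_round(S);
  // round two: co-ageing
  double alpha = S.C * f_opp_frac;
  if (alpha > 1.0) { alpha = 1.0; ++n_clipped; }
  if (alpha > 0.0) {
    for (int i = 0; i < S.n; ++i)
      if (S.status[i] == FUNCTIONAL && S.rng.unif() < alpha) {
        S.status[i] = DYSFUNCTIONAL;
        S.cause[i] = CAUSE_COAGEING;
      }
  }
  propagate(*S.topo, S.status, S.cause);
  repair_round(S);
  S.recount();
}

static bool below_threshold(const Species &S) {
  return (double)S.f / (double)S.n < S.phiT;
}

static void init_species_params(Species &S, List params) {
  S.n = as<int>(params["n_nodes"]);
  S.d = as<double>(params["d"]);
  S.r = as<double>(params["r"]);
  S.C = as<double>(params["C"]);
  S.f0 = as<double>(params["f0"]);
  S.phiT = as<double>(params["phi_T"]);
  S.dead = false; S.censored = false;
  S.death_time = -1; S.death_cause = CAUSE_NONE;
}

// A species whose remaining damage sources are all switched off can never
// die; detecting this lets immortal survivors (e.g. chess winners with
// d = 0) be censored without stepping to max_steps.
static bool immortal_static(const Species &S, const Species *opp) {
  if (S.dead) return false;
  if (S.d > 0.0) return false;
  if (S.C > 0.0 && opp != 0 && !opp->dead) return false;
  // with repair active, residual damage keeps the state evolving (upwards)
  if (S.r > 0.0 && S.f < S.n) return false;
  return true;
}

struct TrajBuf {
  std::vector<int> pair, species, t, f, ns, nc;
  void push(int p, int sp, int tt, const Species &S) {
    pair.push_back(p); species.push_back(sp); t.push_back(tt);
    f.push_back(S.f); ns.push_back(S.ns); nc.push_back(S.nc);
  }
};

// Runs one pair (or a solo individual when has_B is false) to completion.
static void run_pair(Species &A, Species *B, int max_steps,
                     bool winner_continues, int pair_id, bool record,
                     TrajBuf &buf, int &n_clipped) {
  bool has_B = (B != 0);
  if (record) {
    buf.push(pair_id, 1, 0, A);
    if (has_B) buf.push(pair_id, 2, 0, *B);
  }
  // prenatal damage can already place a network under the threshold
  if (below_threshold(A)) {
    A.dead = true; A.death_time = 0;
    A.death_cause = (A.nc > A.ns) ? CAUSE_COAGEING : CAUSE_INTRINSIC;
  }
  if (has_B && below_threshold(*B)) {
    B->dead = true; B->death_time = 0;
    B->death_cause = (B->nc > B->ns) ? CAUSE_COAGEING : CAUSE_INTRINSIC;
  }
  for (int t = 1; t <= max_steps; ++t) {
    bool a_done = A.dead || immortal_static(A, B);
    bool b_done = !has_B || B->dead || immortal_static(*B, &A);
    if (a_done && b_done) break;
    if (!A.dead) {
      double f_opp = 0.0;
      if (has_B && !B->dead) f_opp = (double)B->f / (double)B->n;
      update_species(A, f_opp, n_clipped);
      if (below_threshold(A)) {
        A.dead = true; A.death_time = t;
        A.death_cause = (A.nc > A.ns) ? CAUSE_COAGEING : CAUSE_INTRINSIC;
      }
    }
    if (has_B && !B->dead) {
      double f_opp = A.dead ? 0.0 : (double)A.f / (double)A.n;
      update_species(*B, f_opp, n_clipped);
      if (below_threshold(*B)) {
        B->dead = true; B->death_time = t;
        B->death_cause = (B->nc > B->ns) ? CAUSE_COAGEING : CAUSE_INTRINSIC;
      }
    }
    if (record) {
      buf.push(pair_id, 1, t, A);
      if (has_B) buf.push(pair_id, 2, t, *B);
    }
    if (A.dead && (!has_B || B->dead)) break;
    if (!winner_continues && (A.dead || (has_B && B->dead))) break;
  }
  if (!A.dead) A.censored = true;
  if (has_B && !B->dead) B->censored = true;
}

// [[Rcpp::export(name = ".simulate_cohort_cpp")]]
List simulate_cohort_cpp(IntegerVector depA_ptr, IntegerVector depA_idx,
                         List params_A, SEXP depB_ptr_, SEXP depB_idx_,
                         SEXP params_B_, int cohort_size, int max_steps,
                         bool winner_continues, double master_seed,
                         bool randomize_topology, bool record_trajectories) {
  uint64_t master = (uint64_t)master_seed;
  bool has_B = !Rf_isNull(params_B_);

  Topology topoA, topoB;
  topoA.n = depA_ptr.size() - 1;
  topoA.ptr.assign(depA_ptr.begin(), depA_ptr.end());
  topoA.idx.assign(depA_idx.begin(), depA_idx.end());
  List params_B;
  if (has_B) {
    params_B = List(params_B_);
    IntegerVector bp(depB_ptr_), bi(depB_idx_);
    topoB.n = bp.size() - 1;
    topoB.ptr.assign(bp.begin(), bp.end());
    topoB.idx.assign(bi.begin(), bi.end());
  }

  int n_clipped = 0;
  TrajBuf buf;
  int n_rows = cohort_size * (has_B ? 2 : 1);
  IntegerVector out_pair(n_rows), out_species(n_rows), out_death(n_rows),
      out_cause(n_rows);
  LogicalVector out_cens(n_rows);

  for (int p = 0; p < cohort_size; ++p) {
    Species A, B;
    init_species_params(A, params_A);
    Topology topoA_p, topoB_p;
    if (randomize_topology && A.n >= 2) {
      topoA_p = grow_topology(A.n, key_seed(master, p + 1, 1, PUR_TOPO));
      A.topo = &topoA_p;
    } else {
      A.topo = &topoA;
    }
    A.rng = Rng(key_seed(master, p + 1, 1, PUR_DYNAMICS));
    Rng prngA(key_seed(master, p + 1, 1, PUR_PRENATAL));
    apply_prenatal(A, prngA);

    if (has_B) {
      init_species_params(B, params_B);
      if (randomize_topology && B.n >= 2) {
        topoB_p = grow_topology(B.n, key_seed(master, p + 1, 2, PUR_TOPO));
        B.topo = &topoB_p;
      } else {
        B.topo = &topoB;
      }
      B.rng = Rng(key_seed(master, p + 1, 2, PUR_DYNAMICS));
      Rng prngB(key_seed(master, p + 1, 2, PUR_PRENATAL));
      apply_prenatal(B, prngB);
    }

    run_pair(A, has_B ? &B : 0, max_steps, winner_continues, p + 1,
             record_trajectories, buf, n_clipped);

    int row = p * (has_B ? 2 : 1);
    out_pair[row] = p + 1; out_species[row] = 1;
    out_death[row] = A.dead ? A.death_time : NA_INTEGER;
    out_cause[row] = A.dead ? (int)A.death_cause : NA_INTEGER;
    out_cens[row] = !A.dead;
    if (has_B) {
      out_pair[row + 1] = p + 1; out_species[row + 1] = 2;
      out_death[row + 1] = B.dead ? B.death_time : NA_INTEGER;
      out_cause[row + 1] = B.dead ? (int)B.death_cause : NA_INTEGER;
      out_cens[row + 1] = !B.dead;
    }
  }

  List traj = R_NilValue;
  if (record_trajectories) {
    traj = List::create(
        _["pair"] = IntegerVector(buf.pair.begin(), buf.pair.end()),
        _["species"] = IntegerVector(buf.species.begin(), buf.species.end()),
        _["t"] = IntegerVector(buf.t.begin(), buf.t.end()),
        _["f"] = IntegerVector(buf.f.begin(), buf.f.end()),
        _["ns"] = IntegerVector(buf.ns.begin(), buf.ns.end()),
        _["nc"] = IntegerVector(buf.nc.begin(), buf.nc.end()));
  }
  return List::create(
      _["pair"] = out_pair, _["species"] = out_species,
      _["death_time"] = out_death, _["death_cause"] = out_cause,
      _["censored"] = out_cens, _["trajectory"] = traj,
      _["n_alpha_clipped"] = n_clipped);
}

// One complete time step for an explicit pair state (A's two rounds, then
// B's using A's end-of-update functional fraction).  Exposed for unit-level
// inspection of the update rule.
// [[Rcpp::export(name = ".step_pair_cpp")]]
List step_pair_cpp(IntegerVector depA_ptr, IntegerVector depA_idx,
                   IntegerVector depB_ptr, IntegerVector depB_idx,
                   IntegerVector statusA, IntegerVector causeA,
                   IntegerVector statusB, IntegerVector causeB,
                   List params_A, List params_B, double seed_A, double seed_B) {
  Topology topoA, topoB;
  topoA.n = depA_ptr.size() - 1;
  topoA.ptr.assign(depA_ptr.begin(), depA_ptr.end());
  topoA.idx.assign(depA_idx.begin(), depA_idx.end());
  topoB.n = depB_ptr.size() - 1;
  topoB.ptr.assign(depB_ptr.begin(), depB_ptr.end());
  topoB.idx.assign(depB_idx.begin(), depB_idx.end());

  Species A, B;
  init_species_params(A, params_A);
  init_species_params(B, params_B);
  A.topo = &topoA; B.topo = &topoB;
  A.status.assign(statusA.begin(), statusA.end());
  A.cause.assign(causeA.begin(), causeA.end());
  B.status.assign(statusB.begin(), statusB.end());
  B.cause.assign(causeB.begin(), causeB.end());
  A.recount(); B.recount();
  A.rng = Rng((uint64_t)seed_A);
  B.rng = Rng((uint64_t)seed_B);
  A.dead = below_threshold(A);
  B.dead = below_threshold(B);

  int n_clipped = 0;
  if (!A.dead) {
    double f_opp = B.dead ? 0.0 : (double)B.f / (double)B.n;
    update_species(A, f_opp, n_clipped);
    if (below_threshold(A)) {
      A.dead = true;
      A.death_cause = (A.nc > A.ns) ? CAUSE_COAGEING : CAUSE_INTRINSIC;
    }
  }
  if (!B.dead) {
    double f_opp = A.dead ? 0.0 : (double)A.f / (double)A.n;
    update_species(B, f_opp, n_clipped);
    if (below_threshold(B)) {
      B.dead = true;
      B.death_cause = (B.nc > B.ns) ? CAUSE_COAGEING : CAUSE_INTRINSIC;
    }
  }
  return List::create(
      _["status_A"] = IntegerVector(A.status.begin(), A.status.end()),
      _["cause_A"] = IntegerVector(A.cause.begin(), A.cause.end()),
      _["status_B"] = IntegerVector(B.status.begin(), B.status.end()),
      _["cause_B"] = IntegerVector(B.cause.begin(), B.cause.end()),
      _["dead_A"] = A.dead, _["dead_B"] = B.dead,
      _["f_A"] = A.f, _["ns_A"] = A.ns, _["nc_A"] = A.nc,
      _["f_B"] = B.f, _["ns_B"] = B.ns, _["nc_B"] = B.nc,
      _["n_alpha_clipped"] = n_clipped);
}

// [[Rcpp::export(name = ".derive_seed_cpp")]]
double derive_seed_cpp(double master, double a, double b, double c) {
  // 31-bit result so derived seeds remain valid R integers
  return (double)(key_seed((uint64_t)master, (uint64_t)a, (uint64_t)b,
                           (uint64_t)c) >> 33);
}
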