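// Synchronous multi-valued logical-network engine.
//
// A compiled model (built by compile_model() on the R side) is a list of flat
// integer arrays describing N nodes, their level ranges and their complete
// truth tables:
//   n          number of nodes
//   max_level  integer[N], node i takes levels 0..max_level[i]
//   is_input   integer[N] 0/1; input nodes hold their value
//   reg_off    integer[N+1], offsets into reg_idx (0-based)
//   reg_idx    regulator node indices, concatenated per node,
//              first regulator is the most significant table digit
//   tab_off    integer[N+1], offsets into tab_val
//   tab_val    table outputs, row index = mixed-radix encoding of the
//              regulator levels (first regulator most significant)
//
// States are integer level vectors; the packed form is the mixed-radix
// integer over all nodes in declared order (node 1 most significant),
// held in a uint64 and returned to R as a double (state spaces are
// validated to stay below 2^53 so the double round-trips exactly).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

struct CModel {
  int n;
  std::vector<int> max_level, is_input, reg_off, reg_idx, tab_off, tab_val;
  std::vector<uint64_t> radix_mult; // pack multiplier per node
  double total_states;
};

static CModel as_cmodel(const List& m) {
  CModel cm;
  cm.n = as<int>(m["n"]);
  cm.max_level = as<std::vector<int>>(m["max_level"]);
  cm.is_input = as<std::vector<int>>(m["is_input"]);
  cm.reg_off = as<std::vector<int>>(m["reg_off"]);
  cm.reg_idx = as<std::vector<int>>(m["reg_idx"]);
  cm.tab_off = as<std::vector<int>>(m["tab_off"]);
  cm.tab_val = as<std::vector<int>>(m["tab_val"]);
  cm.radix_mult.assign(cm.n, 1);
  double tot = 1.0;
  uint64_t mult = 1;
  for (int i = cm.n - 1; i >= 0; --i) {
    cm.radix_mult[i] = mult;
    mult *= (uint64_t)(cm.max_level[i] + 1);
    tot *= (double)(cm.max_level[i] + 1);
  }
  cm.total_states = tot;
  if (tot > 9007199254740992.0) // 2^53: packed keys must be exact doubles
    stop("state space too large for exact packed-state arithmetic");
  return cm;
}

static inline uint64_t pack_state(const CModel& cm, const int* x) {
  uint64_t p = 0;
  for (int i = 0; i < cm.n; ++i) p += (uint64_t)x[i] * cm.radix_mult[i];
  return p;
}

static inline void unpack_state(const CModel& cm, uint64_t p, int* x) {
  for (int i = 0; i < cm.n; ++i) {
    x[i] = (int)(p / cm.radix_mult[i]);
    p -= (uint64_t)x[i] * cm.radix_mult[i];
  }
}

// one synchronous update; clamp overrides everything, inputs hold
static inline void step_into(const CModel& cm, const int* cur, int* nxt,
                             const int* clamp_node, const int* clamp_lev,
                             int n_clamp) {
  for (int i = 0; i < cm.n; ++i) {
    if (cm.is_input[i]) { nxt[i] = cur[i]; continue; }
    long idx = 0;
    for (int j = cm.reg_off[i]; j < cm.reg_off[i + 1]; ++j) {
      int r = cm.reg_idx[j];
      idx = idx * (cm.max_level[r] + 1) + cur[r];
    }
    nxt[i] = cm.tab_val[cm.tab_off[i] + idx];
  }
  for (int c = 0; c < n_clamp; ++c) nxt[clamp_node[c]] = clamp_lev[c];
}

struct TrajResult {
  int transient;
  std::vector<uint64_t> cycle; // rotated so the smallest packed state is first
};

// iterate until a state repeats; visited hash map gives the transient length
static TrajResult run_traj(const CModel& cm, const int* start,
                           const int* clamp_node, const int* clamp_lev,
                           int n_clamp, int max_steps) {
  std::vector<int> cur(start, start + cm.n), nxt(cm.n);
  std::unordered_map<uint64_t, int> seen;
  std::vector<uint64_t> traj;
  seen.reserve(64);
  uint64_t p = pack_state(cm, cur.data());
  seen[p] = 0;
  traj.push_back(p);
  for (int t = 1; t <= max_steps; ++t) {
    step_into(cm, cur.data(), nxt.data(), clamp_node, clamp_lev, n_clamp);
    cur.swap(nxt);
    p = pack_state(cm, cur.data());
    auto it = seen.find(p);
    if (it != seen.end()) {
      TrajResult res;
      res.transient = it->second;
      int len = t - it->second;
      res.cycle.assign(traj.begin() + it->second, traj.end());
      // canonical rotation: start at smallest packed state
      int arg = 0;
      for (int k = 1; k < len; ++k) if (res.cycle[k] < res.cycle[arg]) arg = k;
      std::rotate(res.cycle.begin(), res.cycle.begin() + arg, res.cycle.end());
      return res;
    }
    seen[p] = t;
    traj.push_back(p);
  }
  stop("transient too long: no state revisited within max_steps");
}

static void get_clamps(const IntegerVector& ci, const IntegerVector& cl,
                       std::vector<int>& node, std::vector<int>& lev) {
  node.assign(ci.begin(), ci.end());
  lev.assign(cl.begin(), cl.end());
  for (size_t k = 0; k < node.size(); ++k) node[k] -= 1; // R is 1-based
}

// [[Rcpp::export]]
IntegerVector cpp_step(List model, IntegerVector state,
                       IntegerVector clamp_node, IntegerVector clamp_lev) {
  CModel cm = as_cmodel(model);
  std::vector<int> cn, cl;
  get_clamps(clamp_node, clamp_lev, cn, cl);
  IntegerVector out(cm.n);
  std::vector<int> cur(state.begin(), state.end()), nxt(cm.n);
  step_into(cm, cur.data(), nxt.data(), cn.data(), cl.data(), (int)cn.size());
  for (int i = 0; i < cm.n; ++i) out[i] = nxt[i];
  return out;
}

// [[Rcpp::export]]
List cpp_run_to_attractor(List model, IntegerVector state,
                          IntegerVector clamp_node, IntegerVector clamp_lev,
                          int max_steps) {
  CModel cm = as_cmodel(model);
  std::vector<int> cn, cl;
  get_clamps(clamp_node, clamp_lev, cn, cl);
  std::vector<int> st(state.begin(), state.end());
  TrajResult r = run_traj(cm, st.data(), cn.data(), cl.data(),
                          (int)cn.size(), max_steps);
  int len = (int)r.cycle.size();
  IntegerMatrix cyc(len, cm.n);
  std::vector<int> x(cm.n);
  for (int k = 0; k < len; ++k) {
    unpack_state(cm, r.cycle[k], x.data());
    for (int i = 0; i < cm.n; ++i) cyc(k, i) = x[i];
  }
  return List::create(_["transient"] = r.transient,
                      _["length"] = len,
                      _["key"] = (double)r.cycle[0],
                      _["cycle"] = cyc);
}

// [[Rcpp::export]]
List cpp_trajectories(List model, IntegerMatrix states,
                      IntegerVector clamp_node, IntegerVector clamp_lev,
                      int max_steps) {
  CModel cm = as_cmodel(model);
  std::vector<int> cn, cl;
  get_clamps(clamp_node, clamp_lev, cn, cl);
  int n = states.nrow();
  NumericVector key(n);
  IntegerVector transient(n), length(n);
  std::vector<int> st(cm.n);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < cm.n; ++i) st[i] = states(s, i);
    TrajResult r = run_traj(cm, st.data(), cn.data(), cl.data(),
                            (int)cn.size(), max_steps);
    key[s] = (double)r.cycle[0];
    transient[s] = r.transient;
    length[s] = (int)r.cycle.size();
  }
  return List::create(_["key"] = key, _["transient"] = transient,
                      _["length"] = length);
}

static inline int draw_level(int n_levels) {
  int v = (int)(unif_rand() * n_levels);
  return v >= n_levels ? n_levels - 1 : v;
}

// [[Rcpp::export]]
IntegerMatrix cpp_sample_states(List model, IntegerVector fixed_levels, int n) {
  CModel cm = as_cmodel(model);
  IntegerMatrix out(n, cm.n);
  for (int s = 0; s < n; ++s)
    for (int i = 0; i < cm.n; ++i)
      out(s, i) = fixed_levels[i] >= 0 ? fixed_levels[i]
                                       : draw_level(cm.max_level[i] + 1);
  return out;
}

// Random-restart attractor discovery: draw states uniformly (fixed_levels
// entries >= 0 are held), run each to its attractor, stop after n_confirm
// consecutive samples yield nothing new.
// [[Rcpp::export]]
List cpp_discover(List model, IntegerVector fixed_levels,
                  IntegerVector clamp_node, IntegerVector clamp_lev,
                  double n_max, double n_confirm, int max_steps) {
  CModel cm = as_cmodel(model);
  std::vector<int> cn, cl;
  get_clamps(clamp_node, clamp_lev, cn, cl);
  std::unordered_map<uint64_t, int> found;
  std::vector<uint64_t> keys;
  std::vector<double> first_seen;
  std::vector<int> st(cm.n);
  double drawn = 0, since_new = 0;
  bool converged = false;
  while (drawn < n_max) {
    for (int i = 0; i < cm.n; ++i)
      st[i] = fixed_levels[i] >= 0 ? fixed_levels[i]
                                   : draw_level(cm.max_level[i] + 1);
    drawn += 1;
    TrajResult r = run_traj(cm, st.data(), cn.data(), cl.data(),
                            (int)cn.size(), max_steps);
    uint64_t k = r.cycle[0];
    if (found.find(k) == found.end()) {
      found[k] = (int)keys.size();
      keys.push_back(k);
      first_seen.push_back(drawn);
      since_new = 0;
    } else {
      since_new += 1;
      if (since_new >= n_confirm) { converged = true; break; }
    }
    if (((long)drawn & 0x3FF) == 0) checkUserInterrupt();
  }
  NumericVector kout(keys.size()), fs(first_seen.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kout[i] = (double)keys[i];
    fs[i] = first_seen[i];
  }
  return List::create(_["key"] = kout, _["first_seen"] = fs,
                      _["n_drawn"] = drawn, _["converged"] = converged);
}

// Exhaustive state-transition oracle: enumerate every state, follow
// successors with memoized labels (iterative walk, no recursion).
// [[Rcpp::export]]
List cpp_brute_force(List model, IntegerVector clamp_node,
                     IntegerVector clamp_lev, double budget) {
  CModel cm = as_cmodel(model);
  std::vector<int> cn, cl;
  get_clamps(clamp_node, clamp_lev, cn, cl);
  if (cm.total_states > budget)
    stop("state space (%.0f states) exceeds enumeration budget (%.0f)",
         cm.total_states, budget);
  uint64_t S = (uint64_t)cm.total_states;
  std::vector<uint32_t> succ(S);
  std::vector<int> cur(cm.n), nxt(cm.n);
  for (uint64_t s = 0; s < S; ++s) {
    unpack_state(cm, s, cur.data());
    step_into(cm, cur.data(), nxt.data(), cn.data(), cl.data(),
              (int)cn.size());
    succ[s] = (uint32_t)pack_state(cm, nxt.data());
  }
  std::vector<int32_t> label(S, -1);   // attractor index per state
  std::vector<int32_t> onpath(S, -1);  // position in current walk, else -1
  std::vector<uint64_t> attr_key;
  std::vector<int> attr_len;
  std::vector<uint64_t> path;
  for (uint64_t s0 = 0; s0 < S; ++s0) {
    if (label[s0] >= 0) continue;
    path.clear();
    uint64_t s = s0;
    while (label[s] < 0 && onpath[s] < 0) {
      onpath[s] = (int32_t)path.size();
      path.push_back(s);
      s = succ[s];
    }
    int32_t lab;
    if (label[s] >= 0) {
      lab = label[s]; // walked into a known basin
    } else {
      // new cycle: states from onpath[s] to end of path
      int start = onpath[s];
      uint64_t kmin = path[start];
      for (size_t k = start; k < path.size(); ++k)
        if (path[k] < kmin) kmin = path[k];
      lab = (int32_t)attr_key.size();
      attr_key.push_back(kmin);
      attr_len.push_back((int)(path.size() - start));
    }
    for (size_t k = 0; k < path.size(); ++k) {
      label[path[k]] = lab;
      onpath[path[k]] = -1;
    }
  }
  IntegerVector basin(S);
  for (uint64_t s = 0; s < S; ++s) basin[s] = label[s] + 1;
  NumericVector kout(attr_key.size());
  for (size_t i = 0; i < attr_key.size(); ++i) kout[i] = (double)attr_key[i];
  return List::create(_["key"] = kout,
                      _["length"] = IntegerVector(attr_len.begin(),
                                                  attr_len.end()),
                      _["basin"] = basin,
                      _["total_states"] = (double)S);
}

// successor of every state in packed order (for state-transition graphs)
// [[Rcpp::export]]
NumericVector cpp_successors(List model, IntegerVector clamp_node,
                             IntegerVector clamp_lev, double budget) {
  CModel cm = as_cmodel(model);
  std::vector<int> cn, cl;
  get_clamps(clamp_node, clamp_lev, cn, cl);
  if (cm.total_states > budget)
    stop("state space (%.0f states) exceeds enumeration budget (%.0f)",
         cm.total_states, budget);
  uint64_t S = (uint64_t)cm.total_states;
  NumericVector succ(S);
  std::vector<int> cur(cm.n), nxt(cm.n);
  for (uint64_t s = 0; s < S; ++s) {
    unpack_state(cm, s, cur.data());
    step_into(cm, cur.data(), nxt.data(), cn.data(), cl.data(),
              (int)cn.size());
    succ[s] = (double)pack_state(cm, nxt.data());
  }
  return succ;
}

// [[Rcpp::export]]
NumericVector cpp_pack(List model, IntegerMatrix states) {
  CModel cm = as_cmodel(model);
  NumericVector out(states.nrow());
  std::vector<int> x(cm.n);
  for (int s = 0; s < states.nrow(); ++s) {
    for (int i = 0; i < cm.n; ++i) x[i] = states(s, i);
    out[s] = (double)pack_state(cm, x.data());
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_unpack(List model, NumericVector keys) {
  CModel cm = as_cmodel(model);
  IntegerMatrix out(keys.size(), cm.n);
  std::vector<int> x(cm.n);
  for (int s = 0; s < keys.size(); ++s) {
    unpack_state(cm, (uint64_t)keys[s], x.data());
    for (int i = 0; i < cm.n; ++i) out(s, i) = x[i];
  }
  return out;
}
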