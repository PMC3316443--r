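// Reduced ordered binary decision diagrams with a hash-consed unique table.
// State sets are Boolean characteristic functions over the current-state
// variables; transition relations use twice as many variables (current and
// next bits interleaved, so renaming one block onto the other is monotone
// and never reorders nodes).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <functional>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int TERM_VAR = 0xFFFF; // variable id of the two terminal nodes

class BddMgr {
public:
  std::vector<int> var_, lo_, hi_;
  // exact packing: 16-bit var, 24-bit lo, 24-bit hi -> collision-free key
  std::unordered_map<uint64_t, int> unique_;
  std::unordered_map<uint64_t, int> memo_[3]; // AND, OR, XOR
  int nvars_;

  explicit BddMgr(int nvars) : nvars_(nvars) {
    var_ = {TERM_VAR, TERM_VAR};
    lo_ = {0, 1};
    hi_ = {0, 1};
  }

  static uint64_t pack(int v, int l, int h) {
    return (static_cast<uint64_t>(v) << 48) |
           (static_cast<uint64_t>(l) << 24) | static_cast<uint64_t>(h);
  }

  int mk(int v, int l, int h) {
    if (l == h) return l;
    uint64_t key = pack(v, l, h);
    auto it = unique_.find(key);
    if (it != unique_.end()) return it->second;
    if (var_.size() >= (1u << 24))
      stop("BDD node table overflow");
    int id = static_cast<int>(var_.size());
    var_.push_back(v);
    lo_.push_back(l);
    hi_.push_back(h);
    unique_.emplace(key, id);
    return id;
  }

  int apply(int op, int f, int g) {
    switch (op) {
    case 0: // and
      if (f == 0 || g == 0) return 0;
      if (f == 1) return g;
      if (g == 1) return f;
      if (f == g) return f;
      break;
    case 1: // or
      if (f == 1 || g == 1) return 1;
      if (f == 0) return g;
      if (g == 0) return f;
      if (f == g) return f;
      break;
    case 2: // xor
      if (f == g) return 0;
      if (f == 0) return g;
      if (g == 0) return f;
      break;
    }
    uint64_t key = (static_cast<uint64_t>(f) << 32) | static_cast<uint64_t>(g);
    auto &memo = memo_[op];
    auto it = memo.find(key);
    if (it != memo.end()) return it->second;
    int vf = var_[f], vg = var_[g];
    int v = vf < vg ? vf : vg;
    int fl = vf == v ? lo_[f] : f, fh = vf == v ? hi_[f] : f;
    int gl = vg == v ? lo_[g] : g, gh = vg == v ? hi_[g] : g;
    int r = mk(v, apply(op, fl, gl), apply(op, fh, gh));
    memo.emplace(key, r);
    return r;
  }

  int bnot(int f) { return apply(2, f, 1); }

  int exists(int f, const std::vector<char> &mask,
             std::unordered_map<int, int> &memo) {
    if (f <= 1) return f;
    auto it = memo.find(f);
    if (it != memo.end()) return it->second;
    int v = var_[f];
    int l = exists(lo_[f], mask, memo);
    int h = exists(hi_[f], mask, memo);
    int r = mask[v] ? apply(1, l, h) : mk(v, l, h);
    memo.emplace(f, r);
    return r;
  }

  // rename via a variable map that must preserve the global order
  int rename(int f, const std::vector<int> &map,
             std::unordered_map<int, int> &memo) {
    if (f <= 1) return f;
    auto it = memo.find(f);
    if (it != memo.end()) return it->second;
    int r = mk(map[var_[f]], rename(lo_[f], map, memo),
               rename(hi_[f], map, memo));
    memo.emplace(f, r);
    return r;
  }
};

static BddMgr *get(SEXP m) { return Rcpp::XPtr<BddMgr>(m).get(); }

// [[Rcpp::export]]
SEXP bdd_mgr_new(int nvars) {
  Rcpp::XPtr<BddMgr> p(new BddMgr(nvars), true);
  return p;
}

// [[Rcpp::export]]
int bdd_var_node(SEXP m, int v) {
  BddMgr *mgr = get(m);
  if (v < 0 || v >= mgr->nvars_) stop("variable index out of range");
  return mgr->mk(v, 0, 1);
}

// [[Rcpp::export]]
int bdd_not(SEXP m, int f) { return get(m)->bnot(f); }

// [[Rcpp::export]]
int bdd_and(SEXP m, int f, int g) { return get(m)->apply(0, f, g); }

// [[Rcpp::export]]
int bdd_or(SEXP m, int f, int g) { return get(m)->apply(1, f, g); }

// [[Rcpp::export]]
int bdd_xor(SEXP m, int f, int g) { return get(m)->apply(2, f, g); }

// [[Rcpp::export]]
int bdd_exists(SEXP m, int f, IntegerVector vars) {
  BddMgr *mgr = get(m);
  std::vector<char> mask(mgr->nvars_, 0);
  for (int v : vars) mask[v] = 1;
  std::unordered_map<int, int> memo;
  return mgr->exists(f, mask, memo);
}

// [[Rcpp::export]]
int bdd_rename(SEXP m, int f, IntegerVector from, IntegerVector to) {
  BddMgr *mgr = get(m);
  std::vector<int> map(mgr->nvars_);
  for (int i = 0; i < mgr->nvars_; ++i) map[i] = i;
  for (int i = 0; i < from.size(); ++i) map[from[i]] = to[i];
  std::unordered_map<int, int> memo;
  return mgr->rename(f, map, memo);
}

// number of satisfying assignments of f over exactly the given variables
// (ascending var ids; the support of f must be a subset)
// [[Rcpp::export]]
double bdd_satcount(SEXP m, int f, IntegerVector vars) {
  BddMgr *mgr = get(m);
  int L = vars.size();
  std::vector<int> pos(mgr->nvars_, -1);
  for (int i = 0; i < L; ++i) pos[vars[i]] = i;
  // sc(f, i): count over positions i..L-1
  std::unordered_map<int, double> memo; // f -> sc(f, pos(var(f)))
  std::function<double(int, int)> sc = [&](int f, int i) -> double {
    if (f == 0) return 0.0;
    if (f == 1) return std::ldexp(1.0, L - i);
    int j = pos[mgr->var_[f]];
    if (j < 0) stop("BDD support outside counting variables");
    double t;
    auto it = memo.find(f);
    if (it != memo.end()) {
      t = it->second;
    } else {
      t = sc(mgr->lo_[f], j + 1) + sc(mgr->hi_[f], j + 1);
      memo.emplace(f, t);
    }
    return std::ldexp(t, j - i);
  };
  return sc(f, 0);
}

// enumerate satisfying state indices (vars[0] is the most significant bit);
// stops after cap states when cap >= 0
// [[Rcpp::export]]
NumericVector bdd_sat_states(SEXP m, int f, IntegerVector vars, double cap) {
  BddMgr *mgr = get(m);
  int L = vars.size();
  std::vector<int> pos(mgr->nvars_, -1);
  for (int i = 0; i < L; ++i) pos[vars[i]] = i;
  std::vector<double> out;
  bool truncated = false;
  std::function<void(int, int, double)> walk = [&](int f, int i, double acc) {
    if (truncated || f == 0) return;
    if (cap >= 0 && static_cast<double>(out.size()) >= cap) {
      truncated = true;
      return;
    }
    if (i == L) {
      out.push_back(acc);
      return;
    }
    double bitval = std::ldexp(1.0, L - 1 - i);
    int j = (f <= 1) ? L : pos[mgr->var_[f]];
    if (j > i) { // variable at position i unconstrained
      walk(f, i + 1, acc);
      walk(f, i + 1, acc + bitval);
    } else {
      walk(mgr->lo_[f], i + 1, acc);
      walk(mgr->hi_[f], i + 1, acc + bitval);
    }
  };
  walk(f, 0, 0.0);
  NumericVector res(out.begin(), out.end());
  res.attr("truncated") = truncated;
  return res;
}

// enumerate a relation's (source, target) index pairs
// [[Rcpp::export]]
NumericMatrix bdd_sat_pairs(SEXP m, int f, IntegerVector cur_vars,
                            IntegerVector nxt_vars, double cap) {
  BddMgr *mgr = get(m);
  int n = cur_vars.size();
  int L = 2 * n;
  // merged descending-order walk over both blocks
  std::vector<int> vlist(L);
  std::vector<int> block(L), bit(L);
  {
    std::vector<std::pair<int, std::pair<int, int>>> tmp;
    for (int i = 0; i < n; ++i) {
      tmp.push_back({cur_vars[i], {0, i}});
      tmp.push_back({nxt_vars[i], {1, i}});
    }
    std::sort(tmp.begin(), tmp.end());
    for (int i = 0; i < L; ++i) {
      vlist[i] = tmp[i].first;
      block[i] = tmp[i].second.first;
      bit[i] = tmp[i].second.second;
    }
  }
  std::vector<int> pos(mgr->nvars_, -1);
  for (int i = 0; i < L; ++i) pos[vlist[i]] = i;
  std::vector<double> src, dst;
  bool truncated = false;
  std::function<void(int, int, double, double)> walk =
      [&](int f, int i, double s, double t) {
        if (truncated || f == 0) return;
        if (cap >= 0 && static_cast<double>(src.size()) >= cap) {
          truncated = true;
          return;
        }
        if (i == L) {
          src.push_back(s);
          dst.push_back(t);
          return;
        }
        double bv = std::ldexp(1.0, n - 1 - bit[i]);
        double s1 = block[i] == 0 ? s + bv : s;
        double t1 = block[i] == 1 ? t + bv : t;
        int j = (f <= 1) ? L : pos[mgr->var_[f]];
        if (j > i) {
          walk(f, i + 1, s, t);
          walk(f, i + 1, s1, t1);
        } else {
          walk(mgr->lo_[f], i + 1, s, t);
          walk(mgr->hi_[f], i + 1, s1, t1);
        }
      };
  walk(f, 0, 0.0, 0.0);
  NumericMatrix res(src.size(), 2);
  for (size_t i = 0; i < src.size(); ++i) {
    res(i, 0) = src[i];
    res(i, 1) = dst[i];
  }
  res.attr("truncated") = truncated;
  return res;
}

// [[Rcpp::export]]
bool bdd_contains_state(SEXP m, int f, IntegerVector vars, double index) {
  BddMgr *mgr = get(m);
  int L = vars.size();
  std::vector<int> pos(mgr->nvars_, -1);
  for (int i = 0; i < L; ++i) pos[vars[i]] = i;
  uint64_t idx = static_cast<uint64_t>(index);
  while (f > 1) {
    int j = pos[mgr->var_[f]];
    if (j < 0) stop("BDD support outside state variables");
    bool b = (idx >> (L - 1 - j)) & 1u;
    f = b ? mgr->hi_[f] : mgr->lo_[f];
  }
  return f == 1;
}

// conjunction of literals selecting exactly one assignment of vars
// [[Rcpp::export]]
int bdd_cube(SEXP m, IntegerVector vars, double index) {
  BddMgr *mgr = get(m);
  int L = vars.size();
  int node = 1;
  uint64_t idx = static_cast<uint64_t>(index);
  for (int i = L - 1; i >= 0; --i) {
    bool b = (idx >> (L - 1 - i)) & 1u;
    node = b ? mgr->mk(vars[i], 0, node) : mgr->mk(vars[i], node, 0);
  }
  return node;
}

// [[Rcpp::export]]
int bdd_from_states(SEXP m, IntegerVector vars, NumericVector indices) {
  BddMgr *mgr = get(m);
  int acc = 0;
  for (double idx : indices) acc = mgr->apply(1, acc, bdd_cube(m, vars, idx));
  return acc;
}

// [[Rcpp::export]]
int bdd_node_count(SEXP m) {
  return static_cast<int>(get(m)->var_.size());
}
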