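#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <climits>
#include <cmath>
using namespace Rcpp;

// Core kernels for copy-number profile (CNP) distances. Profiles are vectors
// of non-negative integers with implicit zero sentinels at positions 0 and
// n+1. All kernels assume validated input (non-negative integers); the R
// wrappers enforce the contracts.

typedef std::vector<int> ivec;

// ---------------------------------------------------------------------------
// null-position reduction (shared nulls, Lemma 4, Lemma 5)
// rule codes: 1 shared null, 2 Lemma 4, 3 Lemma 5, 4 source null dropped
// ---------------------------------------------------------------------------

static void reduce_core(ivec &u, ivec &v, bool drop_source,
                        ivec *pos_log, ivec *rule_log) {
  int n = (int)u.size();
  ivec idx(n);
  for (int i = 0; i < n; i++) idx[i] = i + 1;

  auto erase_at = [&](int i, int rule) {
    if (pos_log) { pos_log->push_back(idx[i]); rule_log->push_back(rule); }
    u.erase(u.begin() + i);
    v.erase(v.begin() + i);
    idx.erase(idx.begin() + i);
  };

  bool changed = true;
  while (changed) {
    changed = false;
    int m = (int)u.size();
    // nulls of the source profile
    for (int i = 0; i < m; i++) {
      if (u[i] == 0) {
        if (v[i] == 0) { erase_at(i, 1); changed = true; break; }
        if (drop_source) { erase_at(i, 4); changed = true; break; }
        stop("untransformable pair: source has a null where the target is positive");
      }
    }
    if (changed) continue;
    // Lemma 4: consecutive target nulls, drop the position smaller in u
    for (int i = 0; i + 1 < m; i++) {
      if (v[i] == 0 && v[i + 1] == 0) {
        int rm = (u[i] >= u[i + 1]) ? i + 1 : i;
        erase_at(rm, 2); changed = true; break;
      }
    }
    if (changed) continue;
    // Lemma 5: target null not sandwiched by strictly smaller w neighbours
    for (int i = 0; i < m; i++) {
      if (v[i] == 0) {
        int wi = u[i] - v[i];
        int wl = (i > 0) ? u[i - 1] - v[i - 1] : 0;
        int wr = (i + 1 < m) ? u[i + 1] - v[i + 1] : 0;
        if (wl >= wi || wr >= wi) { erase_at(i, 3); changed = true; break; }
      }
    }
  }
}

// [[Rcpp::export]]
List reduce_pair_cpp(IntegerVector u0, IntegerVector v0, bool drop_source_nulls) {
  ivec u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  ivec pos, rule;
  reduce_core(u, v, drop_source_nulls, &pos, &rule);
  return List::create(_["u"] = wrap(u), _["v"] = wrap(v),
                      _["positions"] = wrap(pos), _["rules"] = wrap(rule));
}

// ---------------------------------------------------------------------------
// flat intervals
// ---------------------------------------------------------------------------

// number of maximal flat intervals of w including the zero sentinels
static int flat_count(const ivec &u, const ivec &v) {
  int cnt = 1, prev = 0;
  for (size_t i = 0; i < u.size(); i++) {
    int x = u[i] - v[i];
    if (x != prev) { cnt++; prev = x; }
  }
  if (prev != 0) cnt++;
  return cnt;
}

// ---------------------------------------------------------------------------
// merge-event search for the greedy heuristic
// ---------------------------------------------------------------------------

// sparse table for range maximum over a fixed array (0-based, inclusive)
struct SparseMax {
  int n;
  std::vector<ivec> t;
  void build(const ivec &a) {
    n = (int)a.size();
    int K = 1;
    while ((1 << K) <= n) K++;
    t.assign(K, a);
    for (int k = 1; k < K; k++)
      for (int i = 0; i + (1 << k) <= n; i++)
        t[k][i] = std::max(t[k - 1][i], t[k - 1][i + (1 << (k - 1))]);
  }
  int query(int l, int r) const {
    int k = 0;
    while ((1 << (k + 1)) <= r - l + 1) k++;
    return std::max(t[k][l], t[k][r - (1 << k) + 1]);
  }
};

// An event (i, j, delta) merges the flat intervals adjacent to [i, j] (and so
// reduces |F_w| by 2) precisely when w_{i-1} - w_i = w_{j+1} - w_j = delta.
// Validity: no frozen zero of u inside [i, j]; positions with v_p > 0 must
// stay strictly positive; positions with v_p = 0 must not be pushed below 0
// (reaching exactly 0 is their target and is allowed).
// Tie-break: smallest i, then smallest j. Returns true and fills (ei, ej, ed).
static bool find_merge(const ivec &u, const ivec &v, int &ei, int &ej, int &ed) {
  int n = (int)u.size();
  if (n == 0) return false;
  ivec w(n);
  for (int p = 0; p < n; p++) w[p] = u[p] - v[p];
  auto W = [&](int p) -> int { return (p >= 1 && p <= n) ? w[p - 1] : 0; };

  const int BIG = INT_MAX / 4;
  ivec C(n);  // minimal admissible delta per position (BIG = never admissible)
  for (int p = 0; p < n; p++)
    C[p] = (u[p] == 0) ? BIG : ((v[p] > 0) ? 1 - u[p] : -u[p]);
  SparseMax sm;
  sm.build(C);

  // right boundaries grouped by their difference
  std::unordered_map<int, ivec> ends;
  for (int j = 1; j <= n; j++) {
    int dR = W(j + 1) - W(j);
    if (dR != 0) ends[dR].push_back(j);
  }
  for (int i = 1; i <= n; i++) {
    int dL = W(i - 1) - W(i);
    if (dL == 0) continue;
    std::unordered_map<int, ivec>::const_iterator it = ends.find(dL);
    if (it == ends.end()) continue;
    const ivec &js = it->second;
    ivec::const_iterator lo = std::lower_bound(js.begin(), js.end(), i);
    for (; lo != js.end(); ++lo) {
      int j = *lo;
      if (dL >= sm.query(i - 1, j - 1)) { ei = i; ej = j; ed = dL; return true; }
    }
  }
  return false;
}

// [[Rcpp::export]]
IntegerVector merge_event_cpp(IntegerVector u0, IntegerVector v0) {
  ivec u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  int i, j, d;
  if (find_merge(u, v, i, j, d))
    return IntegerVector::create(i, j, d);
  return IntegerVector(0);
}

static void apply_ev(ivec &u, int s, int t, int d) {
  for (int p = s - 1; p < t; p++)
    if (u[p] > 0) { u[p] += d; if (u[p] < 0) u[p] = 0; }
}

// ---------------------------------------------------------------------------
// greedy improved approximation
// ---------------------------------------------------------------------------

// assumes a reduced, transformable pair
static int heuristic_core(ivec u, const ivec &v, std::vector<ivec> *events) {
  int n = (int)u.size();
  if (n == 0) return 0;
  int guard = flat_count(u, v) + 5;
  int cost = 0;
  for (;;) {
    bool same = true;
    for (int p = 0; p < n; p++) if (u[p] != v[p]) { same = false; break; }
    if (same) break;
    if (--guard < 0)
      stop("internal error: greedy failed to terminate (inputs not reduced?)");
    int i, j, d;
    if (!find_merge(u, v, i, j, d)) {
      // leftmost non-extreme flat interval with a nonzero value
      int a = -1;
      for (int p = 0; p < n; p++) if (u[p] != v[p]) { a = p + 1; break; }
      int wa = u[a - 1] - v[a - 1];
      int b = a;
      while (b < n && u[b] - v[b] == wa) b++;
      i = a; j = b; d = -wa;
    }
    apply_ev(u, i, j, d);
    cost++;
    if (events) { ivec e; e.push_back(i); e.push_back(j); e.push_back(d); events->push_back(e); }
  }
  return cost;
}

// [[Rcpp::export]]
List heuristic_cpp(IntegerVector u0, IntegerVector v0, bool record_events) {
  ivec u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<ivec> evs;
  int cost = heuristic_core(u, v, record_events ? &evs : (std::vector<ivec> *)0);
  IntegerMatrix em((int)evs.size(), 3);
  for (int k = 0; k < (int)evs.size(); k++)
    for (int c = 0; c < 3; c++) em(k, c) = evs[k][c];
  return List::create(_["cost"] = cost, _["events"] = em);
}

// ---------------------------------------------------------------------------
// unit-event (MEDICC model) distance
// ---------------------------------------------------------------------------
//
// With events restricted to delta = +/-1, any optimal solution can be
// normalized to all deletions first, then all amplifications. Writing d_i
// (a_i) for the number of deletion (amplification) events covering position
// i, the number of events equals the number of "rises"
//   sum_i max(d_i - d_{i-1}, 0) + sum_i max(a_i - a_{i-1}, 0)  (d_0 = a_0 = 0)
// and feasibility requires, with w_i = u_i - v_i:
//   v_i > 0 : d_i in [max(0, w_i), u_i - 1], a_i = d_i - w_i;
//   v_i = 0 : d_i >= u_i, a_i free (amplifications pass over a dead zero).
// The free a_i at target nulls never pay (set to the min of their
// neighbours), so the amplification skyline is taken over positions with
// v_i > 0 only. The minimum over d is found by a chain DP over those
// positions; an isolated target null m between states a (left) and b (right)
// contributes max(u_m - max(a, b), 0) deletion rises, obtained in closed
// form from the optimal d_m >= u_m.

static const double DINF = 1e18;

static double zzs_core(const ivec &u, const ivec &v, bool fast_path) {
  int n = (int)u.size();
  if (n == 0) return 0.0;
  bool hasnull = false;
  for (int p = 0; p < n; p++) {
    if (u[p] == 0) {
      if (v[p] > 0) stop("untransformable pair: source null with positive target");
      stop("unit-event distance needs reduced input (shared null present)");
    }
    if (v[p] == 0) hasnull = true;
  }
  if (!hasnull && fast_path) {
    // zero-free closed form: rises of the positive and negative parts of w
    double d = 0.0;
    int pp = 0, pq = 0;
    for (int i = 0; i < n; i++) {
      int w = u[i] - v[i];
      int p = w > 0 ? w : 0, q = w < 0 ? -w : 0;
      if (p > pp) d += p - pp;
      if (q > pq) d += q - pq;
      pp = p; pq = q;
    }
    return d;
  }
  for (int p = 0; p + 1 < n; p++)
    if (v[p] == 0 && v[p + 1] == 0)
      stop("unit-event distance needs reduced input (consecutive target nulls)");

  ivec chain;  // indices with v > 0
  for (int p = 0; p < n; p++) if (v[p] > 0) chain.push_back(p);
  if (chain.empty()) {
    // all target-null; adjacency check implies n == 1
    return (double)u[0];
  }

  int nc = (int)chain.size();
  std::vector<double> dp;
  ivec lo(nc), hi(nc);
  for (int c = 0; c < nc; c++) {
    int p = chain[c], w = u[p] - v[p];
    lo[c] = w > 0 ? w : 0;
    hi[c] = u[p] - 1;
  }

  // first chain element, possibly bridged over a leading target null
  {
    int p = chain[0], w = u[p] - v[p];
    int lead = (p > 0) ? u[p - 1] : -1;  // p > 0 implies p == 1 (isolated null)
    dp.assign(hi[0] - lo[0] + 1, 0.0);
    for (int b = lo[0]; b <= hi[0]; b++) {
      double c = (double)b + std::max(b - w, 0);  // delta rise + eta rise from 0
      if (lead >= 0) c += std::max(lead - std::max(0, b), 0);
      dp[b - lo[0]] = c;
    }
  }

  for (int c = 1; c < nc; c++) {
    int p = chain[c], pprev = chain[c - 1];
    int w = u[p] - v[p], wprev = u[pprev] - v[pprev];
    int mid = (p - pprev == 2) ? u[p - 1] : -1;  // isolated null in between
    std::vector<double> nxt(hi[c] - lo[c] + 1, DINF);
    for (int b = lo[c]; b <= hi[c]; b++) {
      int etab = b - w;
      double best = DINF;
      for (int a = lo[c - 1]; a <= hi[c - 1]; a++) {
        double t = dp[a - lo[c - 1]];
        if (b > a) t += b - a;
        int etaa = a - wprev;
        if (etab > etaa) t += etab - etaa;
        if (mid >= 0) t += std::max(mid - std::max(a, b), 0);
        if (t < best) best = t;
      }
      nxt[b - lo[c]] = best;
    }
    dp.swap(nxt);
  }

  // trailing target null after the last chain element
  int plast = chain[nc - 1];
  int trail = (plast < n - 1) ? u[n - 1] : -1;  // isolated null at position n
  double ans = DINF;
  for (int a = lo[nc - 1]; a <= hi[nc - 1]; a++) {
    double t = dp[a - lo[nc - 1]];
    if (trail >= 0) t += std::max(trail - a, 0);
    if (t < ans) ans = t;
  }
  return ans;
}

// [[Rcpp::export]]
double zzs_cpp(IntegerVector u0, IntegerVector v0, bool fast_path) {
  ivec u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  return zzs_core(u, v, fast_path);
}

// ---------------------------------------------------------------------------
// symmetrized pairwise distance matrix
// methods: 1 = flat interval count, 2 = greedy heuristic, 3 = unit-event
// ---------------------------------------------------------------------------

static double dir_dist(ivec x, ivec y, int method) {
  reduce_core(x, y, true, 0, 0);
  int n = (int)x.size();
  if (n == 0) return 0.0;
  bool same = true;
  for (int p = 0; p < n; p++) if (x[p] != y[p]) { same = false; break; }
  if (same) return 0.0;
  switch (method) {
  case 1: { int f = flat_count(x, y) - 2; return f > 0 ? (double)f : 0.0; }
  case 2: return (double)heuristic_core(x, y, 0);
  case 3: return zzs_core(x, y, true);
  }
  stop("unknown method code");
  return 0.0;  // not reached
}

static double sym_pair(const ivec &x, const ivec &y, int method) {
  int n = (int)x.size();
  bool und1 = false, und2 = false;
  for (int p = 0; p < n; p++) {
    if (x[p] == 0 && y[p] > 0) und1 = true;
    if (y[p] == 0 && x[p] > 0) und2 = true;
  }
  if (und1 && und2) {
    // both directions undefined: fall back to dropping one-sided nulls
    ivec xx, yy;
    for (int p = 0; p < n; p++)
      if ((x[p] == 0) == (y[p] == 0)) { xx.push_back(x[p]); yy.push_back(y[p]); }
    return std::min(dir_dist(xx, yy, method), dir_dist(yy, xx, method));
  }
  double best = DINF;
  if (!und1) best = std::min(best, dir_dist(x, y, method));
  if (!und2) best = std::min(best, dir_dist(y, x, method));
  return best;
}

// [[Rcpp::export]]
NumericMatrix pairwise_cpp(IntegerMatrix profiles, int method) {
  int l = profiles.nrow(), n = profiles.ncol();
  NumericMatrix D(l, l);
  std::vector<ivec> rows(l, ivec(n));
  for (int i = 0; i < l; i++)
    for (int p = 0; p < n; p++) rows[i][p] = profiles(i, p);
  for (int i = 0; i < l; i++)
    for (int j = i + 1; j < l; j++) {
      double d = sym_pair(rows[i], rows[j], method);
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}

// [[Rcpp::export]]
double sym_pair_cpp(IntegerVector x0, IntegerVector y0, int method) {
  ivec x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  return sym_pair(x, y, method);
}
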