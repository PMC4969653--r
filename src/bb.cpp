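// Branch-and-bound search for the minimum-ESS0 monotone adaptive two-stage
// design at fixed (n1, n).
//
// Design space: one decision per first-stage response count s = 0..n1 --
// stop for futility (conditional rejection probability 0), stop for
// efficacy (probability 1), or continue with n2(s) patients and reject at
// the end iff the total response count exceeds r(s); the conditional
// error of a continuation is 1 - pbinom(r(s) - s, n2(s), p).  Futility
// stops form a prefix (s = 0 always stops), efficacy stops a suffix, and
// n2(s) is non-increasing over the continuation region.  With exact_mss
// the first continuation takes n2 = n - n1, so the maximum sample size is
// exactly n.
//
// Search organisation.  ESS0 depends on the schedule only through the
// n2-sequence, so the search branches depth-first over s on the stage-2
// *size* decision (futility / efficacy suffix / n2 = 1..limit) and defers
// the critical values: once a complete size sequence survives the bounds,
// an exact inner solve picks critical values r(s) satisfying the alpha
// and power constraints (any assignment yields the same ESS0).  Bounds at
// a size-level node:
//   (a) the minimal attainable type I mass of the decided states already
//       exceeds alpha;
//   (b) the exact partial ESS0, with undecided s contributing n1 only,
//       meets the incumbent (exact in size space: decided states pay
//       their full expected cost immediately);
//   (c) a linear-programming relaxation of "power >= target subject to
//       type I <= alpha": each decided continuation contributes the
//       concave frontier of its fixed-n2 conditional-error points (the
//       segment slopes are binomial likelihood ratios, so the staircase
//       is concave), each undecided s contributes the upper concave
//       envelope of all candidates with n2 <= limit plus both stops.
//       The relaxation ignores monotonicity and the prefix/suffix
//       structure, so it is conservative.  Decided frontiers live in a
//       Fenwick-indexed global segment pool updated as the search moves;
//       undecided suffixes are precomputed cumulative knapsack tables;
//       a bound query merges the two by a binary search on the
//       power-per-alpha ratio threshold.
// All bounds are conservative: the returned optimum equals exhaustive
// enumeration; the bounds only affect runtime.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
#include <cmath>

using namespace Rcpp;

namespace {

const double CTOL = 1e-12;  // conservative feasibility slack
const double TTOL = 1e-9;   // objective tie tolerance (first found wins)

struct Fenwick {
  int n = 0;
  std::vector<double> c, g;
  void init(int n_) { n = n_; c.assign(n + 1, 0.0); g.assign(n + 1, 0.0); }
  void add(int i, double cost, double gain) {
    for (++i; i <= n; i += i & -i) { c[i] += cost; g[i] += gain; }
  }
  void prefix(int i, double& cost, double& gain) const {  // ranks 0..i
    cost = 0; gain = 0;
    for (++i; i > 0; i -= i & -i) { cost += c[i]; gain += g[i]; }
  }
};

struct Engine {
  int n1, n, n2max;
  double alpha, beta, p0, p1;
  bool exact_mss;

  std::vector<double> b0, ba, B0tail, Batail;
  std::vector<double> ce0min;          // p0^k: smallest conditional error
  std::vector<double> ce0max;          // 1-(1-p0)^k: largest
  // fixed-n2 frontier vertices per k (origin + points j = k-1..0,
  // ascending x), flat storage
  std::vector<double> fx, fy;
  std::vector<int> foff;
  // undecided-suffix knapsack tables, one block per n2 limit L
  std::vector<std::vector<double>> lp_cost, lp_gain, lp_ratio;
  std::vector<std::vector<int>> lp_off;
  // global decided-segment universe: one segment per (state t, k, i)
  std::vector<int> seg_rank;
  std::vector<double> rank_ratio;
  std::vector<double> seg_cost, seg_gain, seg_ratio;
  std::vector<int> seg_off;            // block (t, k) at t * (n2max + 1) + k
  Fenwick fen;

  // Lagrangian fast bound: a small multiplier grid; per-multiplier
  // suffix sums and per-(state, k) decided-frontier duals, with the
  // decided part maintained as running scalars along the search path
  std::vector<double> lam;                       // multiplier grid
  std::vector<std::vector<double>> Gsuf;         // [li][L * (n1 + 2) + s]
  std::vector<std::vector<double>> gfix;         // [li][t * (n2max + 1) + k]
  std::vector<double> poolDual;                  // running per multiplier
  std::vector<double> pwMaxFix;                  // (1-(1-p1)^k) per k

  double best;                 // incumbent ESS0
  double ess_lower = R_NegInf; // proven bound: no feasible design below it
  double max_nodes = R_PosInf; // exploration cap (diagnostics only)
  bool aborted = false;
  bool found = false;
  std::vector<int> curKind, curN2;     // 0 fut, 1 cont, 2 eff
  std::vector<int> bestKind, bestN2, bestJ;
  std::vector<int> contS, contK;       // decided continuation states
  double bestAlpha = 0, bestPower = 0;
  double nodes = 0, dfsNodes = 0, innNodes = 0, pushes = 0, prA = 0,
         prF = 0, prLP = 0, prLam = 0, solves = 0, ties = 0;

  // ---------------------------------------------------------------- init
  void init(bool light = false) {
    n2max = n - n1;
    b0.resize(n1 + 1); ba.resize(n1 + 1);
    for (int s = 0; s <= n1; ++s) {
      b0[s] = R::dbinom(s, n1, p0, 0);
      ba[s] = R::dbinom(s, n1, p1, 0);
    }
    B0tail.assign(n1 + 2, 0.0); Batail.assign(n1 + 2, 0.0);
    for (int s = n1; s >= 0; --s) {
      B0tail[s] = B0tail[s + 1] + b0[s];
      Batail[s] = Batail[s + 1] + ba[s];
    }
    ce0min.assign(n2max + 1, 0.0);
    ce0max.assign(n2max + 1, 0.0);
    pwMaxFix.assign(n2max + 1, 0.0);
    for (int k = 1; k <= n2max; ++k) {
      ce0min[k] = std::pow(p0, k);
      ce0max[k] = 1.0 - std::pow(1.0 - p0, k);
      pwMaxFix[k] = 1.0 - std::pow(1.0 - p1, k);
    }
    build_frontiers();
    if (!light) {
      build_suffix_tables();
      build_universe();
      build_lambda_tables();
    } else {
      build_universe();
    }
    innC.assign(1, {}); innG.assign(1, {}); innR.assign(1, {});
    minApre.assign(1, 0.0);
    curKind.assign(n1 + 1, 2); curN2.assign(n1 + 1, 0);
  }

  // joint (alpha, objective-budget) dual grid: pairs (lambda, mu) with
  // lambda pricing type I mass and mu pricing expected stage-2 cost
  std::vector<double> lamG, muG;                 // per grid point
  std::vector<std::vector<double>> Gsuf3;        // [gi][L * (n1 + 2) + s]

  // multiplier grid seeded by the marginal power-per-alpha ratio of the
  // whole-problem LP relaxation
  void build_lambda_tables() {
    double lamStar = 1.0;
    lp_bound(1, n2max, alpha + CTOL, &lamStar);
    if (!(lamStar > 0) || !std::isfinite(lamStar)) lamStar = 1.0;
    lam = {0.0, 0.25 * lamStar, lamStar, 4.0 * lamStar};
    int nl = (int)lam.size();
    Gsuf.assign(nl, std::vector<double>((n2max + 1) * (n1 + 2), 0.0));
    gfix.assign(nl, std::vector<double>((n1 + 1) * (n2max + 1), 0.0));
    poolDual.assign(nl, 0.0);
    std::vector<double> hx, hy;
    for (int L = 0; L <= n2max; ++L) {
      hull(L, hx, hy);
      for (int li = 0; li < nl; ++li) {
        std::vector<double>& g = Gsuf[li];
        double l = lam[li];
        for (int s = n1; s >= 1; --s) {
          double mx = 0.0;
          for (size_t i = 0; i < hx.size(); ++i) {
            double v = ba[s] * hy[i] - l * b0[s] * hx[i];
            if (v > mx) mx = v;
          }
          g[L * (n1 + 2) + s] = g[L * (n1 + 2) + s + 1] + mx;
        }
        g[L * (n1 + 2)] = g[L * (n1 + 2) + 1];
      }
    }
    for (int li = 0; li < nl; ++li) {
      double l = lam[li];
      for (int t = 1; t <= n1; ++t)
        for (int k = 1; k <= n2max; ++k) {
          int o = foff[k];
          double mx = 0.0;
          for (int i = 0; i <= k; ++i) {
            double v = ba[t] * fy[o + i] - l * b0[t] * fx[o + i];
            if (v > mx) mx = v;
          }
          gfix[li][t * (n2max + 1) + k] = mx;
        }
    }
    // (lambda, mu) grid: mu scaled by power demand per unit of the
    // whole-problem objective slack
    double muStar = 0.1;
    if (std::isfinite(best) && best - n1 > 1e-6)
      muStar = (1 - beta) / (best - n1);
    lamG.clear(); muG.clear();
    for (double l : {0.0, lamStar, 4.0 * lamStar})
      for (double m : {0.25 * muStar, muStar, 4.0 * muStar}) {
        lamG.push_back(l); muG.push_back(m);
      }
    int ng = (int)lamG.size();
    Gsuf3.assign(ng, std::vector<double>((n2max + 1) * (n1 + 2), 0.0));
    // gfix grid index: reuse the lambda grid by lookup table
    lamIdxOf.assign(ng, 0);
    for (int gi = 0; gi < ng; ++gi)
      for (int li = 0; li < nl; ++li)
        if (lam[li] == lamG[gi]) { lamIdxOf[gi] = li; break; }
    for (int gi = 0; gi < ng; ++gi) {
      int li = lamIdxOf[gi];
      double l = lamG[gi], m = muG[gi];
      std::vector<double>& g = Gsuf3[gi];
      for (int t = 1; t <= n1; ++t) {
        double runmax = 0.0;  // over k <= L, plus stops
        double effv = ba[t] - l * b0[t];
        for (int L = 1; L <= n2max; ++L) {
          double v = gfix[li][t * (n2max + 1) + L] - m * L * b0[t];
          if (v > runmax) runmax = v;
          double g3 = std::max(std::max(0.0, effv), runmax);
          g[L * (n1 + 2) + t] += g3;  // temporarily per-state, summed below
        }
        // L = 0: stops only
        g[t] += std::max(0.0, effv);
      }
      // turn per-state values into suffix sums for every L
      for (int L = 0; L <= n2max; ++L) {
        double acc = 0.0;
        for (int s = n1; s >= 1; --s) {
          acc += g[L * (n1 + 2) + s];
          g[L * (n1 + 2) + s] = acc;
        }
        g[L * (n1 + 2)] = g[L * (n1 + 2) + 1];
      }
    }
  }

  // weak duality over (type I mass <= aCap, future stage-2 expected cost
  // <= essCap): true if the subtree cannot reach the power target
  bool mu_prune(int s, int L, double aCap, double essCap,
                double need) const {
    if (s == 0) s = 1;
    for (size_t gi = 0; gi < lamG.size(); ++gi) {
      double suf = s <= n1 ? Gsuf3[gi][L * (n1 + 2) + s] : 0.0;
      if (poolDual[lamIdxOf[gi]] + suf + lamG[gi] * aCap +
          muG[gi] * essCap < need - 1e-9)
        return true;
    }
    return false;
  }

  // weak-duality check: true if the subtree is provably power-infeasible
  bool lambda_prune(int s, int L, double budget, double need) const {
    if (s == 0) s = 1;
    for (size_t li = 0; li < lam.size(); ++li) {
      double suf = s <= n1 ? Gsuf[li][L * (n1 + 2) + s] : 0.0;
      if (poolDual[li] + suf + lam[li] * budget < need - 1e-9) return true;
    }
    return false;
  }

  double cex(int k, int j, double p) const {   // j = r - s
    return 1.0 - R::pbinom(j, k, p, 1, 0);
  }

  void build_frontiers() {
    foff.assign(n2max + 2, 0);
    for (int k = 1; k <= n2max; ++k) foff[k + 1] = foff[k] + (k + 1);
    fx.assign(foff[n2max + 1], 0.0); fy.assign(foff[n2max + 1], 0.0);
    for (int k = 1; k <= n2max; ++k) {
      int o = foff[k];
      fx[o] = 0.0; fy[o] = 0.0;
      for (int i = 1; i <= k; ++i) {   // i-th vertex: j = k - i
        fx[o + i] = cex(k, k - i, p0);
        fy[o + i] = cex(k, k - i, p1);
      }
    }
  }

  void hull(int L, std::vector<double>& hx, std::vector<double>& hy) const {
    std::vector<std::pair<double, double>> pts;
    pts.emplace_back(0.0, 0.0);
    pts.emplace_back(1.0, 1.0);
    for (int k = 1; k <= L; ++k)
      for (int j = 0; j < k; ++j)
        pts.emplace_back(cex(k, j, p0), cex(k, j, p1));
    std::sort(pts.begin(), pts.end());
    hx.clear(); hy.clear();
    for (auto& p : pts) {
      if (!hx.empty() && p.first == hx.back()) {
        if (p.second <= hy.back()) continue;
        hx.pop_back(); hy.pop_back();
      }
      while (hx.size() >= 2) {
        double x0 = hx[hx.size() - 2], y0 = hy[hy.size() - 2];
        double x1 = hx.back(), y1 = hy.back();
        if ((x1 - x0) * (p.second - y0) - (y1 - y0) * (p.first - x0) >= 0) {
          hx.pop_back(); hy.pop_back();
        } else break;
      }
      hx.push_back(p.first); hy.push_back(p.second);
    }
  }

  void build_suffix_tables() {
    lp_cost.assign(n2max + 1, {});
    lp_gain.assign(n2max + 1, {});
    lp_ratio.assign(n2max + 1, {});
    lp_off.assign(n2max + 1, std::vector<int>(n1 + 3, 0));
    std::vector<double> hx, hy;
    for (int L = 0; L <= n2max; ++L) {
      hull(L, hx, hy);
      int m = (int)hx.size() - 1;
      std::vector<double> sl(m), dx(m), dy(m);
      for (int i = 0; i < m; ++i) {
        dx[i] = hx[i + 1] - hx[i];
        dy[i] = hy[i + 1] - hy[i];
        sl[i] = dx[i] > 0 ? dy[i] / dx[i] : R_PosInf;
      }
      long total = 0;
      for (int s = 1; s <= n1; ++s) total += (long)(n1 - s + 1) * m;
      std::vector<double>&C = lp_cost[L], &Gn = lp_gain[L], &Rt = lp_ratio[L];
      C.resize(total); Gn.resize(total); Rt.resize(total);
      std::vector<int>& off = lp_off[L];
      off[n1 + 1] = (int)total;
      int pos = (int)total;
      std::vector<double> prevC, prevG, prevR;
      for (int s = n1; s >= 1; --s) {
        int len = (int)prevC.size() + m;
        pos -= len;
        off[s] = pos;
        double w = b0[s] > 0 ? ba[s] / b0[s] : R_PosInf;
        int i = 0; size_t k = 0; int o = pos;
        double cc = 0, cg = 0, pc = 0, pg = 0;
        while (i < m || k < prevC.size()) {
          double rs = i < m
            ? (std::isfinite(w) ? sl[i] * w : (dy[i] > 0 ? R_PosInf : 0.0))
            : -1.0;
          double rp = k < prevC.size() ? prevR[k] : -1.0;
          if (i < m && rs >= rp) {
            cc += dx[i] * b0[s]; cg += dy[i] * ba[s];
            C[o] = cc; Gn[o] = cg; Rt[o] = rs; ++o; ++i;
          } else {
            cc += prevC[k] - pc; cg += prevG[k] - pg;
            C[o] = cc; Gn[o] = cg; Rt[o] = rp; ++o;
            pc = prevC[k]; pg = prevG[k]; ++k;
          }
        }
        prevC.assign(C.begin() + pos, C.begin() + pos + len);
        prevG.assign(Gn.begin() + pos, Gn.begin() + pos + len);
        prevR.assign(Rt.begin() + pos, Rt.begin() + pos + len);
      }
      off[0] = off[1];  // s = 0 is a forced futility stop
    }
  }

  void build_universe() {
    seg_off.assign((n1 + 1) * (n2max + 1) + 1, 0);
    int U = 0;
    for (int t = 1; t <= n1; ++t)
      for (int k = 1; k <= n2max; ++k) U += k;
    seg_cost.resize(U); seg_gain.resize(U); seg_ratio.resize(U);
    int pos = 0;
    for (int t = 1; t <= n1; ++t)
      for (int k = 1; k <= n2max; ++k) {
        seg_off[t * (n2max + 1) + k] = pos;
        int o = foff[k];
        for (int i = 0; i < k; ++i) {
          double dx = fx[o + i + 1] - fx[o + i];
          double dy = fy[o + i + 1] - fy[o + i];
          double cost = dx * b0[t], gain = dy * ba[t];
          seg_cost[pos] = cost;
          seg_gain[pos] = gain;
          seg_ratio[pos] = cost > 0 ? gain / cost
                                    : (gain > 0 ? R_PosInf : 0.0);
          ++pos;
        }
      }
    seg_off.back() = pos;
    std::vector<int> ord(U);
    for (int i = 0; i < U; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return seg_ratio[a] > seg_ratio[b];
    });
    seg_rank.assign(U, 0);
    rank_ratio.assign(U, 0.0);
    for (int r = 0; r < U; ++r) {
      seg_rank[ord[r]] = r;
      rank_ratio[r] = seg_ratio[ord[r]];
    }
    fen.init(U);
  }

  std::vector<int> lamIdxOf;  // lambda-grid index per (lambda, mu) pair

  void pool_push(int t, int k, double sign) {
    int o = seg_off[t * (n2max + 1) + k];
    for (int i = 0; i < k; ++i)
      fen.add(seg_rank[o + i], sign * seg_cost[o + i],
              sign * seg_gain[o + i]);
    for (size_t li = 0; li < lam.size(); ++li)
      poolDual[li] += sign * gfix[li][t * (n2max + 1) + k];
  }

  int suffix_count(int L, int s, double lam) const {
    const std::vector<double>& Rt = lp_ratio[L];
    int lo = lp_off[L][s], hi = lp_off[L][s + 1];
    int a = lo, b = hi;
    while (a < b) {
      int mid = (a + b) / 2;
      if (Rt[mid] >= lam) a = mid + 1; else b = mid;
    }
    return a - lo;
  }

  // LP upper bound on total power within the alpha budget, over the
  // decided pool plus the undecided suffix s..n1 limited to n2 <= L;
  // lamOut receives the marginal ratio at the budget cutoff
  double lp_bound(int s, int L, double budget,
                  double* lamOut = nullptr) const {
    if (s == 0) s = 1;
    bool hasSuf = s <= n1;
    int lo = hasSuf ? lp_off[L][s] : 0;
    int slen = hasSuf ? lp_off[L][s + 1] - lo : 0;
    const std::vector<double>* C = hasSuf ? &lp_cost[L] : nullptr;
    const std::vector<double>* Gn = hasSuf ? &lp_gain[L] : nullptr;
    const std::vector<double>* Rt = hasSuf ? &lp_ratio[L] : nullptr;
    int U = (int)rank_ratio.size();
    auto total_at = [&](int r, double& cost, double& gain, int& scnt) {
      double fc = 0, fg = 0;
      if (r >= 0) fen.prefix(r, fc, fg);
      scnt = 0;
      if (slen > 0 && r >= 0) scnt = suffix_count(L, s, rank_ratio[r]);
      cost = fc + (scnt > 0 ? (*C)[lo + scnt - 1] : 0.0);
      gain = fg + (scnt > 0 ? (*Gn)[lo + scnt - 1] : 0.0);
    };
    // largest rank r with total cost <= budget (monotone in r); r = -1
    // takes nothing from the pool and nothing from the suffix
    int a = -1;
    {
      int loR = -1, hiR = U - 1;
      while (loR < hiR) {
        int mid = (loR + hiR + 1) / 2;
        double cc, gg; int sc;
        total_at(mid, cc, gg, sc);
        if (cc <= budget) loR = mid; else hiR = mid - 1;
      }
      a = loR;
    }
    double cost, gain; int scnt;
    total_at(a, cost, gain, scnt);
    // uncounted suffix segments with ratio above the pool threshold:
    // extend in suffix order while they fit whole (they are sorted by
    // ratio, so this continues the exact greedy)
    double lamPool = a + 1 < U ? rank_ratio[a + 1] : 0.0;
    while (scnt < slen && (*Rt)[lo + scnt] >= lamPool) {
      double segc = (*C)[lo + scnt] - (scnt > 0 ? (*C)[lo + scnt - 1] : 0.0);
      if (cost + segc > budget) break;
      cost += segc;
      gain += (*Gn)[lo + scnt] - (scnt > 0 ? (*Gn)[lo + scnt - 1] : 0.0);
      ++scnt;
    }
    // partial fill at the best remaining ratio: a valid upper bound
    // because every remaining segment has ratio <= lamNext
    double lamNext = lamPool;
    if (scnt < slen) lamNext = std::max(lamNext, (*Rt)[lo + scnt]);
    if (lamOut) *lamOut = lamNext;
    double rem = budget - cost;
    if (rem > 0 && lamNext > 0) {
      if (std::isfinite(lamNext)) gain += rem * lamNext;
      else return 2.0;  // free mass remains: bound is vacuous
    }
    return gain;
  }

  // ------------------------------------------------- inner (exact) solve
  // Knapsack lists over the decided continuations, maintained
  // incrementally along the search path: level d merges the frontier
  // segments of the first d continuation states, cumulated in
  // power-per-alpha ratio order.  minApre[d] is the minimal type I mass
  // of those d states.
  std::vector<std::vector<double>> innC, innG, innR;
  std::vector<double> minApre;

  void inner_push(int t, int k) {
    const std::vector<double>& pC = innC.back();
    const std::vector<double>& pG = innG.back();
    const std::vector<double>& pR = innR.back();
    int o = seg_off[t * (n2max + 1) + k];
    int len = (int)pC.size() + k;
    std::vector<double> C(len), G(len), R(len);
    int ii = 0; size_t kk = 0; int oo = 0;
    double cc = 0, cg = 0, pc = 0, pg = 0;
    while (ii < k || kk < pC.size()) {
      double rs = ii < k ? seg_ratio[o + ii] : -1.0;
      double rp = kk < pC.size() ? pR[kk] : -1.0;
      if (ii < k && rs >= rp) {
        cc += seg_cost[o + ii]; cg += seg_gain[o + ii];
        C[oo] = cc; G[oo] = cg; R[oo] = rs; ++oo; ++ii;
      } else {
        cc += pC[kk] - pc; cg += pG[kk] - pg;
        C[oo] = cc; G[oo] = cg; R[oo] = rp; ++oo;
        pc = pC[kk]; pg = pG[kk]; ++kk;
      }
    }
    pushes += 1;
    innC.push_back(std::move(C));
    innG.push_back(std::move(G));
    innR.push_back(std::move(R));
    minApre.push_back(minApre.back() + ce0min[k] * b0[t]);
  }

  void inner_pop() {
    innC.pop_back(); innG.pop_back(); innR.pop_back();
    minApre.pop_back();
  }

  // fractional max power over the first d continuation states
  double inner_bound(int d, double budget) const {
    if (d <= 0 || budget <= 0) return 0.0;
    const std::vector<double>& C = innC[d];
    const std::vector<double>& G = innG[d];
    const std::vector<double>& R = innR[d];
    int hi = (int)C.size();
    if (hi == 0) return 0.0;
    int a = (int)(std::upper_bound(C.begin(), C.end(), budget) - C.begin());
    if (a == 0) {
      double r = R[0];
      return std::isfinite(r) ? budget * r : G[0];
    }
    double val = G[a - 1];
    if (a < hi) {
      double r = R[a];
      double spare = budget - C[a - 1];
      val += std::isfinite(r) ? spare * r : (G[a] - G[a - 1]);
    }
    return val;
  }

  // Exact search over critical values.  States are reordered by
  // probability mass (heaviest first) so the binding tradeoffs are
  // decided early; the light tail is absorbed by the early exit, which
  // assigns every remaining state its minimal conditional error.  Local
  // cumulative knapsack tables over the reordered suffixes provide the
  // fractional power bound.
  struct InnerCtx {
    std::vector<int> ord;                     // indices into contS/contK
    std::vector<double> minA;                 // minimal alpha, suffix
    std::vector<std::vector<double>> C, G, R; // knapsack per suffix
    double aBudget, pNeed;
  };

  double inner_suffix_bound(const InnerCtx& cx, int i, double budget) const {
    if (i >= (int)cx.ord.size() || budget <= 0) return 0.0;
    const std::vector<double>&C = cx.C[i], &G = cx.G[i], &R = cx.R[i];
    int hi = (int)C.size();
    if (hi == 0) return 0.0;
    int a = (int)(std::upper_bound(C.begin(), C.end(), budget) - C.begin());
    if (a == 0) return std::isfinite(R[0]) ? budget * R[0] : G[0];
    double val = G[a - 1];
    if (a < hi) {
      double spare = budget - C[a - 1];
      val += std::isfinite(R[a]) ? spare * R[a] : (G[a] - G[a - 1]);
    }
    return val;
  }

  bool inner_rec2(const InnerCtx& cx, const std::vector<int>& states,
                  int i, double al, double pw, std::vector<int>& js) {
    nodes += 1; innNodes += 1;
    int c = (int)cx.ord.size();
    if (pw >= cx.pNeed && al + cx.minA[i] <= cx.aBudget) {
      for (int l = i; l < c; ++l)
        js[cx.ord[l]] = contK[states[cx.ord[l]]] - 1;
      return true;
    }
    if (i == c) return false;
    if (pw < cx.pNeed &&
        inner_suffix_bound(cx, i, cx.aBudget - al) < cx.pNeed - pw - 1e-9)
      return false;
    int idx = cx.ord[i];
    int t = contS[states[idx]], k = contK[states[idx]];
    for (int j = k - 1; j >= 0; --j) {   // null error ascending
      double a2 = al + cex(k, j, p0) * b0[t];
      if (a2 + cx.minA[i + 1] > cx.aBudget) break;
      js[idx] = j;
      if (inner_rec2(cx, states, i + 1, a2, pw + cex(k, j, p1) * ba[t], js))
        return true;
    }
    return false;
  }

  // Relaxation tier: states whose whole alpha range is negligible
  // relative to the budget slack contribute their maximal rejection mass
  // and their minimal type I mass; the exact solve then runs over the
  // remaining (heavy) states only.  Rejection by the relaxed problem is
  // sound (it only overstates the attainable power); acceptance is
  // verified exactly before being believed.
  bool inner_solve(double aBudget, double pNeed, std::vector<int>& js) {
    int c = (int)contS.size();
    js.assign(c, 0);
    for (int i = 0; i < c; ++i) js[i] = contK[i] - 1;
    if (c == 0) return pNeed <= 0;
    double minTot = 0;
    for (int i = 0; i < c; ++i) minTot += ce0min[contK[i]] * b0[contS[i]];
    if (minTot > aBudget) return false;
    double slack = aBudget - minTot;
    double lightTol = 0.02 * slack / c;
    std::vector<int> heavy;
    double lightP = 0, lightA = 0, giveaway = 0;
    for (int i = 0; i < c; ++i) {
      double span = (ce0max[contK[i]] - ce0min[contK[i]]) * b0[contS[i]];
      if (span <= lightTol) {
        lightP += pwMaxFix[contK[i]] * ba[contS[i]];
        lightA += ce0min[contK[i]] * b0[contS[i]];
        giveaway += span;
        js[i] = 0;  // maximal conditional rejection for light states
      } else {
        heavy.push_back(i);
      }
    }
    if (!heavy.empty() && (int)heavy.size() < c) {
      std::vector<int> hjs;
      if (!inner_core(heavy, aBudget - lightA, pNeed - lightP, hjs))
        return false;  // relaxation infeasible: truly infeasible
      // verify the combined assignment exactly (light states at j = 0)
      double al = 0, pw = 0;
      for (size_t h = 0; h < heavy.size(); ++h) js[heavy[h]] = hjs[h];
      for (int i = 0; i < c; ++i) {
        al += cex(contK[i], js[i], p0) * b0[contS[i]];
        pw += cex(contK[i], js[i], p1) * ba[contS[i]];
      }
      if (al <= aBudget && pw >= pNeed) return true;
      // relaxed accept did not verify: fall through to the exact solve
      for (int i = 0; i < c; ++i) js[i] = contK[i] - 1;
    }
    std::vector<int> all(c);
    for (int i = 0; i < c; ++i) all[i] = i;
    return inner_core(all, aBudget, pNeed, js);
  }

  // exact solve over an index subset of the decided continuations;
  // js is sized and indexed by position within `states`
  bool inner_core(const std::vector<int>& states, double aBudget,
                  double pNeed, std::vector<int>& js) {
    int c = (int)states.size();
    js.assign(c, 0);
    for (int i = 0; i < c; ++i) js[i] = contK[states[i]] - 1;
    if (c == 0) return pNeed <= 0;
    if (aBudget < 0) return false;
    InnerCtx cx;
    cx.aBudget = aBudget; cx.pNeed = pNeed;
    cx.ord.resize(c);
    for (int i = 0; i < c; ++i) cx.ord[i] = i;
    std::sort(cx.ord.begin(), cx.ord.end(), [&](int a, int b) {
      return b0[contS[states[a]]] + ba[contS[states[a]]] >
             b0[contS[states[b]]] + ba[contS[states[b]]];
    });
    cx.minA.assign(c + 1, 0.0);
    for (int i = c - 1; i >= 0; --i)
      cx.minA[i] = cx.minA[i + 1] +
        ce0min[contK[states[cx.ord[i]]]] * b0[contS[states[cx.ord[i]]]];
    if (cx.minA[0] > aBudget) return false;
    cx.C.resize(c); cx.G.resize(c); cx.R.resize(c);
    {
      std::vector<double> pC, pG, pR;
      for (int i = c - 1; i >= 0; --i) {
        int t = contS[states[cx.ord[i]]], k = contK[states[cx.ord[i]]];
        int o = seg_off[t * (n2max + 1) + k];
        int len = (int)pC.size() + k;
        cx.C[i].resize(len); cx.G[i].resize(len); cx.R[i].resize(len);
        int ii = 0; size_t kk = 0; int oo = 0;
        double cc = 0, cg = 0, pc = 0, pg = 0;
        while (ii < k || kk < pC.size()) {
          double rs = ii < k ? seg_ratio[o + ii] : -1.0;
          double rp = kk < pC.size() ? pR[kk] : -1.0;
          if (ii < k && rs >= rp) {
            cc += seg_cost[o + ii]; cg += seg_gain[o + ii];
            cx.C[i][oo] = cc; cx.G[i][oo] = cg; cx.R[i][oo] = rs;
            ++oo; ++ii;
          } else {
            cc += pC[kk] - pc; cg += pG[kk] - pg;
            cx.C[i][oo] = cc; cx.G[i][oo] = cg; cx.R[i][oo] = rp; ++oo;
            pc = pC[kk]; pg = pG[kk]; ++kk;
          }
        }
        pC = cx.C[i]; pG = cx.G[i]; pR = cx.R[i];
      }
    }
    return inner_rec2(cx, states, 0, 0.0, 0.0, js);
  }

  // ---------------------------------------------------------- leaf check
  // pwMax: sum of the decided continuations' maximal rejection masses
  void leaf(int effFrom, double ess, double pwMax) {
    if (ess >= best - TTOL) return;
    if (ess < ess_lower) return;   // proven infeasible by an earlier sweep
    if (exact_mss && contS.empty()) return;
    double aSuffix = B0tail[effFrom], pSuffix = Batail[effFrom];
    if (aSuffix > alpha + CTOL) return;
    double pNeed = 1 - beta - CTOL - pSuffix;
    if (pwMax < pNeed) return;          // cheap reject before solving
    double aBudget = alpha + CTOL - aSuffix;
    if (aBudget < minApre.back()) return;
    int c = (int)contS.size();
    if (pNeed > 0 && inner_bound(c, aBudget) < pNeed - 1e-9) {
      prLP += 1; return;                // exact LP over the frontiers
    }
    solves += 1;
    std::vector<int> js;
    if (!inner_solve(aBudget, pNeed, js))
      return;
    best = ess; found = true;
    bestKind = curKind; bestN2 = curN2; bestJ.assign(n1 + 1, 0);
    for (int t = effFrom; t <= n1; ++t) { bestKind[t] = 2; bestN2[t] = 0; }
    bestAlpha = aSuffix; bestPower = pSuffix;
    for (size_t i = 0; i < contS.size(); ++i) {
      bestJ[contS[i]] = js[i];
      bestAlpha += cex(contK[i], js[i], p0) * b0[contS[i]];
      bestPower += cex(contK[i], js[i], p1) * ba[contS[i]];
    }
  }

  // ------------------------------------------------------ size-level DFS
  // phase 0: futility prefix open; phase 1: continuation started.
  // pwMax: sum of decided continuations' maximal rejection masses.
  void dfs(int s, int phase, int limit, double alMin, double ess,
           double pwMax) {
    nodes += 1; dfsNodes += 1;
    if (aborted || nodes > max_nodes) { aborted = true; return; }
    if (s > n1) { leaf(n1 + 1, ess, pwMax); return; }
    if (alMin > alpha + CTOL) { prA += 1; return; }
    if (ess + n1 * B0tail[s] >= best - TTOL) { prF += 1; return; }
    int L = phase == 0 ? n2max : limit;
    // every completion of this subtree costs less than the proven lower
    // bound: all of them are known infeasible
    if (ess + (double)(n1 + L) * B0tail[s] < ess_lower) { prF += 1; return; }
    double need = 1 - beta - CTOL;
    if (pwMax + Batail[s] < need) { prLam += 1; return; }
    if (lambda_prune(s, L, alpha + CTOL, need)) { prLam += 1; return; }
    double essCap = std::isfinite(best)
      ? (best - TTOL) - ess - n1 * B0tail[s] : R_PosInf;
    if (std::isfinite(essCap) &&
        mu_prune(s, L, alpha + CTOL, essCap, need)) { prLam += 1; return; }
    if (lp_bound(s, L, alpha + CTOL) < need - 1e-9) { prLP += 1; return; }

    if (phase == 0) {
      curKind[s] = 0; curN2[s] = 0;
      dfs(s + 1, 0, n2max, alMin, ess + n1 * b0[s], pwMax);
      if (aborted) return;
      if (s == 0) return;  // no responses: futility is forced
    }
    // efficacy suffix from s (closes the schedule)
    leaf(s, ess + n1 * B0tail[s], pwMax);
    // continuations: n2 ascending; with exact_mss the first continuation
    // is pinned to n2max so the maximum sample size is exactly n
    int kFrom = 1, kTo = L;
    if (exact_mss && phase == 0) kFrom = kTo = n2max;
    for (int k = kFrom; k <= kTo; ++k) {
      double ess2 = ess + (double)(n1 + k) * b0[s];
      if (ess2 + n1 * B0tail[s + 1] >= best - TTOL) { prF += 1; continue; }
      double al2 = alMin + ce0min[k] * b0[s];
      if (al2 > alpha + CTOL) { prA += 1; continue; }
      curKind[s] = 1; curN2[s] = k;
      contS.push_back(s); contK.push_back(k);
      pool_push(s, k, 1.0);
      inner_push(s, k);
      dfs(s + 1, 1, k, al2, ess2, pwMax + pwMaxFix[k] * ba[s]);
      inner_pop();
      pool_push(s, k, -1.0);
      contS.pop_back(); contK.pop_back();
      if (aborted) return;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".bb_search_cpp")]]
List bb_search_cpp(int n1, int n, double alpha, double beta, double p0,
                   double p1, bool exact_mss, double incumbent,
                   double max_nodes, double ess_lower) {
  Engine e;
  e.n1 = n1; e.n = n; e.alpha = alpha; e.beta = beta;
  e.p0 = p0; e.p1 = p1; e.exact_mss = exact_mss;
  e.best = incumbent;
  e.ess_lower = ess_lower;
  e.max_nodes = max_nodes;
  e.init();

  double lp_pow = e.lp_bound(1, e.n2max, alpha + CTOL);
  if (lp_pow >= 1 - beta - CTOL - 1e-9)
    e.dfs(0, 0, e.n2max, 0.0, 0.0, 0.0);

  List stats = List::create(
      _["nodes"] = e.nodes, _["pruned_alpha"] = e.prA,
      _["pruned_objective"] = e.prF, _["pruned_lp"] = e.prLP,
      _["pruned_dual"] = e.prLam, _["lp_power_bound"] = lp_pow,
      _["inner_solves"] = e.solves, _["dfs_nodes"] = e.dfsNodes,
      _["inner_nodes"] = e.innNodes, _["pushes"] = e.pushes,
      _["ties"] = e.ties, _["aborted"] = e.aborted);
  if (!e.found)
    return List::create(_["feasible"] = false, _["stats"] = stats);

  IntegerVector kind(n1 + 1), n2(n1 + 1), r(n1 + 1);
  for (int s = 0; s <= n1; ++s) {
    kind[s] = e.bestKind[s];
    n2[s] = e.bestN2[s];
    r[s] = e.bestKind[s] == 1 ? s + e.bestJ[s] : 0;
  }
  return List::create(
      _["feasible"] = true, _["kind"] = kind, _["n2"] = n2, _["r"] = r,
      _["ess0"] = e.best, _["alpha"] = e.bestAlpha,
      _["power"] = e.bestPower, _["stats"] = stats);
}

// Seeding heuristic: the best *two-level* monotone schedule at (n1, n) --
// a futility prefix, a first block of continuations at size k1, an
// optional second block at size k2 < k1, and an efficacy suffix, with
// critical values resolved by the exact inner solve.  Published optimal
// schedules are predominantly of this shape, so this provides sharp
// incumbents for the branch-and-bound at negligible cost.  Purely an
// upper bound: the main search only ever improves on it.
// [[Rcpp::export(name = ".two_level_best_cpp")]]
List two_level_best_cpp(int n1, int n, double alpha, double beta, double p0,
                        double p1, bool exact_mss, double incumbent) {
  Engine e;
  e.n1 = n1; e.n = n; e.alpha = alpha; e.beta = beta;
  e.p0 = p0; e.p1 = p1; e.exact_mss = exact_mss;
  e.best = incumbent;
  e.init(true);
  int n2max = e.n2max;
  std::vector<double> Pb0(n1 + 2, 0.0), Pba(n1 + 2, 0.0);
  for (int s = 0; s <= n1; ++s) {
    Pb0[s + 1] = Pb0[s] + e.b0[s];
    Pba[s + 1] = Pba[s] + e.ba[s];
  }
  double bestEss = incumbent;
  bool found = false;
  std::vector<int> bKind, bN2, bR;
  std::vector<int> js;
  double need = 1 - beta - CTOL;
  for (int t0 = 1; t0 <= n1; ++t0) {
    for (int eidx = t0 + 1; eidx <= n1 + 1; ++eidx) {
      double aSuffix = e.B0tail[eidx > n1 ? n1 + 1 : eidx];
      if (aSuffix > alpha + CTOL) continue;
      double pSuffix = e.Batail[eidx > n1 ? n1 + 1 : eidx];
      int k1lo = exact_mss ? n2max : 1;
      for (int k1 = n2max; k1 >= k1lo; --k1) {
        // m = first state of the second block; m == eidx means none
        for (int m = eidx; m >= t0 + 1; --m) {
          int k2hi = m == eidx ? 0 : k1 - 1;
          for (int k2 = k2hi; k2 >= (m == eidx ? 0 : 1); --k2) {
            double ess = n1 + k1 * (Pb0[m] - Pb0[t0]) +
                         (m == eidx ? 0.0 : k2 * (Pb0[eidx] - Pb0[m]));
            if (ess >= bestEss - TTOL) continue;
            double pwMax = pSuffix +
              e.pwMaxFix[k1] * (Pba[m] - Pba[t0]) +
              (m == eidx ? 0.0 : e.pwMaxFix[k2] * (Pba[eidx] - Pba[m]));
            if (pwMax < need) continue;
            double alMin = aSuffix +
              e.ce0min[k1] * (Pb0[m] - Pb0[t0]) +
              (m == eidx ? 0.0 : e.ce0min[k2] * (Pb0[eidx] - Pb0[m]));
            if (alMin > alpha + CTOL) continue;
            e.contS.clear(); e.contK.clear();
            for (int s = t0; s < m; ++s) {
              e.contS.push_back(s); e.contK.push_back(k1);
            }
            for (int s = m; s < eidx; ++s) {
              e.contS.push_back(s); e.contK.push_back(k2);
            }
            if (!e.inner_solve(alpha + CTOL - aSuffix, need - pSuffix, js))
              continue;
            bestEss = ess; found = true;
            bKind.assign(n1 + 1, 0); bN2.assign(n1 + 1, 0);
            bR.assign(n1 + 1, 0);
            for (int s = 0; s <= n1; ++s)
              bKind[s] = s < t0 ? 0 : (s < eidx ? 1 : 2);
            for (size_t i = 0; i < e.contS.size(); ++i) {
              bN2[e.contS[i]] = e.contK[i];
              bR[e.contS[i]] = e.contS[i] + js[i];
            }
          }
          if (m == eidx && exact_mss) continue;
        }
      }
    }
  }
  if (!found) return List::create(_["feasible"] = false);
  return List::create(_["feasible"] = true, _["kind"] = bKind,
                      _["n2"] = bN2, _["r"] = bR, _["ess0"] = bestEss);
}
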