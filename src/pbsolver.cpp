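// Exact branch-and-bound solver for 0/1 pseudo-boolean programs:
//   minimize  sum_v obj[v] * x[v]
//   s.t.      sum_v coef[c,v] * x[v]  >=  rhs[c]   (all rows normalised to >=)
//             x binary
//
// Queue-based unit propagation over [minL, maxL] bounds per constraint: a row
// whose maximal achievable LHS falls below its rhs is a conflict; a free
// variable whose unfavourable value would create one is fixed. Branching is
// dynamic: among not-yet-guaranteed rows pick the one with fewest free
// variables and branch its largest-coefficient free variable, trying the
// satisfying value first. When every row is guaranteed (minL >= rhs), free
// variables take the objective-optimal value 0. The incumbent objective
// prunes; with a non-negative objective a 0-cost incumbent is optimal.

#include <Rcpp.h>
#include <vector>
#include <cstdlib>
#include <chrono>
using namespace Rcpp;

namespace {

struct Solver {
  int nvar, ncon;
  std::vector<int> obj;
  std::vector<int> conStart, conVar, conCoef, rhs;  // CSR rows
  std::vector<int> varConStart, varCon, varCoef;    // CSC: rows per variable
  std::vector<int> val;                              // -1 free, 0, 1
  std::vector<int> minL, maxL, nFree;
  std::vector<int> trail;
  long long nodes = 0;
  double tEnd;
  bool timedOut = false;
  std::vector<int> best;
  long long bestCost;

  double now() {
    return std::chrono::duration<double>(
      std::chrono::steady_clock::now().time_since_epoch()).count();
  }

  void init() {
    val.assign(nvar, -1);
    minL.assign(ncon, 0); maxL.assign(ncon, 0); nFree.assign(ncon, 0);
    std::vector<int> cnt(nvar, 0);
    for (int c = 0; c < ncon; ++c)
      for (int t = conStart[c]; t < conStart[c + 1]; ++t) ++cnt[conVar[t]];
    varConStart.assign(nvar + 1, 0);
    for (int v = 0; v < nvar; ++v) varConStart[v + 1] = varConStart[v] + cnt[v];
    varCon.resize(conStart[ncon]); varCoef.resize(conStart[ncon]);
    std::vector<int> pos(varConStart.begin(), varConStart.end() - 1);
    for (int c = 0; c < ncon; ++c)
      for (int t = conStart[c]; t < conStart[c + 1]; ++t) {
        int v = conVar[t];
        varCon[pos[v]] = c; varCoef[pos[v]] = conCoef[t]; ++pos[v];
      }
    for (int c = 0; c < ncon; ++c) {
      int lo = 0, hi = 0, nf = 0;
      for (int t = conStart[c]; t < conStart[c + 1]; ++t) {
        int a = conCoef[t];
        if (a > 0) hi += a; else lo += a;
        ++nf;
      }
      minL[c] = lo; maxL[c] = hi; nFree[c] = nf;
    }
  }

  // assign v := b; push touched rows on the propagation queue.
  // Returns false on an immediate bound conflict.
  bool assign(int v, int b, std::vector<int>& queue) {
    val[v] = b;
    trail.push_back(v);
    bool ok = true;
    for (int t = varConStart[v]; t < varConStart[v + 1]; ++t) {
      int c = varCon[t], a = varCoef[t];
      if (a > 0) { if (b == 0) maxL[c] -= a; else minL[c] += a; }
      else       { if (b == 1) maxL[c] += a; else minL[c] -= a; }
      --nFree[c];
      if (maxL[c] < rhs[c]) ok = false;
      queue.push_back(c);
    }
    return ok;
  }

  void undoTo(size_t mark) {
    while (trail.size() > mark) {
      int v = trail.back(); trail.pop_back();
      int b = val[v];
      for (int t = varConStart[v]; t < varConStart[v + 1]; ++t) {
        int c = varCon[t], a = varCoef[t];
        if (a > 0) { if (b == 0) maxL[c] += a; else minL[c] -= a; }
        else       { if (b == 1) maxL[c] -= a; else minL[c] += a; }
        ++nFree[c];
      }
      val[v] = -1;
    }
  }

  // queue-based propagation to fixpoint; false on conflict
  bool propagate(std::vector<int>& queue) {
    for (size_t qi = 0; qi < queue.size(); ++qi) {
      int c = queue[qi];
      if (maxL[c] < rhs[c]) return false;
      if (minL[c] >= rhs[c] || nFree[c] == 0) continue;
      for (int t = conStart[c]; t < conStart[c + 1]; ++t) {
        int v = conVar[t];
        if (val[v] != -1) continue;
        int a = conCoef[t];
        if (a > 0 && maxL[c] - a < rhs[c]) {
          if (!assign(v, 1, queue)) return false;
        } else if (a < 0 && maxL[c] + a < rhs[c]) {
          if (!assign(v, 0, queue)) return false;
        }
      }
    }
    return true;
  }

  long long curCost() {
    long long s = 0;
    for (int v = 0; v < nvar; ++v) if (val[v] == 1) s += obj[v];
    return s;
  }

  std::vector<int> decision, preferred;  // static branch order + value hints

  // pick branching variable: unsatisfied row with fewest free vars, then its
  // free var with largest |coef|; preferred value is the satisfying one.
  // Returns -1 when every row is guaranteed.
  int pickVar(int& prefer) {
    int bc = -1, bestFree = INT_MAX;
    for (int c = 0; c < ncon; ++c) {
      if (minL[c] >= rhs[c] || nFree[c] == 0) continue;
      if (nFree[c] < bestFree) { bestFree = nFree[c]; bc = c; }
    }
    if (bc == -1) return -1;
    // prefer objective-free variables (branching a costed variable toward 1
    // just to satisfy a row fights the minimisation)
    int bv = -1, bCoef = 0; bool bCosted = true;
    for (int t = conStart[bc]; t < conStart[bc + 1]; ++t) {
      int v = conVar[t];
      if (val[v] != -1) continue;
      int a = conCoef[t];
      bool costed = obj[v] > 0;
      if ((bCosted && !costed) ||
          (costed == bCosted && std::abs(a) > std::abs(bCoef))) {
        bCoef = a; bv = v; bCosted = costed;
      }
    }
    prefer = obj[bv] > 0 ? 0 : (bCoef > 0 ? 1 : 0);
    return bv;
  }

  // branch the next free variable of the static decision order; once it is
  // exhausted, fall back to dynamic selection to settle the auxiliaries
  void dfs(size_t di) {
    if (timedOut) return;
    if (++nodes % 1024 == 0 && now() > tEnd) { timedOut = true; return; }
    long long cost = curCost();
    if (cost >= bestCost) return;
    while (di < decision.size() && val[decision[di]] != -1) ++di;
    int v, prefer;
    if (di < decision.size()) {
      v = decision[di];
      prefer = preferred[v];
    } else {
      v = pickVar(prefer);
      if (v == -1) {
        // all rows guaranteed: free vars take 0, the objective-optimal value
        bestCost = cost;
        best.assign(val.begin(), val.end());
        for (int u = 0; u < nvar; ++u) if (best[u] == -1) best[u] = 0;
        return;
      }
    }
    for (int pass = 0; pass < 2 && !timedOut; ++pass) {
      int b = pass == 0 ? prefer : 1 - prefer;
      size_t mark = trail.size();
      std::vector<int> queue;
      if (assign(v, b, queue) && propagate(queue)) dfs(di);
      undoTo(mark);
      if (bestCost == 0) return;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".pbSolve")]]
List pbSolve(int nvar, IntegerVector obj,
             IntegerVector conStart, IntegerVector conVar,
             IntegerVector conCoef, IntegerVector rhs,
             IntegerVector decision, IntegerVector preferred,
             double timeLimit) {
  Solver s;
  s.nvar = nvar;
  s.ncon = rhs.size();
  s.obj.assign(obj.begin(), obj.end());
  s.conStart.assign(conStart.begin(), conStart.end());
  s.conVar.assign(conVar.begin(), conVar.end());
  s.conCoef.assign(conCoef.begin(), conCoef.end());
  s.rhs.assign(rhs.begin(), rhs.end());
  s.decision.assign(decision.begin(), decision.end());
  s.preferred.assign(preferred.begin(), preferred.end());
  s.bestCost = 1LL << 60;
  s.init();
  s.tEnd = s.now() + timeLimit;
  std::vector<int> rootQueue;
  for (int c = 0; c < s.ncon; ++c) rootQueue.push_back(c);
  if (s.propagate(rootQueue)) s.dfs(0);
  bool feasible = s.bestCost < (1LL << 60);
  std::string status;
  if (s.timedOut) status = "time-limited";
  else status = feasible ? "optimal" : "cutoff";
  IntegerVector sol(nvar, NA_INTEGER);
  if (feasible) for (int v = 0; v < nvar; ++v) sol[v] = s.best[v];
  return List::create(_["status"] = status,
                      _["objective"] = feasible ? (double)s.bestCost : R_PosInf,
                      _["solution"] = sol,
                      _["nodes"] = (double)s.nodes);
}
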