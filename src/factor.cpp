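#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Unit propagation for the log-linear propensity-factorization system
//   ltheta[ti[e]] + lomega[wi[e]] + lkappa[ki[e]] = rhs[e]
// (all indices 0-based). Variables are unified: theta block, then omega
// block, then kappa block. Seeds fix gauge values (theta(b)=0, omega(b)=0).
// When propagation stalls, the lowest-index still-unknown variable appearing
// in an unresolved equation is fixed to 0 (a gauge choice on an
// underdetermined component); genuine inconsistencies are detected by the
// final residual scan in R.
// [[Rcpp::export]]
List factor_propagate(int n_theta, int n_omega, int n_kappa,
                      IntegerVector ti, IntegerVector wi, IntegerVector ki,
                      NumericVector rhs,
                      IntegerVector seed_var, NumericVector seed_val) {
  const int ne = rhs.size();
  const int nv = n_theta + n_omega + n_kappa;
  std::vector<double> val(nv, 0.0);
  std::vector<char> known(nv, 0);
  std::vector<int> unk(ne);
  // adjacency var -> equations
  std::vector<int> deg(nv, 0);
  for (int e = 0; e < ne; e++) {
    deg[ti[e]]++; deg[n_theta + wi[e]]++; deg[n_theta + n_omega + ki[e]]++;
  }
  std::vector<int> start(nv + 1, 0);
  for (int v = 0; v < nv; v++) start[v + 1] = start[v] + deg[v];
  std::vector<int> adj(start[nv]);
  std::vector<int> pos(nv, 0);
  for (int e = 0; e < ne; e++) {
    int a = ti[e], b = n_theta + wi[e], c = n_theta + n_omega + ki[e];
    adj[start[a] + pos[a]++] = e;
    adj[start[b] + pos[b]++] = e;
    adj[start[c] + pos[c]++] = e;
  }
  for (int e = 0; e < ne; e++) unk[e] = 3;

  std::queue<int> q;
  int n_gauged = 0;
  auto set_var = [&](int v, double x) {
    if (known[v]) return;
    known[v] = 1; val[v] = x; q.push(v);
  };
  for (int i = 0; i < seed_var.size(); i++) set_var(seed_var[i], seed_val[i]);

  auto drain = [&]() {
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int j = start[v]; j < start[v + 1]; j++) {
        int e = adj[j];
        if (--unk[e] == 1) {
          int a = ti[e], b = n_theta + wi[e], c = n_theta + n_omega + ki[e];
          double s = rhs[e];
          int miss = -1;
          if (!known[a]) miss = a; else s -= val[a];
          if (!known[b]) { if (miss < 0) miss = b; } else s -= val[b];
          if (!known[c]) { if (miss < 0) miss = c; } else s -= val[c];
          if (miss >= 0) set_var(miss, s);
        }
      }
    }
  };
  drain();
  // gauge completion for underdetermined components
  bool progress = true;
  while (progress) {
    progress = false;
    int pick = -1;
    for (int e = 0; e < ne && pick < 0; e++) {
      if (unk[e] >= 2) {
        int a = ti[e], b = n_theta + wi[e], c = n_theta + n_omega + ki[e];
        if (!known[a]) pick = a;
        else if (!known[b]) pick = b;
        else pick = c;
      }
    }
    if (pick >= 0) {
      set_var(pick, 0.0); n_gauged++;
      drain();
      progress = true;
    }
  }
  NumericVector lt(n_theta), lw(n_omega), lk(n_kappa);
  LogicalVector kt(n_theta), kw(n_omega), kk(n_kappa);
  for (int v = 0; v < n_theta; v++) { lt[v] = val[v]; kt[v] = known[v]; }
  for (int v = 0; v < n_omega; v++) { lw[v] = val[n_theta + v]; kw[v] = known[n_theta + v]; }
  for (int v = 0; v < n_kappa; v++) { lk[v] = val[n_theta + n_omega + v]; kk[v] = known[n_theta + n_omega + v]; }
  return List::create(_["ltheta"] = lt, _["lomega"] = lw, _["lkappa"] = lk,
                      _["known_theta"] = kt, _["known_omega"] = kw,
                      _["known_kappa"] = kk, _["n_gauged"] = n_gauged);
}
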