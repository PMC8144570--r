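#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-method Gillespie SSA for networks whose propensities flatten to
// sums of mass-action terms. Each term has a rate and a source complex; a
// reaction's propensity is the sum of its terms' alpha * falling factorials.
// Uses R's RNG (exp_rand / unif_rand) so set.seed() governs reproducibility.
//
// record: 0 = end state only
//         1 = full trajectory (times, states, reaction indices)
//         2 = change times and values of species `track` (plus end state)
//         3 = holding-time-weighted occupancy histogram of species `track`
//             for t > burn (length max_count + 1)
// [[Rcpp::export]]
List ssa_cpp(IntegerMatrix term_src, NumericVector term_rate,
             IntegerVector term_rxn, IntegerMatrix gamma,
             IntegerVector n0, double t_end, int record = 0,
             int track = 0, double burn = 0.0, int max_count = 4095,
             double max_events = 1e9) {
  const int nt = term_rate.size();
  const int d = n0.size();
  const int nr = gamma.nrow();
  std::vector<double> n(d);
  for (int i = 0; i < d; i++) n[i] = n0[i];
  // per-term nonzero source entries
  std::vector<std::vector<std::pair<int,int> > > tsrc(nt);
  for (int k = 0; k < nt; k++)
    for (int i = 0; i < d; i++)
      if (term_src(k, i) > 0) tsrc[k].push_back(std::make_pair(i, term_src(k, i)));

  std::vector<double> rec_t, rec_v;
  std::vector<int> rec_rxn;
  std::vector<std::vector<double> > rec_state;
  std::vector<double> occ(record == 3 ? max_count + 1 : 0, 0.0);

  double t = 0.0, events = 0.0;
  bool absorbed = false, capped = false;
  std::vector<double> a(nt);
  if (record == 1) {
    rec_t.push_back(0.0);
    rec_state.push_back(n);
    rec_rxn.push_back(NA_INTEGER);
  }
  if (record == 2) { rec_t.push_back(0.0); rec_v.push_back(n[track]); }

  while (t < t_end) {
    double a0 = 0.0;
    for (int k = 0; k < nt; k++) {
      double ak = term_rate[k];
      for (size_t j = 0; j < tsrc[k].size(); j++) {
        int i = tsrc[k][j].first, ord = tsrc[k][j].second;
        if (n[i] < ord) { ak = 0.0; break; }
        for (int q = 0; q < ord; q++) ak *= (n[i] - q);
      }
      a[k] = ak; a0 += ak;
    }
    if (a0 <= 0.0) { absorbed = true; break; }
    double dt = R::exp_rand() / a0;
    double t_next = t + dt;
    if (t_next > t_end) t_next = t_end;
    if (record == 3 && t_next > burn) {
      double lo = t > burn ? t : burn;
      int v = (int)n[track]; if (v > max_count) v = max_count;
      occ[v] += t_next - lo;
    }
    t += dt;
    if (t > t_end) break;
    double u = R::unif_rand() * a0, acc = 0.0;
    int pick = nt - 1;
    for (int k = 0; k < nt; k++) { acc += a[k]; if (u <= acc) { pick = k; break; } }
    int rxn = term_rxn[pick];
    for (int i = 0; i < d; i++) n[i] += gamma(rxn, i);
    events += 1.0;
    if (record == 1) {
      rec_t.push_back(t);
      rec_state.push_back(n);
      rec_rxn.push_back(rxn + 1);
    }
    if (record == 2) {
      if (rec_v.empty() || rec_v.back() != n[track]) {
        rec_t.push_back(t); rec_v.push_back(n[track]);
      }
    }
    if (events >= max_events) { capped = true; break; }
  }
  IntegerVector nend(d);
  for (int i = 0; i < d; i++) nend[i] = (int)n[i];
  List out = List::create(_["end_state"] = nend, _["t"] = t,
                          _["events"] = events, _["absorbed"] = absorbed,
                          _["capped"] = capped);
  if (record == 1) {
    NumericMatrix S(rec_state.size(), d);
    for (size_t r = 0; r < rec_state.size(); r++)
      for (int i = 0; i < d; i++) S(r, i) = rec_state[r][i];
    out["times"] = wrap(rec_t);
    out["states"] = S;
    out["reaction"] = wrap(rec_rxn);
  }
  if (record == 2) {
    out["times"] = wrap(rec_t);
    out["values"] = wrap(rec_v);
  }
  if (record == 3) out["occupancy"] = wrap(occ);
  return out;
}
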