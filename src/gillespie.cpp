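#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Outcome codes shared with the R wrappers:
// 0 = absorbed A, 1 = absorbed B, 2 = deadlock, 3 = censored (max_events hit)

// Mass-action propensity of one reaction: rate * falling-factorial product of
// reactant counts (n for a single molecule, n*(n-1) for two identical ones).
static inline double rxn_propensity(const int *reac, const int *state,
                                    int n_sp, double rate) {
  double a = rate;
  for (int s = 0; s < n_sp; ++s) {
    int c = reac[s];
    for (int k = 0; k < c; ++k) a *= (double)(state[s] - k);
    if (c > 0 && state[s] < c) return 0.0;
  }
  return a > 0.0 ? a : 0.0;
}

static inline bool predicate_holds(const IntegerVector &zero_idx,
                                   const std::vector<int> &state) {
  for (int i = 0; i < zero_idx.size(); ++i)
    if (state[zero_idx[i]] != 0) return false;
  return true;
}

// Simulate the embedded jump chain of a mass-action CRN until an absorbing
// predicate holds, the total propensity vanishes, or max_events is reached.
// reactants / net are n_rxn x n_sp count matrices; absorbing_A/absorbing_B are
// 0-based indices of species that must all be zero.
// [[Rcpp::export(name = ".gillespie_core")]]
List gillespie_core(IntegerMatrix reactants, IntegerMatrix net,
                    NumericVector rates, IntegerVector init,
                    IntegerVector absorbing_A, IntegerVector absorbing_B,
                    int max_events, bool record) {
  const int n_rxn = reactants.nrow();
  const int n_sp  = reactants.ncol();

  // row-major copies for cache-friendly access
  std::vector<int> reac(n_rxn * n_sp), dnet(n_rxn * n_sp);
  for (int r = 0; r < n_rxn; ++r)
    for (int s = 0; s < n_sp; ++s) {
      reac[r * n_sp + s] = reactants(r, s);
      dnet[r * n_sp + s] = net(r, s);
    }

  std::vector<int> state(init.begin(), init.end());
  std::vector<int> events;
  std::vector<int> traj;
  if (record) {
    traj.reserve(1024 * n_sp);
    traj.insert(traj.end(), state.begin(), state.end());
  }

  std::vector<double> a(n_rxn);
  int outcome = 3;
  int n_events = 0;

  for (;;) {
    if (predicate_holds(absorbing_A, state)) { outcome = 0; break; }
    if (predicate_holds(absorbing_B, state)) { outcome = 1; break; }
    if (n_events >= max_events) { outcome = 3; break; }

    double total = 0.0;
    for (int r = 0; r < n_rxn; ++r) {
      a[r] = rxn_propensity(&reac[r * n_sp], state.data(), n_sp, rates[r]);
      total += a[r];
    }
    if (total <= 0.0) { outcome = 2; break; }

    double u = unif_rand() * total;
    int chosen = n_rxn - 1;
    double acc = 0.0;
    for (int r = 0; r < n_rxn; ++r) {
      acc += a[r];
      if (u < acc) { chosen = r; break; }
    }

    for (int s = 0; s < n_sp; ++s) state[s] += dnet[chosen * n_sp + s];
    ++n_events;
    if (record) {
      events.push_back(chosen + 1);
      traj.insert(traj.end(), state.begin(), state.end());
    }
  }

  List out = List::create(
    _["outcome_code"] = outcome,
    _["n_events"]     = n_events,
    _["final_state"]  = IntegerVector(state.begin(), state.end()));
  if (record) {
    IntegerMatrix states((int)traj.size() / n_sp, n_sp);
    for (int i = 0; i < states.nrow(); ++i)
      for (int s = 0; s < n_sp; ++s) states(i, s) = traj[i * n_sp + s];
    out["states"] = states;
    out["reaction_indices"] = IntegerVector(events.begin(), events.end());
  }
  return out;
}

// Replicated outcome-only runs from a common initial state.
// [[Rcpp::export(name = ".gillespie_outcomes_core")]]
List gillespie_outcomes_core(IntegerMatrix reactants, IntegerMatrix net,
                             NumericVector rates, IntegerVector init,
                             IntegerVector absorbing_A,
                             IntegerVector absorbing_B,
                             int max_events, int n_runs) {
  const int n_rxn = reactants.nrow();
  const int n_sp  = reactants.ncol();
  std::vector<int> reac(n_rxn * n_sp), dnet(n_rxn * n_sp);
  for (int r = 0; r < n_rxn; ++r)
    for (int s = 0; s < n_sp; ++s) {
      reac[r * n_sp + s] = reactants(r, s);
      dnet[r * n_sp + s] = net(r, s);
    }

  IntegerVector outcomes(n_runs), lengths(n_runs);
  std::vector<double> a(n_rxn);
  std::vector<int> state(n_sp);

  for (int run = 0; run < n_runs; ++run) {
    std::copy(init.begin(), init.end(), state.begin());
    int outcome = 3, n_events = 0;
    for (;;) {
      if (predicate_holds(absorbing_A, state)) { outcome = 0; break; }
      if (predicate_holds(absorbing_B, state)) { outcome = 1; break; }
      if (n_events >= max_events) { outcome = 3; break; }
      double total = 0.0;
      for (int r = 0; r < n_rxn; ++r) {
        a[r] = rxn_propensity(&reac[r * n_sp], state.data(), n_sp, rates[r]);
        total += a[r];
      }
      if (total <= 0.0) { outcome = 2; break; }
      double u = unif_rand() * total;
      int chosen = n_rxn - 1;
      double acc = 0.0;
      for (int r = 0; r < n_rxn; ++r) {
        acc += a[r];
        if (u < acc) { chosen = r; break; }
      }
      for (int s = 0; s < n_sp; ++s) state[s] += dnet[chosen * n_sp + s];
      ++n_events;
    }
    outcomes[run] = outcome;
    lengths[run] = n_events;
  }
  return List::create(_["outcomes"] = outcomes, _["n_events"] = lengths);
}
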