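#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Millisecond-resolution cascade simulation.
//
// logq(i, j) = log(1 - p(j -> i)): log-probability that a spike of unit j
// fails to trigger unit i on the next step. Units are refractory for one
// step after each spike. Stimulus steps force the target units to fire
// (unless refractory). Uses the R RNG so set.seed() in R gives
// reproducibility.
// [[Rcpp::export]]
List cascade_sim_cpp(NumericMatrix logq, double spont_prob,
                     IntegerVector stim_steps, IntegerVector stim_targets,
                     int n_steps, int n_units) {
  std::vector<int> out_step;
  std::vector<int> out_unit;
  std::vector<char> fired(n_units, 0), refract(n_units, 0);
  std::vector<double> lp(n_units, 0.0);
  std::vector<int> fired_idx;
  fired_idx.reserve(n_units);

  // mark stimulus steps for O(1) lookup
  std::vector<char> is_stim(n_steps, 0);
  for (int k = 0; k < stim_steps.size(); ++k) {
    int s = stim_steps[k];
    if (s >= 0 && s < n_steps) is_stim[s] = 1;
  }

  for (int t = 0; t < n_steps; ++t) {
    // propagation pressure from last step's spikes
    bool any_lp = !fired_idx.empty();
    if (any_lp) {
      std::fill(lp.begin(), lp.end(), 0.0);
      for (size_t k = 0; k < fired_idx.size(); ++k) {
        int j = fired_idx[k];
        for (int i = 0; i < n_units; ++i) lp[i] += logq(i, j);
      }
    }
    std::vector<char> now(n_units, 0);
    for (int i = 0; i < n_units; ++i) {
      if (refract[i]) continue;
      double p_noise = spont_prob;
      double p = any_lp ? 1.0 - (1.0 - p_noise) * std::exp(lp[i]) : p_noise;
      if (p > 0.0 && unif_rand() < p) now[i] = 1;
    }
    if (is_stim[t]) {
      for (int k = 0; k < stim_targets.size(); ++k) {
        int i = stim_targets[k];
        if (!refract[i]) now[i] = 1;
      }
    }
    fired_idx.clear();
    for (int i = 0; i < n_units; ++i) {
      refract[i] = now[i];  // one refractory step after each spike
      if (now[i]) {
        fired_idx.push_back(i);
        out_step.push_back(t);
        out_unit.push_back(i);
      }
    }
  }
  return List::create(_["step"] = wrap(out_step), _["unit"] = wrap(out_unit));
}
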