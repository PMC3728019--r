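#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of the two-state (telegraph) transcription
// model for independent cells. Each cell runs a Gillespie chain of
// promoter switching (k_on, k_off), transcription while ON (k_tx) and
// first-order mRNA degradation (k_deg) from time 0 to t_end; the mRNA
// copy number at t_end is returned. The promoter is initialized from its
// stationary law and mRNA starts at zero, so t_end acts as the burn-in.
// Randomness comes from R's RNG, so set.seed() upstream makes runs
// reproducible.
// [[Rcpp::export(name = ".ssa_two_state")]]
IntegerVector ssa_two_state(int n_cells, double k_on, double k_off,
                            double k_tx, double k_deg, double t_end) {
  IntegerVector out(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    bool on = unif_rand() < k_on / (k_on + k_off);
    long m = 0;
    double t = 0.0;
    for (;;) {
      double r_switch = on ? k_off : k_on;
      double r_tx = on ? k_tx : 0.0;
      double r_deg = m * k_deg;
      double total = r_switch + r_tx + r_deg;
      t += exp_rand() / total;
      if (t > t_end) break;
      double u = unif_rand() * total;
      if (u < r_switch) {
        on = !on;
      } else if (u < r_switch + r_tx) {
        ++m;
      } else {
        --m;
      }
    }
    out[i] = (int)m;
  }
  return out;
}
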