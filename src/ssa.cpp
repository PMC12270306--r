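#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-method stochastic simulation of a mass-action reaction network.
// Propensities are recomputed after every firing; one reaction may be
// modulated by a piecewise-constant external input (the Spo0A~P level at
// the sinI promoter), refreshed on the input grid. Between refresh points
// the algorithm is exact.
//
// reactants / products: n_reactions x n_species stoichiometry (counts).
// rates: per-reaction constants, already on the count scale (1/h).
// input_reaction: 1-based index of the modulated reaction, 0 for none.
// record_times: increasing; state is snapshotted at each.
// Uses R's RNG (set.seed() upstream gives reproducibility).

struct SparseReaction {
  // reactant (species, order) pairs and net state changes
  std::vector<int> r_sp, r_ord;
  std::vector<int> d_sp, d_ch;
};

// [[Rcpp::export]]
IntegerMatrix ssa_run_cpp(IntegerMatrix reactants, IntegerMatrix products,
                          NumericVector rates, int input_reaction,
                          NumericVector input_times, NumericVector input_values,
                          NumericVector record_times, IntegerVector x0) {
  const int nr = reactants.nrow(), ns = reactants.ncol();
  if (products.nrow() != nr || products.ncol() != ns)
    stop("stoichiometry dimensions disagree");
  if (rates.size() != nr) stop("rates length != number of reactions");
  const int n_rec = record_times.size();
  IntegerMatrix out(n_rec, ns);

  std::vector<double> x(ns);
  for (int i = 0; i < ns; ++i) x[i] = x0[i];

  std::vector<SparseReaction> rx(nr);
  std::vector<double> k(nr);
  for (int j = 0; j < nr; ++j) {
    k[j] = rates[j];
    for (int i = 0; i < ns; ++i) {
      int nu = reactants(j, i);
      if (nu > 0) { rx[j].r_sp.push_back(i); rx[j].r_ord.push_back(nu); }
      int d = products(j, i) - nu;
      if (d != 0) { rx[j].d_sp.push_back(i); rx[j].d_ch.push_back(d); }
    }
  }

  const bool has_input = input_reaction > 0;
  const int jin = input_reaction - 1;
  const double k_in_base = has_input ? k[jin] : 0.0;
  int seg = 0;
  const int n_seg = input_times.size();
  double t = 0.0;
  int irec = 0;
  std::vector<double> a(nr);
  RNGScope scope;
  const double t_end = record_times[n_rec - 1];

  while (irec < n_rec) {
    if (has_input) {
      while (seg + 1 < n_seg && input_times[seg + 1] <= t + 1e-12) ++seg;
      k[jin] = k_in_base * input_values[seg];
    }
    double seg_end = t_end + 1.0;
    if (has_input && seg + 1 < n_seg) seg_end = input_times[seg + 1];

    // simulate exactly within [t, seg_end) with constant k
    while (true) {
      double a0 = 0.0;
      for (int j = 0; j < nr; ++j) {
        double aj = k[j];
        const SparseReaction& R = rx[j];
        for (size_t q = 0; q < R.r_sp.size(); ++q) {
          const double xv = x[R.r_sp[q]];
          const int nu = R.r_ord[q];
          if (nu == 1) aj *= xv;
          else if (nu == 2) aj *= 0.5 * xv * (xv - 1.0);
          else { double f = 1; for (int m = 0; m < nu; ++m) f *= (xv - m) / (m + 1.0); aj *= f; }
          if (aj <= 0) { aj = 0; break; }
        }
        a[j] = aj; a0 += aj;
      }
      double t_next = (a0 > 0) ? t + R::exp_rand() / a0 : seg_end;
      double t_stop = std::min(t_next, seg_end);
      while (irec < n_rec && record_times[irec] <= t_stop + 1e-12) {
        for (int i = 0; i < ns; ++i) out(irec, i) = (int)x[i];
        ++irec;
      }
      if (irec >= n_rec) return out;
      if (t_next >= seg_end) { t = seg_end; break; }  // refresh input
      // fire
      double r = unif_rand() * a0, cum = 0.0;
      int jf = nr - 1;
      for (int j = 0; j < nr; ++j) { cum += a[j]; if (r <= cum) { jf = j; break; } }
      const SparseReaction& R = rx[jf];
      for (size_t q = 0; q < R.d_sp.size(); ++q) {
        x[R.d_sp[q]] += R.d_ch[q];
        if (x[R.d_sp[q]] < 0) stop("negative count for species %d", R.d_sp[q] + 1);
      }
      t = t_next;
    }
  }
  return out;
}
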