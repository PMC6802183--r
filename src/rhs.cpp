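#include <Rcpp.h>
using namespace Rcpp;

// Flattened-network ODE right-hand side. The plan (built by network_plan())
// encodes every reaction as a law code, packed parameters, and index lists
// into the state vector. Negative state entries are floored at zero before
// rate evaluation (stiff-solver round-off); clamped species (oxygen) are
// overridden from the environment and get derivative zero.
//
// law codes: 1 mass_action, 2 degradation, 3 michaelis_menten,
//            4 atp_phospho, 5 vegf_synthesis, 6 vegf_binding
// par columns per reaction (6 rows):
//  1: kf | k | km   | k_prime | k_syn   | k1f
//  2: kr | - | vmax | vmax    | k_alpha | k1r
//  3: -  | - | kcat | kcat    | mrna0   | -
//  4: -  | - | -    | k_ab    | -       | -
//  5: -  | - | -    | k_m_atp | -       | -

// [[Rcpp::export]]
NumericVector rhs_compiled(List plan, NumericVector state, double atp,
                           NumericVector drugs, double o2) {
  const IntegerVector law = plan["law"];
  const NumericMatrix par = plan["par"];
  const IntegerVector drug_idx = plan["drug_idx"];   // 0 = none, else 1..4
  const IntegerVector enz_idx = plan["enz_idx"];     // 0 = none (also mrna idx)
  const IntegerVector r_off = plan["r_off"];
  const IntegerVector r_idx = plan["r_idx"];
  const NumericVector r_coef = plan["r_coef"];
  const IntegerVector p_off = plan["p_off"];
  const IntegerVector p_idx = plan["p_idx"];
  const NumericVector p_coef = plan["p_coef"];
  const IntegerVector clamped = plan["clamped"];

  const int n = state.size();
  const int m = law.size();
  NumericVector conc(n);
  for (int i = 0; i < n; ++i) conc[i] = state[i] > 0 ? state[i] : 0.0;
  for (int k = 0; k < clamped.size(); ++k) conc[clamped[k] - 1] = o2;

  NumericVector dx(n);
  for (int j = 0; j < m; ++j) {
    const double d = drug_idx[j] > 0 ? drugs[drug_idx[j] - 1] : 0.0;
    double v = 0.0;
    switch (law[j]) {
    case 1: { // mass action, optionally reversible
      double fwd = par(0, j);
      for (int k = r_off[j]; k < r_off[j + 1]; ++k)
        for (int c = 0; c < (int)r_coef[k]; ++c) fwd *= conc[r_idx[k] - 1];
      double rev = 0.0;
      if (par(1, j) != 0.0) {
        rev = par(1, j);
        for (int k = p_off[j]; k < p_off[j + 1]; ++k)
          for (int c = 0; c < (int)p_coef[k]; ++c) rev *= conc[p_idx[k] - 1];
      }
      v = fwd - rev;
      break;
    }
    case 2: // degradation
      v = par(0, j) * conc[r_idx[r_off[j]] - 1];
      break;
    case 3: { // Michaelis-Menten, enzyme optional
      const double s = conc[r_idx[r_off[j]] - 1];
      const double vmax = enz_idx[j] > 0 ? par(2, j) * conc[enz_idx[j] - 1]
                                         : par(1, j);
      v = vmax * s / (par(0, j) + s);
      break;
    }
    case 4: { // ATP-dependent phosphorylation (or original law if k_ab == 0)
      const double s = conc[r_idx[r_off[j]] - 1];
      const double vmax = enz_idx[j] > 0 ? par(2, j) * conc[enz_idx[j] - 1]
                                         : par(1, j);
      const double kab = par(3, j);
      if (kab == 0.0) {
        v = vmax * s / (par(0, j) * (1.0 + d) + s);
      } else {
        v = vmax * atp * s /
            (par(4, j) * kab * (1.0 + d) + kab * atp + atp * s);
      }
      break;
    }
    case 5: { // VEGF synthesis (constant if not yet coupled to mRNA)
      if (enz_idx[j] > 0 && par(2, j) > 0.0) {
        const double ratio = conc[enz_idx[j] - 1] / par(2, j);
        v = par(0, j) * std::pow(ratio, par(1, j));
      } else {
        v = par(0, j);
      }
      break;
    }
    case 6: { // VEGF-receptor binding
      const double ligand = conc[r_idx[r_off[j]] - 1];
      const double receptor = conc[r_idx[r_off[j] + 1] - 1];
      const double complex_ = conc[p_idx[p_off[j]] - 1];
      v = par(0, j) * ligand * receptor / (1.0 + d) - par(1, j) * complex_;
      break;
    }
    }
    for (int k = r_off[j]; k < r_off[j + 1]; ++k)
      dx[r_idx[k] - 1] -= r_coef[k] * v;
    for (int k = p_off[j]; k < p_off[j + 1]; ++k)
      dx[p_idx[k] - 1] += p_coef[k] * v;
  }
  for (int k = 0; k < clamped.size(); ++k) dx[clamped[k] - 1] = 0.0;
  return dx;
}
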