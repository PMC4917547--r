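#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integration of the per-cell receptor-trafficking system,
// batched over cells (rows of S). Column layout must match MOL_NSTATE in
// R/molecular.R: R, C_s, C_i, A, A_cum, U, Ldeg, Lsec, T_local.
// kon is per-cell; P is the frozen local PGE2; omega converts molecules to
// ng/ml in the cell's voxel (0 disables local depletion).

struct MolPar {
  double v_R, k_off, k_int, k_rec, k_degC, k_tR, K_S, K_P,
         k_synA, k_degA, k_synL, b0, a_max;
};

static inline void deriv(const double *s, double P, double kon,
                         const MolPar &p, double omega, double *d) {
  double bind = kon * s[8] * s[0];
  double diss = p.k_off * s[1];
  double Ssig = s[2] / (s[2] + p.K_S);
  double I_P = 1.0 / (1.0 + P / p.K_P);
  double head = 1.0 - s[3] / p.a_max;
  if (head < 0) head = 0;
  double synA = p.k_synA * Ssig * I_P * head;
  d[0] = p.v_R + p.k_rec * s[2] - bind + diss - p.k_tR * s[0];
  d[1] = bind - diss - p.k_int * s[1];
  d[2] = p.k_int * s[1] - (p.k_rec + p.k_degC) * s[2];
  d[3] = synA - p.k_degA * s[3];
  d[4] = synA;
  d[5] = bind - diss;
  d[6] = (p.k_rec + p.k_degC) * s[2];
  d[7] = p.k_synL * (p.b0 + (1.0 - p.b0) * Ssig) * I_P;
  d[8] = -(bind - diss) * omega;
}

// [[Rcpp::export]]
NumericMatrix mol_rk4_cpp(NumericMatrix S, NumericVector P, NumericVector kon,
                          NumericVector par, double dt, int n_sub,
                          double omega) {
  MolPar p = {par[0], par[1], par[2], par[3], par[4], par[5], par[6], par[7],
              par[8], par[9], par[10], par[11], par[12]};
  int n = S.nrow();
  const int m = 9;
  NumericMatrix out = clone(S);
  double h = dt / n_sub;
  double s0[m], st[m], k1[m], k2[m], k3[m], k4[m];
  for (int c = 0; c < n; ++c) {
    for (int q = 0; q < m; ++q) s0[q] = out(c, q);
    for (int step = 0; step < n_sub; ++step) {
      deriv(s0, P[c], kon[c], p, omega, k1);
      for (int q = 0; q < m; ++q) st[q] = s0[q] + 0.5 * h * k1[q];
      deriv(st, P[c], kon[c], p, omega, k2);
      for (int q = 0; q < m; ++q) st[q] = s0[q] + 0.5 * h * k2[q];
      deriv(st, P[c], kon[c], p, omega, k3);
      for (int q = 0; q < m; ++q) st[q] = s0[q] + h * k3[q];
      deriv(st, P[c], kon[c], p, omega, k4);
      for (int q = 0; q < m; ++q) {
        s0[q] += h / 6.0 * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);
        if (s0[q] < 0 && s0[q] > -1e-9) s0[q] = 0;
      }
    }
    for (int q = 0; q < m; ++q) out(c, q) = s0[q];
  }
  return out;
}
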