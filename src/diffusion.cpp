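#include <Rcpp.h>
using namespace Rcpp;

// 3D lattice index helper: column-major, i fastest (matches R array layout)
static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// One explicit FTCS step of the 7-point diffusion stencil with reflecting
// (no-flux) boundaries. alpha = D * dt / dx^2 must satisfy alpha <= 1/6 for
// stability; the caller is responsible for checking.
// [[Rcpp::export]]
NumericVector ftcs_step_cpp(NumericVector conc, int nx, int ny, int nz,
                            double alpha) {
  NumericVector out(conc.size());
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int c = idx3(i, j, k, nx, ny);
        double u = conc[c];
        double lap = 0.0;
        // reflecting boundary: missing neighbour contributes zero flux
        lap += (i > 0      ? conc[c - 1]       : u) - u;
        lap += (i < nx - 1 ? conc[c + 1]       : u) - u;
        lap += (j > 0      ? conc[c - nx]      : u) - u;
        lap += (j < ny - 1 ? conc[c + nx]      : u) - u;
        lap += (k > 0      ? conc[c - nx * ny] : u) - u;
        lap += (k < nz - 1 ? conc[c + nx * ny] : u) - u;
        out[c] = u + alpha * lap;
      }
    }
  }
  return out;
}

// Precompute Thomas coefficients for (I - alpha * L1d) with the 1D Neumann
// Laplacian (end rows degree 1, interior degree 2). The matrix is symmetric
// and diagonally dominant; its column sums are 1, so each sweep conserves
// the line sum exactly.
static void thomas_coef(int n, double alpha, std::vector<double> &cp,
                        std::vector<double> &minv) {
  double b0 = 1.0 + alpha, bi = 1.0 + 2.0 * alpha, a = -alpha;
  cp.resize(n); minv.resize(n);
  minv[0] = 1.0 / b0;
  cp[0] = a * minv[0];
  for (int i = 1; i < n; ++i) {
    double diag = (i == n - 1) ? b0 : bi;
    double m = diag - a * cp[i - 1];
    minv[i] = 1.0 / m;
    cp[i] = a * minv[i];
  }
}

// One implicit dimensional-split (Lie) backward-Euler diffusion step:
// sequentially solves (I - alpha Lx), (I - alpha Ly), (I - alpha Lz).
// Unconditionally stable, mass-conserving, never produces negatives.
// Sweeps are batched so all memory access is in storage order.
// [[Rcpp::export]]
NumericVector adi_step_cpp(NumericVector conc, int nx, int ny, int nz,
                           double alpha) {
  NumericVector out = clone(conc);
  double *p = REAL(out);
  double a = -alpha;
  std::vector<double> cp, minv;
  // x sweeps: lines contiguous in memory
  if (nx > 1) {
    thomas_coef(nx, alpha, cp, minv);
    for (int l = 0; l < ny * nz; ++l) {
      double *x = p + (R_xlen_t)l * nx;
      x[0] *= minv[0];
      for (int i = 1; i < nx; ++i) x[i] = (x[i] - a * x[i - 1]) * minv[i];
      for (int i = nx - 2; i >= 0; --i) x[i] -= cp[i] * x[i + 1];
    }
  }
  // y sweeps: batch across i (contiguous rows of length nx)
  if (ny > 1) {
    thomas_coef(ny, alpha, cp, minv);
    for (int k = 0; k < nz; ++k) {
      double *s = p + (R_xlen_t)k * nx * ny;
      for (int i = 0; i < nx; ++i) s[i] *= minv[0];
      for (int j = 1; j < ny; ++j) {
        double *row = s + (R_xlen_t)j * nx, *prev = row - nx;
        for (int i = 0; i < nx; ++i) row[i] = (row[i] - a * prev[i]) * minv[j];
      }
      for (int j = ny - 2; j >= 0; --j) {
        double *row = s + (R_xlen_t)j * nx, *next = row + nx;
        for (int i = 0; i < nx; ++i) row[i] -= cp[j] * next[i];
      }
    }
  }
  // z sweeps: batch across whole layers (contiguous blocks of nx*ny)
  if (nz > 1) {
    thomas_coef(nz, alpha, cp, minv);
    R_xlen_t L = (R_xlen_t)nx * ny;
    for (R_xlen_t q = 0; q < L; ++q) p[q] *= minv[0];
    for (int k = 1; k < nz; ++k) {
      double *lay = p + k * L, *prev = lay - L;
      for (R_xlen_t q = 0; q < L; ++q) lay[q] = (lay[q] - a * prev[q]) * minv[k];
    }
    for (int k = nz - 2; k >= 0; --k) {
      double *lay = p + k * L, *next = lay + L;
      for (R_xlen_t q = 0; q < L; ++q) lay[q] -= cp[k] * next[q];
    }
  }
  return out;
}
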