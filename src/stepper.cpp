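// Explicit finite-difference time stepper for the nonlinear axisymmetric
// heat equation.
//
// Update rule (five-point stencil, forward Euler, cell-centered grid):
//   T'   = T + dt * [ (k+z (Tdn - T) + k-z (Tup - T)) / dz^2
//                   + (k+r r+ (Trt - T) + k-r r- (Tlf - T)) / (r dr^2) ] / C
// where k± are harmonic-mean pair conductivities, C = rho(T) * Cp_eff(T),
// and r± are the half-shifted radii.  The conductivity field is refreshed
// from the current temperatures before every update (two-pass scheme), and
// fixed nodes (cryoapplicator during freezing, the deep bath row) are
// skipped, not overwritten, so their outgoing fluxes stay physical.
//
// Material properties arrive as dense lookup tables (uniform temperature
// grid, linear interpolation) precomputed in R from the piecewise property
// formulas of the material library; the table resolution (0.01 degC) keeps
// the interpolation error orders of magnitude below the uncertainty of the
// property data while letting the kernel run at memory speed.  Pair
// conductivities are computed once per pair and shared by both neighbours.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Lut {
  double lo, inv_step;
  int n;
  const double* v;
  // mirror of the R-side interpolation in lut_eval(): clamped linear interp.
  // The guards also keep the index finite for NaN/Inf temperatures (a
  // diverging run), so the caller can detect the non-finite field safely.
  double eval(double T) const {
    double x = (T - lo) * inv_step;
    if (!(x > 0.0)) x = 0.0;
    if (x > (double)(n - 1)) x = (double)(n - 1);
    int i = (int)x;
    if (i > n - 2) i = n - 2;
    double frac = x - i;
    if (frac > 1.0) frac = 1.0;
    return v[i] + (v[i + 1] - v[i]) * frac;
  }
};

struct Material {
  Lut k, invC;
};

std::vector<Material> parse_materials(List mats) {
  std::vector<Material> out;
  for (int m = 0; m < mats.size(); ++m) {
    List mm = mats[m];
    Material M;
    NumericVector kv = mm["k_lut"], cv = mm["invC_lut"];
    M.k.lo = M.invC.lo = as<double>(mm["lut_lo"]);
    M.k.inv_step = M.invC.inv_step = as<double>(mm["lut_inv_step"]);
    M.k.n = kv.size();
    M.invC.n = cv.size();
    M.k.v = REAL(kv);
    M.invC.v = REAL(cv);
    out.push_back(M);
  }
  return out;
}

inline double harm(double k1, double k2) {
  double s = k1 + k2;
  return s > 0.0 ? 2.0 * k1 * k2 / s : 0.0;
}

} // namespace

// Advance the temperature field by nsteps explicit steps (in place).
// T: (nz x nr) storage incl. ghost contour; mat: material index per node
// (0 = ghost/void, else 1-based index into `materials`); fixed: nodes whose
// temperature is never updated; r, rp, rm: cell-center and half-shifted
// radii per storage column (ghost entries unused).  `materials` carries the
// lookup tables built by kernel_materials() in R.
// [[Rcpp::export]]
NumericMatrix step_chunk_cpp(NumericMatrix T, IntegerMatrix mat,
                             LogicalMatrix fixed,
                             NumericVector r, NumericVector rp,
                             NumericVector rm,
                             double dz, double dr, double dt, int nsteps,
                             List materials) {
  const int nz = T.nrow(), nr = T.ncol();
  const size_t n_tot = (size_t)nz * nr;
  std::vector<Material> mats = parse_materials(materials);
  std::vector<double> A(T.begin(), T.end()), B(A), K(n_tot, 0.0),
    KZ(n_tot, 0.0), KR(n_tot, 0.0);
  const int* Mm = INTEGER(mat);
  const int* Fx = LOGICAL(fixed);
  const double inv_dz2 = 1.0 / (dz * dz);
  const double inv_dr2 = 1.0 / (dr * dr);

  double* a = A.data();
  double* b = B.data();
  for (int s = 0; s < nsteps; ++s) {
    // pass 1: refresh the conductivity field from the current temperatures
    for (size_t idx = 0; idx < n_tot; ++idx) {
      int m = Mm[idx];
      K[idx] = m > 0 ? mats[m - 1].k.eval(a[idx]) : 0.0;
    }
    // pass 2: harmonic-mean pair conductivities, one per node pair
    // KZ[idx]: between (i, j) and (i+1, j); KR[idx]: between (i, j) and
    // (i, j+1).  Ghost pairs vanish via the zero-conductivity convention.
    for (size_t idx = 0; idx + 1 < n_tot; ++idx)
      KZ[idx] = harm(K[idx], K[idx + 1]);
    for (size_t idx = 0; idx + nz < n_tot; ++idx)
      KR[idx] = harm(K[idx], K[idx + nz]);
    // pass 3: five-point update of every non-fixed material node
    for (int j = 1; j < nr - 1; ++j) {
      const double rpj = rp[j], rmj = rm[j];
      const double rad_w = inv_dr2 / r[j];
      const size_t col = (size_t)j * nz;
      for (int i = 1; i < nz - 1; ++i) {
        const size_t idx = col + i;
        const int m = Mm[idx];
        if (m == 0 || Fx[idx]) { b[idx] = a[idx]; continue; }
        const double Tij = a[idx];
        const double num =
          (KZ[idx] * (a[idx + 1] - Tij) + KZ[idx - 1] * (a[idx - 1] - Tij)) *
            inv_dz2 +
          (KR[idx] * rpj * (a[idx + nz] - Tij) +
           KR[idx - nz] * rmj * (a[idx - nz] - Tij)) * rad_w;
        b[idx] = Tij + dt * num * mats[m - 1].invC.eval(Tij);
      }
    }
    std::swap(a, b);
  }
  std::copy(a, a + n_tot, T.begin());
  return T;
}

// Interpolate a lookup table exactly as the kernel does -- used by tests to
// confirm the R mirror (lut_eval) is bit-identical.
// [[Rcpp::export]]
NumericVector lut_eval_cpp(NumericVector values, double lo, double inv_step,
                           NumericVector T) {
  Lut L;
  L.lo = lo;
  L.inv_step = inv_step;
  L.n = values.size();
  L.v = REAL(values);
  NumericVector out(T.size());
  for (int i = 0; i < T.size(); ++i) out[i] = L.eval(T[i]);
  return out;
}
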