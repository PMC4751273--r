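#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Explicit forward-Euler update of the coupled two-compartment transport
// model on a uniform grid (column-major storage, x index fastest).
//
// ECS field c:  dc/dt = div(D grad c) - div_upwind(u c) - k c
//   * diffusion in flux form with face coefficients fe/fn (zero faces act
//     as no-flux walls, both at the domain edge and at the needle);
//   * first-order upwind advection in flux form (face velocity = mean of
//     the two adjacent cell velocities; faces to inactive cells carry no
//     flux, so tracer accumulates at downstream boundaries);
//   * the tensor cross-component Dxy (rotated white-matter fibers) is
//     discretized as d/dx(Dxy dc/dy) + d/dy(Dxy dc/dx) with centered
//     derivatives averaged to faces.
//
// Membrane field cb:  dcb/dt = -div_upwind(ub cb) + k c   (no diffusion)
//
// The injected concentration is prescribed on the inflow cells: c = c0
// while t <= t_inject, afterwards c = 0 (post_mode 0, the literal
// injection schedule) or left free (post_mode 1, no-flux).
//
// Returns the advanced fields, the reached time, and a status flag
// (0 ok, 1 divergence: non-finite value or |value| > blow).

// [[Rcpp::export]]
List advance_fields_cpp(NumericMatrix c_in, NumericMatrix cb_in,
                        NumericMatrix fe_in, NumericMatrix fn_in,
                        NumericMatrix dxy_in,
                        NumericMatrix ux_in, NumericMatrix uy_in,
                        NumericMatrix ubx_in, NumericMatrix uby_in,
                        NumericMatrix kup_in,
                        LogicalMatrix ecs_in, LogicalMatrix mem_in,
                        IntegerVector inflow, double c0, double t_inject,
                        int post_mode, double dx, double dt, int nsteps,
                        double t0, double blow,
                        bool use_cross, bool use_ecs_adv, bool use_mem_adv) {
  const int nx = c_in.nrow(), ny = c_in.ncol();
  const R_xlen_t n = (R_xlen_t)nx * ny;
  NumericMatrix cA = clone(c_in), cbA = clone(cb_in);
  NumericMatrix cB(nx, ny), cbB(nx, ny);
  std::vector<double> Fx(n, 0.0), Fy(n, 0.0), Bx(n, 0.0), By(n, 0.0);
  std::vector<double> Gx, Gy, cxg, cyg;
  if (use_cross) {
    Gx.assign(n, 0.0); Gy.assign(n, 0.0);
    cxg.assign(n, 0.0); cyg.assign(n, 0.0);
  }

  const double *fe = REAL(fe_in), *fn = REAL(fn_in), *dxy = REAL(dxy_in);
  const double *ux = REAL(ux_in), *uy = REAL(uy_in);
  const double *ubx = REAL(ubx_in), *uby = REAL(uby_in);
  const double *kup = REAL(kup_in);
  const int *ecs = LOGICAL(ecs_in), *mem = LOGICAL(mem_in);

  double *c = REAL(cA), *cb = REAL(cbA), *cn = REAL(cB), *cbn = REAL(cbB);
  // which SEXP currently holds the state (for returning after swaps)
  bool stateInA = true;

  const double inv_dx = 1.0 / dx;
  const double inv_dx2 = 1.0 / (dx * dx);
  double t = t0;
  int status = 0;
  double t_fail = NA_REAL;

  for (int s = 0; s < nsteps; ++s) {
    if (use_ecs_adv) {
      for (int j = 0; j < ny; ++j) {
        R_xlen_t o = (R_xlen_t)j * nx;
        for (int i = 0; i < nx; ++i) {
          R_xlen_t k = o + i;
          double fx = 0.0, fy = 0.0;
          if (i + 1 < nx && ecs[k] && ecs[k + 1]) {
            double uf = 0.5 * (ux[k] + ux[k + 1]);
            fx = uf >= 0 ? uf * c[k] : uf * c[k + 1];
          }
          if (j + 1 < ny && ecs[k] && ecs[k + nx]) {
            double uf = 0.5 * (uy[k] + uy[k + nx]);
            fy = uf >= 0 ? uf * c[k] : uf * c[k + nx];
          }
          Fx[k] = fx;
          Fy[k] = fy;
        }
      }
    }
    if (use_mem_adv) {
      for (int j = 0; j < ny; ++j) {
        R_xlen_t o = (R_xlen_t)j * nx;
        for (int i = 0; i < nx; ++i) {
          R_xlen_t k = o + i;
          double fx = 0.0, fy = 0.0;
          if (i + 1 < nx && mem[k] && mem[k + 1]) {
            double uf = 0.5 * (ubx[k] + ubx[k + 1]);
            fx = uf >= 0 ? uf * cb[k] : uf * cb[k + 1];
          }
          if (j + 1 < ny && mem[k] && mem[k + nx]) {
            double uf = 0.5 * (uby[k] + uby[k + nx]);
            fy = uf >= 0 ? uf * cb[k] : uf * cb[k + nx];
          }
          Bx[k] = fx;
          By[k] = fy;
        }
      }
    }
    if (use_cross) {
      for (int j = 0; j < ny; ++j) {
        R_xlen_t o = (R_xlen_t)j * nx;
        for (int i = 0; i < nx; ++i) {
          R_xlen_t k = o + i;
          double gx = 0.0, gy = 0.0;
          if (ecs[k]) {
            if (i > 0 && i + 1 < nx && ecs[k - 1] && ecs[k + 1])
              gx = 0.5 * inv_dx * (c[k + 1] - c[k - 1]);
            if (j > 0 && j + 1 < ny && ecs[k - nx] && ecs[k + nx])
              gy = 0.5 * inv_dx * (c[k + nx] - c[k - nx]);
          }
          cxg[k] = gx;
          cyg[k] = gy;
        }
      }
      for (int j = 0; j < ny; ++j) {
        R_xlen_t o = (R_xlen_t)j * nx;
        for (int i = 0; i < nx; ++i) {
          R_xlen_t k = o + i;
          double gx = 0.0, gy = 0.0;
          if (i + 1 < nx && ecs[k] && ecs[k + 1])
            gx = 0.25 * (dxy[k] + dxy[k + 1]) * (cyg[k] + cyg[k + 1]);
          if (j + 1 < ny && ecs[k] && ecs[k + nx])
            gy = 0.25 * (dxy[k] + dxy[k + nx]) * (cxg[k] + cxg[k + nx]);
          Gx[k] = gx;
          Gy[k] = gy;
        }
      }
    }

    double maxabs = 0.0;
    for (int j = 0; j < ny; ++j) {
      R_xlen_t o = (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) {
        R_xlen_t k = o + i;
        double vnew, bnew;
        if (!ecs[k]) {
          vnew = 0.0;
        } else {
          double v = c[k];
          double diff =
              fe[k] * ((i + 1 < nx ? c[k + 1] : v) - v) -
              (i > 0 ? fe[k - 1] * (v - c[k - 1]) : 0.0) +
              fn[k] * ((j + 1 < ny ? c[k + nx] : v) - v) -
              (j > 0 ? fn[k - nx] * (v - c[k - nx]) : 0.0);
          double dcdt = diff * inv_dx2 - kup[k] * v;
          if (use_ecs_adv)
            dcdt -= inv_dx * (Fx[k] - (i > 0 ? Fx[k - 1] : 0.0) +
                              Fy[k] - (j > 0 ? Fy[k - nx] : 0.0));
          if (use_cross)
            dcdt += inv_dx * (Gx[k] - (i > 0 ? Gx[k - 1] : 0.0) +
                              Gy[k] - (j > 0 ? Gy[k - nx] : 0.0));
          vnew = v + dt * dcdt;
        }
        if (!mem[k]) {
          bnew = 0.0;
        } else {
          double dbdt = kup[k] * c[k];
          if (use_mem_adv)
            dbdt -= inv_dx * (Bx[k] - (i > 0 ? Bx[k - 1] : 0.0) +
                              By[k] - (j > 0 ? By[k - nx] : 0.0));
          bnew = cb[k] + dt * dbdt;
        }
        cn[k] = vnew;
        cbn[k] = bnew;
        double a1 = std::fabs(vnew), a2 = std::fabs(bnew);
        if (a1 > maxabs) maxabs = a1;
        if (a2 > maxabs) maxabs = a2;
      }
    }

    t = t0 + (s + 1) * dt;

    if (!(maxabs <= blow)) { // catches NaN as well
      status = 1;
      t_fail = t;
      break;
    }

    if (inflow.size() > 0) {
      if (t <= t_inject + 1e-9) {
        for (int q = 0; q < inflow.size(); ++q) cn[inflow[q] - 1] = c0;
      } else if (post_mode == 0) {
        for (int q = 0; q < inflow.size(); ++q) cn[inflow[q] - 1] = 0.0;
      }
    }

    std::swap(c, cn);
    std::swap(cb, cbn);
    stateInA = !stateInA;
  }

  return List::create(
    _["c"] = stateInA ? cA : cB,
    _["cb"] = stateInA ? cbA : cbB,
    _["t"] = t, _["status"] = status, _["t_fail"] = t_fail
  );
}
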