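// Core numerical kernels:
//  - stair-step masking of analytic solids on a rectilinear grid
//  - artificial-compressibility solver for steady / time-marched
//    incompressible laminar flow in a periodic unit cell (staggered grid,
//    local pseudo-time stepping, minmod-limited second-order upwind
//    advection, low-Reynolds preconditioned artificial sound speed)
//  - trilinear velocity interpolation (periodic in x)
//  - Euler-Maruyama agent transport with continuous segment capture tests
//
// All solver quantities are nondimensional: lengths in cylinder diameters,
// velocities in units of the inlet speed. The R wrappers handle scaling.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

// positive modulo without fmod (avoids a glibc>=2.38 versioned symbol)
static inline double pmod(double x, double m) {
  double r = x - std::floor(x / m) * m;
  if (r >= m) r -= m;
  if (r < 0) r = 0;
  return r;
}

// ---------------------------------------------------------------------------
// masking
// ---------------------------------------------------------------------------

// Cell is solid when its center lies inside a solid. Solids thinner than the
// local grid are inflated to `inflate` times the local max spacing so that
// sub-grid features (polyp tentacles) still block at least one cell.
// [[Rcpp::export]]
IntegerVector gf_mask_cells(NumericVector xc, NumericVector yc, NumericVector zc,
                            NumericVector hx, NumericVector hy, NumericVector hz,
                            double cell_width,
                            NumericMatrix cyl, NumericMatrix cap,
                            double inflate) {
  const int nx = xc.size(), ny = yc.size(), nz = zc.size();
  IntegerVector out(nx * ny * nz);
  const double w = cell_width;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const double hloc = std::max(hx[i], std::max(hy[j], hz[k]));
        const double x = xc[i], y = yc[j], z = zc[k];
        int solid = 0;
        for (int s = 0; s < cyl.nrow() && !solid; ++s) {
          const double reff = std::max(cyl(s, 2), inflate * hloc);
          if (z < cyl(s, 3) || z > cyl(s, 4)) continue;
          double dx0 = x - cyl(s, 0);
          dx0 -= w * std::round(dx0 / w);  // nearest periodic image
          if (sq(dx0) + sq(y - cyl(s, 1)) <= sq(reff)) solid = 1;
        }
        for (int s = 0; s < cap.nrow() && !solid; ++s) {
          const double reff = std::max(cap(s, 6), inflate * hloc);
          const double ax = cap(s, 0), ay = cap(s, 1), az = cap(s, 2);
          double bx = cap(s, 3) - ax, by = cap(s, 4) - ay, bz = cap(s, 5) - az;
          double dx0 = x - ax;
          dx0 -= w * std::round(dx0 / w);
          const double py = y - ay, pz = z - az;
          const double bb = bx * bx + by * by + bz * bz;
          double t = bb > 0 ? (dx0 * bx + py * by + pz * bz) / bb : 0.0;
          t = std::min(std::max(t, 0.0), 1.0);
          const double d2 = sq(dx0 - t * bx) + sq(py - t * by) + sq(pz - t * bz);
          if (d2 <= sq(reff)) solid = 1;
        }
        out[i + nx * (j + (R_xlen_t)ny * k)] = solid;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// flow solver
// ---------------------------------------------------------------------------

static inline double mm2(double a, double b) {
  if (a * b <= 0.0) return 0.0;
  return std::fabs(a) < std::fabs(b) ? a : b;
}

// limited second-order upwind derivative at the point carrying q0;
// takes reciprocal spacings and precomputed blend factors f = h/(h + h_next)
static inline double dlim(double a,
                          double qmm, double qm, double q0, double qp, double qpp,
                          double ihmm, double ihm, double fm,
                          double ihp, double ihpp, double fp,
                          bool okm, bool okp) {
  if (a >= 0.0) {
    const double s1 = (q0 - qm) * ihm;
    double c = 0.0;
    if (okm) c = (s1 - (qm - qmm) * ihmm) * fm;
    return s1 + mm2(c, 0.5 * s1);
  } else {
    const double s1 = (qp - q0) * ihp;
    double c = 0.0;
    if (okp) c = (s1 - (qpp - qp) * ihpp) * fp;
    return s1 + mm2(c, 0.5 * s1);
  }
}

// [[Rcpp::export]]
List gf_solve(int nx, int ny, int nz, double dx,
              NumericVector dyv, NumericVector dzv,
              IntegerVector mask, double nu,
              double tol, int max_iter, double cfl,
              int mode, double total_time, int check_every, bool verbose,
              NumericVector init_u, NumericVector init_v,
              NumericVector init_w, NumericVector init_p, double pdiss,
              double beta_k, double adv_scale, double stall_factor) {
  const int NX = nx + 2, NY = ny + 3, NZ = nz + 3;
  const R_xlen_t size = (R_xlen_t)NX * NY * NZ;
  auto id = [NX, NY](int i, int j, int k) -> R_xlen_t {
    return i + (R_xlen_t)NX * (j + (R_xlen_t)NY * k);
  };

  // cell widths with ghosts
  std::vector<double> dy(ny + 3), dz(nz + 3);
  for (int j = 1; j <= ny; ++j) dy[j] = dyv[j - 1];
  dy[0] = dy[1]; dy[ny + 1] = dy[ny]; dy[ny + 2] = dy[ny];
  for (int k = 1; k <= nz; ++k) dz[k] = dzv[k - 1];
  dz[0] = dz[1]; dz[nz + 1] = dz[nz]; dz[nz + 2] = dz[nz];
  // center-to-center distances (index f = distance between centers f-1 and f)
  std::vector<double> dyc(ny + 3), dzc(nz + 3);
  for (int j = 1; j <= ny + 2; ++j) dyc[j] = 0.5 * (dy[j - 1] + dy[j]);
  dyc[0] = dyc[1];
  for (int k = 1; k <= nz + 2; ++k) dzc[k] = 0.5 * (dz[k - 1] + dz[k]);
  dzc[0] = dzc[1];

  // precomputed reciprocals and second-order upwind blend factors
  const double ihx = 1.0 / dx;
  const double dx2 = ihx * ihx;
  std::vector<double> idy(ny + 3), idyc(ny + 3), idz(nz + 3), idzc(nz + 3);
  for (int j = 0; j <= ny + 2; ++j) { idy[j] = 1.0 / dy[j]; idyc[j] = 1.0 / dyc[j]; }
  for (int k = 0; k <= nz + 2; ++k) { idz[k] = 1.0 / dz[k]; idzc[k] = 1.0 / dzc[k]; }
  // at cell-center positions (u,w along y; u,v along z): spacings are dyc/dzc
  std::vector<double> fm_cy(ny + 2), fp_cy(ny + 2), fm_cz(nz + 2), fp_cz(nz + 2);
  for (int j = 1; j <= ny + 1; ++j) {
    fm_cy[j] = dyc[j] / (dyc[j] + dyc[j - 1]);
    fp_cy[j] = dyc[j + 1] / (dyc[j + 1] + dyc[std::min(j + 2, ny + 2)]);
  }
  for (int k = 1; k <= nz + 1; ++k) {
    fm_cz[k] = dzc[k] / (dzc[k] + dzc[k - 1]);
    fp_cz[k] = dzc[k + 1] / (dzc[k + 1] + dzc[std::min(k + 2, nz + 2)]);
  }
  // at face positions (v along y; w along z): spacings are dy/dz
  std::vector<double> fm_fy(ny + 2), fp_fy(ny + 2), fm_fz(nz + 2), fp_fz(nz + 2);
  for (int j = 1; j <= ny + 1; ++j) {
    fm_fy[j] = dy[j - 1] / (dy[j - 1] + dy[std::max(j - 2, 0)]);
    fp_fy[j] = dy[j] / (dy[j] + dy[std::min(j + 1, ny + 2)]);
  }
  for (int k = 1; k <= nz + 1; ++k) {
    fm_fz[k] = dz[k - 1] / (dz[k - 1] + dz[std::max(k - 2, 0)]);
    fp_fz[k] = dz[k] / (dz[k] + dz[std::min(k + 1, nz + 2)]);
  }

  // solid mask with ghosts (periodic in x, fluid elsewhere)
  std::vector<signed char> msk(size, 0);
  for (int k = 1; k <= nz; ++k)
    for (int j = 1; j <= ny; ++j)
      for (int i = 1; i <= nx; ++i)
        msk[id(i, j, k)] =
          (signed char)mask[(i - 1) + (R_xlen_t)nx * ((j - 1) + (R_xlen_t)ny * (k - 1))];
  for (int k = 0; k <= nz + 1; ++k)
    for (int j = 0; j <= ny + 1; ++j) {
      msk[id(0, j, k)] = msk[id(nx, j, k)];
      msk[id(nx + 1, j, k)] = msk[id(1, j, k)];
    }

  std::vector<double> u(size, 0.0), v(size, 0.0), w(size, 0.0), p(size, 0.0);
  std::vector<double> u2(size, 0.0), v2(size, 0.0), w2(size, 0.0);
  std::vector<double> dtc(size, 0.0), betac(size, 0.0), csc(size, 0.0);

  // initial condition: supplied cell-centered guess, else uniform inflow
  const bool has_init = init_u.size() == (R_xlen_t)nx * ny * nz;
  auto cidx = [nx, ny](int i, int j, int k) -> R_xlen_t {
    return (i - 1) + (R_xlen_t)nx * ((j - 1) + (R_xlen_t)ny * (k - 1));
  };
  if (has_init) {
    for (int k = 1; k <= nz; ++k)
      for (int j = 1; j <= ny; ++j)
        for (int i = 1; i <= nx; ++i) {
          const int im = (i == 1) ? nx : i - 1;
          if (!msk[id(i - 1, j, k)] && !msk[id(i, j, k)])
            u[id(i, j, k)] = 0.5 * (init_u[cidx(im, j, k)] + init_u[cidx(i, j, k)]);
          if (j >= 2 && !msk[id(i, j - 1, k)] && !msk[id(i, j, k)])
            v[id(i, j, k)] = 0.5 * (init_v[cidx(i, j - 1, k)] + init_v[cidx(i, j, k)]);
          if (k >= 2 && !msk[id(i, j, k - 1)] && !msk[id(i, j, k)])
            w[id(i, j, k)] = 0.5 * (init_w[cidx(i, j, k - 1)] + init_w[cidx(i, j, k)]);
          if (!msk[id(i, j, k)]) p[id(i, j, k)] = init_p[cidx(i, j, k)];
        }
    for (int k = 1; k <= nz; ++k)
      for (int i = 1; i <= nx; ++i)
        if (!msk[id(i, 1, k)]) v[id(i, 1, k)] = 1.0;
  } else {
    for (int k = 1; k <= nz; ++k)
      for (int j = 1; j <= ny + 1; ++j)
        for (int i = 1; i <= nx; ++i)
          if (!msk[id(i, j - 1, k)] && !msk[id(i, j, k)]) v[id(i, j, k)] = 1.0;
  }

  auto fill_ghosts = [&](std::vector<double>& U, std::vector<double>& V,
                         std::vector<double>& W, std::vector<double>& P) {
    // y ghosts
    for (int k = 1; k <= nz; ++k)
      for (int i = 1; i <= nx; ++i) {
        U[id(i, 0, k)] = -U[id(i, 1, k)];          // u = 0 on inlet plane
        U[id(i, ny + 1, k)] = U[id(i, ny, k)];     // zero-gradient outlet
        W[id(i, 0, k)] = -W[id(i, 1, k)];
        W[id(i, ny + 1, k)] = W[id(i, ny, k)];
        V[id(i, 1, k)] = 1.0;                      // uniform inflow
        V[id(i, 0, k)] = 1.0;
        V[id(i, ny + 1, k)] = V[id(i, ny, k)];     // convective outflow
        V[id(i, ny + 2, k)] = V[id(i, ny, k)];
        P[id(i, 0, k)] = P[id(i, 1, k)];
        P[id(i, ny + 1, k)] = -P[id(i, ny, k)];    // p = 0 on outlet face
      }
    // z ghosts (symmetry / free-slip at both ends)
    for (int j = 0; j <= ny + 2; ++j)
      for (int i = 1; i <= nx; ++i) {
        W[id(i, j, 1)] = 0.0;
        W[id(i, j, nz + 1)] = 0.0;
        W[id(i, j, 0)] = -W[id(i, j, 2)];
        W[id(i, j, nz + 2)] = -W[id(i, j, nz)];
        U[id(i, j, 0)] = U[id(i, j, 1)];
        U[id(i, j, nz + 1)] = U[id(i, j, nz)];
        V[id(i, j, 0)] = V[id(i, j, 1)];
        V[id(i, j, nz + 1)] = V[id(i, j, nz)];
        P[id(i, j, 0)] = P[id(i, j, 1)];
        P[id(i, j, nz + 1)] = P[id(i, j, nz)];
      }
    // x periodic wrap, last so ghost corners are consistent
    for (int k = 0; k <= nz + 2; ++k)
      for (int j = 0; j <= ny + 2; ++j) {
        U[id(0, j, k)] = U[id(nx, j, k)];
        U[id(nx + 1, j, k)] = U[id(1, j, k)];
        V[id(0, j, k)] = V[id(nx, j, k)];
        V[id(nx + 1, j, k)] = V[id(1, j, k)];
        W[id(0, j, k)] = W[id(nx, j, k)];
        W[id(nx + 1, j, k)] = W[id(1, j, k)];
        P[id(0, j, k)] = P[id(nx, j, k)];
        P[id(nx + 1, j, k)] = P[id(1, j, k)];
      }
  };

  // local pseudo-time step and preconditioned artificial sound speed
  double dtmin = 1e30;
  auto dt_pass = [&]() {
    dtmin = 1e30;
    for (int k = 1; k <= nz; ++k) {
      const double hz1 = idz[k], hz2 = idz[k] * idz[k];
      for (int j = 1; j <= ny; ++j) {
        const double hy1 = idy[j], hy2 = idy[j] * idy[j];
        const double hmin = std::min(dx, std::min(dy[j], dz[k]));
        const double bfloor = sq(beta_k * nu / hmin);
        const double vcoef = 0.5 * nu * (dx2 + hy2 + hz2);
        for (int i = 1; i <= nx; ++i) {
          const R_xlen_t c = id(i, j, k);
          const double uc = 0.5 * (u[c] + u[id(i + 1, j, k)]);
          const double vc = 0.5 * (v[c] + v[id(i, j + 1, k)]);
          const double wc = 0.5 * (w[c] + w[id(i, j, k + 1)]);
          const double q2 = uc * uc + vc * vc + wc * wc;
          const double b = std::max(1.0 + q2, bfloor);
          const double cs = std::sqrt(b);
          betac[c] = b;
          csc[c] = cs;
          const double denom =
            (adv_scale * std::fabs(uc) + cs) * ihx +
            (adv_scale * std::fabs(vc) + cs) * hy1 +
            (adv_scale * std::fabs(wc) + cs) * hz1 + vcoef;
          dtc[c] = cfl / denom;
          if (dtc[c] < dtmin) dtmin = dtc[c];
        }
      }
    }
    for (int k = 1; k <= nz; ++k)
      for (int j = 1; j <= ny; ++j) {
        dtc[id(0, j, k)] = dtc[id(nx, j, k)];
        dtc[id(nx + 1, j, k)] = dtc[id(1, j, k)];
      }
  };

  std::vector<double> res_hist;
  double res = NA_REAL;
  double sim_time = 0.0, dtg = 0.0;
  int iter = 0;
  bool converged = false;
  bool plateaued = false;
  // exponential moving average of the fields (cycle mean for flows that
  // settle into a pseudo-time limit cycle instead of a fixed point)
  const double ema_a = 1.0 / 2000.0;
  std::vector<double> ub(size, 0.0), vb(size, 0.0), wb(size, 0.0), pb(size, 0.0);

  for (iter = 1; iter <= max_iter; ++iter) {
    fill_ghosts(u, v, w, p);
    // dt/beta refresh: every step while time-accurate and during the
    // initial transient, every 4th once the field has settled
    if (mode == 1 || iter <= 1000 || iter % 4 == 0) dt_pass();
    if (mode == 1) dtg = dtmin;

    const bool checking = (iter % check_every == 0) || iter == max_iter;
    double r2 = 0.0, s2n = 0.0;
    R_xlen_t nfaces = 0;

    // u momentum (x faces)
    for (int k = 1; k <= nz; ++k) {
      const double izc_m = idzc[k], izc_p = idzc[k + 1], iz = idz[k];
      const double fmz = fm_cz[k], fpz = fp_cz[k];
      const bool okmz = k >= 2, okpz = k <= nz - 1;
      for (int j = 1; j <= ny; ++j) {
        const double iyc_m = idyc[j], iyc_p = idyc[j + 1], iy = idy[j];
        const double fmy = fm_cy[j], fpy = fp_cy[j];
        const bool okmy = j >= 2, okpy = j <= ny - 1;
        const double ad = nu * (2.0 * dx2 + (iyc_p + iyc_m) * iy +
                                (izc_p + izc_m) * iz);
        for (int i = 1; i <= nx; ++i) {
          const R_xlen_t c = id(i, j, k);
          if (msk[id(i - 1, j, k)] || msk[c]) { u2[c] = 0.0; continue; }
          const double dtf = (mode == 0)
            ? std::min(dtc[id(i - 1, j, k)], dtc[c]) : dtg;
          const double uu = u[c];
          const double vv = 0.25 * (v[id(i - 1, j, k)] + v[c] +
                                    v[id(i - 1, j + 1, k)] + v[id(i, j + 1, k)]);
          const double ww = 0.25 * (w[id(i - 1, j, k)] + w[c] +
                                    w[id(i - 1, j, k + 1)] + w[id(i, j, k + 1)]);
          const int imm = (i >= 3) ? i - 2 : i - 2 + nx;
          const int ipp = (i <= nx - 2) ? i + 2 : i + 2 - nx;
          const double dux = dlim(uu,
            u[id(imm, j, k)], u[id(i - 1, j, k)], u[c],
            u[id(i + 1, j, k)], u[id(ipp, j, k)],
            ihx, ihx, 0.5, ihx, ihx, 0.5, true, true);
          const double duy = dlim(vv,
            u[id(i, std::max(j - 2, 0), k)], u[id(i, j - 1, k)], u[c],
            u[id(i, j + 1, k)], u[id(i, j + 2, k)],
            idyc[j - 1], iyc_m, fmy, iyc_p, idyc[std::min(j + 2, ny + 2)], fpy,
            okmy, okpy);
          const double duz = dlim(ww,
            u[id(i, j, std::max(k - 2, 0))], u[id(i, j, k - 1)], u[c],
            u[id(i, j, k + 1)], u[id(i, j, k + 2)],
            idzc[k - 1], izc_m, fmz, izc_p, idzc[std::min(k + 2, nz + 2)], fpz,
            okmz, okpz);
          const double lap =
            (u[id(i + 1, j, k)] - 2.0 * u[c] + u[id(i - 1, j, k)]) * dx2 +
            ((u[id(i, j + 1, k)] - u[c]) * iyc_p -
             (u[c] - u[id(i, j - 1, k)]) * iyc_m) * iy +
            ((u[id(i, j, k + 1)] - u[c]) * izc_p -
             (u[c] - u[id(i, j, k - 1)]) * izc_m) * iz;
          const double dpdx = (p[c] - p[id(i - 1, j, k)]) * ihx;
          const double rhs = -adv_scale * (uu * dux + vv * duy + ww * duz) + nu * lap - dpdx;
          u2[c] = u[c] + dtf * rhs / (1.0 + dtf * ad);
          if (checking) { r2 += rhs * rhs; s2n += u[c] * u[c]; ++nfaces; }
        }
      }
    }

    // v momentum (y faces), j = 2..ny; inlet face fixed, outlet face copied
    for (int k = 1; k <= nz; ++k) {
      const double izc_m = idzc[k], izc_p = idzc[k + 1], iz = idz[k];
      const double fmz = fm_cz[k], fpz = fp_cz[k];
      const bool okmz = k >= 2, okpz = k <= nz - 1;
      for (int j = 2; j <= ny; ++j) {
        const double iy_m = idy[j - 1], iy_p = idy[j], iyc = idyc[j];
        const double fmy = fm_fy[j], fpy = fp_fy[j];
        const double ad = nu * (2.0 * dx2 + (iy_p + iy_m) * iyc +
                                (izc_p + izc_m) * iz);
        for (int i = 1; i <= nx; ++i) {
          const R_xlen_t c = id(i, j, k);
          if (msk[id(i, j - 1, k)] || msk[c]) { v2[c] = 0.0; continue; }
          const double dtf = (mode == 0)
            ? std::min(dtc[id(i, j - 1, k)], dtc[c]) : dtg;
          const double vv = v[c];
          const double uu = 0.25 * (u[id(i, j - 1, k)] + u[id(i + 1, j - 1, k)] +
                                    u[c] + u[id(i + 1, j, k)]);
          const double ww = 0.25 * (w[id(i, j - 1, k)] + w[id(i, j - 1, k + 1)] +
                                    w[c] + w[id(i, j, k + 1)]);
          const int imm = (i >= 3) ? i - 2 : i - 2 + nx;
          const int ipp = (i <= nx - 2) ? i + 2 : i + 2 - nx;
          const double dvx = dlim(uu,
            v[id(imm, j, k)], v[id(i - 1, j, k)], v[c],
            v[id(i + 1, j, k)], v[id(ipp, j, k)],
            ihx, ihx, 0.5, ihx, ihx, 0.5, true, true);
          const double dvy = dlim(vv,
            v[id(i, j - 2, k)], v[id(i, j - 1, k)], v[c],
            v[id(i, j + 1, k)], v[id(i, j + 2, k)],
            idy[std::max(j - 2, 0)], iy_m, fmy, iy_p, idy[std::min(j + 1, ny + 2)],
            fpy, true, true);
          const double dvz = dlim(ww,
            v[id(i, j, std::max(k - 2, 0))], v[id(i, j, k - 1)], v[c],
            v[id(i, j, k + 1)], v[id(i, j, k + 2)],
            idzc[k - 1], izc_m, fmz, izc_p, idzc[std::min(k + 2, nz + 2)], fpz,
            okmz, okpz);
          const double lap =
            (v[id(i + 1, j, k)] - 2.0 * v[c] + v[id(i - 1, j, k)]) * dx2 +
            ((v[id(i, j + 1, k)] - v[c]) * iy_p -
             (v[c] - v[id(i, j - 1, k)]) * iy_m) * iyc +
            ((v[id(i, j, k + 1)] - v[c]) * izc_p -
             (v[c] - v[id(i, j, k - 1)]) * izc_m) * iz;
          const double dpdy = (p[c] - p[id(i, j - 1, k)]) * iyc;
          const double rhs = -adv_scale * (uu * dvx + vv * dvy + ww * dvz) + nu * lap - dpdy;
          v2[c] = v[c] + dtf * rhs / (1.0 + dtf * ad);
          if (checking) { r2 += rhs * rhs; s2n += v[c] * v[c]; ++nfaces; }
        }
      }
    }

    // w momentum (z faces), k = 2..nz; symmetry faces stay zero
    for (int k = 2; k <= nz; ++k) {
      const double iz_m = idz[k - 1], iz_p = idz[k], izc = idzc[k];
      const double fmz = fm_fz[k], fpz = fp_fz[k];
      for (int j = 1; j <= ny; ++j) {
        const double iyc_m = idyc[j], iyc_p = idyc[j + 1], iy = idy[j];
        const double fmy = fm_cy[j], fpy = fp_cy[j];
        const bool okmy = j >= 2, okpy = j <= ny - 1;
        const double ad = nu * (2.0 * dx2 + (iyc_p + iyc_m) * iy +
                                (iz_p + iz_m) * izc);
        for (int i = 1; i <= nx; ++i) {
          const R_xlen_t c = id(i, j, k);
          if (msk[id(i, j, k - 1)] || msk[c]) { w2[c] = 0.0; continue; }
          const double dtf = (mode == 0)
            ? std::min(dtc[id(i, j, k - 1)], dtc[c]) : dtg;
          const double ww = w[c];
          const double uu = 0.25 * (u[id(i, j, k - 1)] + u[id(i + 1, j, k - 1)] +
                                    u[c] + u[id(i + 1, j, k)]);
          const double vv = 0.25 * (v[id(i, j, k - 1)] + v[id(i, j + 1, k - 1)] +
                                    v[c] + v[id(i, j + 1, k)]);
          const int imm = (i >= 3) ? i - 2 : i - 2 + nx;
          const int ipp = (i <= nx - 2) ? i + 2 : i + 2 - nx;
          const double dwx = dlim(uu,
            w[id(imm, j, k)], w[id(i - 1, j, k)], w[c],
            w[id(i + 1, j, k)], w[id(ipp, j, k)],
            ihx, ihx, 0.5, ihx, ihx, 0.5, true, true);
          const double dwy = dlim(vv,
            w[id(i, std::max(j - 2, 0), k)], w[id(i, j - 1, k)], w[c],
            w[id(i, j + 1, k)], w[id(i, j + 2, k)],
            idyc[j - 1], iyc_m, fmy, iyc_p, idyc[std::min(j + 2, ny + 2)], fpy,
            okmy, okpy);
          const double dwz = dlim(ww,
            w[id(i, j, k - 2)], w[id(i, j, k - 1)], w[c],
            w[id(i, j, k + 1)], w[id(i, j, k + 2)],
            idz[std::max(k - 2, 0)], iz_m, fmz, iz_p, idz[std::min(k + 1, nz + 2)],
            fpz, true, true);
          const double lap =
            (w[id(i + 1, j, k)] - 2.0 * w[c] + w[id(i - 1, j, k)]) * dx2 +
            ((w[id(i, j + 1, k)] - w[c]) * iyc_p -
             (w[c] - w[id(i, j - 1, k)]) * iyc_m) * iy +
            ((w[id(i, j, k + 1)] - w[c]) * iz_p -
             (w[c] - w[id(i, j, k - 1)]) * iz_m) * izc;
          const double dpdz = (p[c] - p[id(i, j, k - 1)]) * izc;
          const double rhs = -adv_scale * (uu * dwx + vv * dwy + ww * dwz) + nu * lap - dpdz;
          w2[c] = w[c] + dtf * rhs / (1.0 + dtf * ad);
          if (checking) { r2 += rhs * rhs; s2n += w[c] * w[c]; ++nfaces; }
        }
      }
    }

    // boundary values on the new velocities needed by the divergence
    for (int k = 1; k <= nz; ++k)
      for (int i = 1; i <= nx; ++i) {
        v2[id(i, 1, k)] = (msk[id(i, 1, k)] ? 0.0 : 1.0);
        v2[id(i, ny + 1, k)] = v2[id(i, ny, k)];
      }
    for (int j = 1; j <= ny; ++j)
      for (int i = 1; i <= nx; ++i) {
        w2[id(i, j, 1)] = 0.0;
        w2[id(i, j, nz + 1)] = 0.0;
      }
    for (int k = 1; k <= nz + 1; ++k)
      for (int j = 1; j <= ny + 1; ++j) {
        u2[id(nx + 1, j, k)] = u2[id(1, j, k)];
      }

    // pressure update from the divergence of the new field, with
    // Rusanov-type dissipation on the acoustic subsystem
    for (int k = 1; k <= nz; ++k) {
      const double iz = idz[k], izc_m = idzc[k], izc_p = idzc[k + 1];
      for (int j = 1; j <= ny; ++j) {
        const double iy = idy[j], iyc_m = idyc[j], iyc_p = idyc[j + 1];
        for (int i = 1; i <= nx; ++i) {
          const R_xlen_t c = id(i, j, k);
          if (msk[c]) { p[c] = 0.0; continue; }
          double div =
            (u2[id(i + 1, j, k)] - u2[c]) * ihx +
            (v2[id(i, j + 1, k)] - v2[c]) * iy +
            (w2[id(i, j, k + 1)] - w2[c]) * iz;
          const double pP = p[c];
          const double pxm = msk[id(i - 1, j, k)] ? pP : p[id(i - 1, j, k)];
          const double pxp = msk[id(i + 1, j, k)] ? pP : p[id(i + 1, j, k)];
          const double pym = msk[id(i, j - 1, k)] ? pP : p[id(i, j - 1, k)];
          const double pyp = msk[id(i, j + 1, k)] ? pP : p[id(i, j + 1, k)];
          const double pzm = msk[id(i, j, k - 1)] ? pP : p[id(i, j, k - 1)];
          const double pzp = msk[id(i, j, k + 1)] ? pP : p[id(i, j, k + 1)];
          div -= pdiss * ((pxp - pP) * ihx + (pxm - pP) * ihx +
                          (pyp - pP) * iyc_p + (pym - pP) * iyc_m +
                          (pzp - pP) * izc_p + (pzm - pP) * izc_m) /
                 (2.0 * csc[c]);
          const double dtp = (mode == 0) ? dtc[c] : dtg;
          p[c] -= dtp * betac[c] * div;
        }
      }
    }

    std::swap(u, u2); std::swap(v, v2); std::swap(w, w2);
    if (mode == 1) sim_time += dtg;
    if (mode == 0) {
      if (iter == 1) { ub = u; vb = v; wb = w; pb = p; }
      else if (iter % 4 == 0) {
        const double a4 = 4.0 * ema_a;
        for (R_xlen_t c = 0; c < size; ++c) {
          ub[c] += a4 * (u[c] - ub[c]);
          vb[c] += a4 * (v[c] - vb[c]);
          wb[c] += a4 * (w[c] - wb[c]);
          pb[c] += a4 * (p[c] - pb[c]);
        }
      }
    }

    if (checking) {
      const double urms = std::sqrt(s2n / std::max<R_xlen_t>(nfaces, 1));
      res = std::sqrt(r2 / std::max<R_xlen_t>(nfaces, 1)) /
        (std::max(1.0, nu) * std::max(urms, 1e-12));
      res_hist.push_back(res);
      if (verbose)
        Rprintf("iter %6d  res %.3e%s\n", iter, res,
                mode == 1 ? "  (unsteady)" : "");
      if (mode == 0 && res < tol) { converged = true; break; }
      if (!(res == res)) break;  // NaN: diverged, abort early
      // stall detection: when the windowed-best residual stops improving,
      // the iteration is in a limit cycle and further work changes nothing
      if (mode == 0) {
        const int wlen = std::max(3000 / check_every, 4);
        const int nh = (int)res_hist.size();
        if (nh >= 2 * wlen) {
          double recent = R_PosInf, before = R_PosInf;
          for (int q = nh - wlen; q < nh; ++q) recent = std::min(recent, res_hist[q]);
          for (int q = nh - 2 * wlen; q < nh - wlen; ++q) before = std::min(before, res_hist[q]);
          if (stall_factor > 0 && recent > stall_factor * before) {
            plateaued = true; break;
          }
        }
      }
      if (mode == 1 && sim_time >= total_time) {
        converged = true;  // reached requested horizon
        break;
      }
      Rcpp::checkUserInterrupt();
    }
    if (mode == 1 && sim_time >= total_time) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  // outputs: cell-centered velocities, pressure, per-face streamwise flux,
  // maximum effective divergence over fluid cells. Fluxes and divergence
  // use the scheme's effective face mass flux (velocity plus the
  // pressure-dissipation term), which is what the converged state conserves.
  if (plateaued) {
    std::swap(u, ub); std::swap(v, vb); std::swap(w, wb); std::swap(p, pb);
  }
  fill_ghosts(u, v, w, p);
  dt_pass();
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  NumericVector uc_(ncell), vc_(ncell), wc_(ncell), p_(ncell);
  IntegerVector mask_(ncell);
  double maxdiv = 0.0;
  for (int k = 1; k <= nz; ++k)
    for (int j = 1; j <= ny; ++j)
      for (int i = 1; i <= nx; ++i) {
        const R_xlen_t c = id(i, j, k);
        const R_xlen_t r = (i - 1) + (R_xlen_t)nx * ((j - 1) + (R_xlen_t)ny * (k - 1));
        uc_[r] = 0.5 * (u[c] + u[id(i + 1, j, k)]);
        vc_[r] = 0.5 * (v[c] + v[id(i, j + 1, k)]);
        wc_[r] = 0.5 * (w[c] + w[id(i, j, k + 1)]);
        p_[r] = p[c];
        mask_[r] = msk[c];
        if (!msk[c]) {
          double div =
            (u[id(i + 1, j, k)] - u[c]) * ihx +
            (v[id(i, j + 1, k)] - v[c]) * idy[j] +
            (w[id(i, j, k + 1)] - w[c]) * idz[k];
          const double pP = p[c];
          const double pxm = msk[id(i - 1, j, k)] ? pP : p[id(i - 1, j, k)];
          const double pxp = msk[id(i + 1, j, k)] ? pP : p[id(i + 1, j, k)];
          const double pym = msk[id(i, j - 1, k)] ? pP : p[id(i, j - 1, k)];
          const double pyp = msk[id(i, j + 1, k)] ? pP : p[id(i, j + 1, k)];
          const double pzm = msk[id(i, j, k - 1)] ? pP : p[id(i, j, k - 1)];
          const double pzp = msk[id(i, j, k + 1)] ? pP : p[id(i, j, k + 1)];
          div -= pdiss * ((pxp - pP) * ihx + (pxm - pP) * ihx +
                          (pyp - pP) * idyc[j + 1] + (pym - pP) * idyc[j] +
                          (pzp - pP) * idzc[k + 1] + (pzm - pP) * idzc[k]) /
                 (2.0 * csc[c]);
          maxdiv = std::max(maxdiv, std::fabs(div));
        }
      }
  NumericVector flux(ny + 1);
  for (int j = 1; j <= ny + 1; ++j) {
    double q = 0.0;
    for (int k = 1; k <= nz; ++k)
      for (int i = 1; i <= nx; ++i)
        q += v[id(i, j, k)] * dx * dz[k];
    flux[j - 1] = q;
  }

  return List::create(
    _["u"] = uc_, _["v"] = vc_, _["w"] = wc_, _["p"] = p_,
    _["mask"] = mask_,
    _["iterations"] = iter, _["residual"] = res,
    _["residual_history"] = wrap(res_hist),
    _["converged"] = converged, _["plateaued"] = plateaued,
    _["max_divergence"] = maxdiv,
    _["flux_faces"] = flux, _["sim_time"] = sim_time,
    _["dt_global"] = dtg);
}
// ---------------------------------------------------------------------------
// trilinear interpolation (periodic in x, clamped in y and z)
// ---------------------------------------------------------------------------

struct InterpGrid {
  const double *xc, *yc, *zc, *u, *v, *w;
  int nx, ny, nz;
  double width, dxg, x0;
  R_xlen_t idx(int i, int j, int k) const {
    return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  }
  void locate1(const double* cc, int n, double q, int& i0, double& t) const {
    if (q <= cc[0]) { i0 = 0; t = 0.0; return; }
    if (q >= cc[n - 1]) { i0 = n - 2; t = 1.0; return; }
    const double* it = std::upper_bound(cc, cc + n, q);
    i0 = (int)(it - cc) - 1;
    t = (q - cc[i0]) / (cc[i0 + 1] - cc[i0]);
  }
  void vel(double x, double y, double z, double* out) const {
    const double xm = pmod(x - x0, width);
    // x centers are uniform starting at dxg/2
    double fi = (xm - 0.5 * dxg) / dxg;
    int i0 = (int)std::floor(fi);
    double tx = fi - i0;
    int ia = ((i0 % nx) + nx) % nx;
    int ib = (ia + 1) % nx;
    int j0, k0; double ty, tz;
    locate1(yc, ny, y, j0, ty);
    locate1(zc, nz, z, k0, tz);
    for (int cpt = 0; cpt < 3; ++cpt) {
      const double* f = (cpt == 0) ? u : (cpt == 1) ? v : w;
      double acc = 0.0;
      for (int dk = 0; dk < 2; ++dk)
        for (int dj = 0; dj < 2; ++dj) {
          const double wjk = (dj ? ty : 1 - ty) * (dk ? tz : 1 - tz);
          acc += wjk * ((1 - tx) * f[idx(ia, j0 + dj, k0 + dk)] +
                        tx * f[idx(ib, j0 + dj, k0 + dk)]);
        }
      out[cpt] = acc;
    }
  }
};

// [[Rcpp::export]]
NumericMatrix gf_interp(NumericVector xc, NumericVector yc, NumericVector zc,
                        NumericVector u, NumericVector v, NumericVector w,
                        double cell_width, NumericMatrix pts) {
  InterpGrid g;
  g.xc = xc.begin(); g.yc = yc.begin(); g.zc = zc.begin();
  g.u = u.begin(); g.v = v.begin(); g.w = w.begin();
  g.nx = xc.size(); g.ny = yc.size(); g.nz = zc.size();
  g.width = cell_width; g.dxg = cell_width / g.nx; g.x0 = 0.0;
  NumericMatrix out(pts.nrow(), 3);
  double vv[3];
  for (int r = 0; r < pts.nrow(); ++r) {
    g.vel(pts(r, 0), pts(r, 1), pts(r, 2), vv);
    out(r, 0) = vv[0]; out(r, 1) = vv[1]; out(r, 2) = vv[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// capture detection
// ---------------------------------------------------------------------------

// first intersection of segment p->q with a finite vertical cylinder
static bool seg_hit_cyl(double px, double py, double pz,
                        double dxs, double dys, double dzs,
                        double cx, double cy, double r, double z0, double z1,
                        double& thit) {
  const double mx = px - cx, my = py - cy;
  const double a = dxs * dxs + dys * dys;
  const double b = 2.0 * (mx * dxs + my * dys);
  const double c = mx * mx + my * my - r * r;
  double best = 2.0;
  if (c <= 0.0 && pz >= z0 && pz <= z1) { thit = 0.0; return true; }
  if (a > 0.0) {
    const double disc = b * b - 4.0 * a * c;
    if (disc >= 0.0) {
      const double sd = std::sqrt(disc);
      for (double t : { (-b - sd) / (2 * a), (-b + sd) / (2 * a) }) {
        if (t >= 0.0 && t <= 1.0) {
          const double z = pz + t * dzs;
          if (z >= z0 && z <= z1 && t < best) best = t;
        }
      }
    }
  }
  // end caps
  if (dzs != 0.0) {
    for (double zc : { z0, z1 }) {
      const double t = (zc - pz) / dzs;
      if (t >= 0.0 && t <= 1.0 && t < best) {
        const double x = mx + t * dxs, y = my + t * dys;
        if (x * x + y * y <= r * r) best = t;
      }
    }
  }
  if (best <= 1.0) { thit = best; return true; }
  return false;
}

// distance from point to segment a-b
static double pt_seg_d(double px, double py, double pz,
                       double ax, double ay, double az,
                       double bx, double by, double bz) {
  const double ex = bx - ax, ey = by - ay, ez = bz - az;
  const double ee = ex * ex + ey * ey + ez * ez;
  double t = ee > 0 ? ((px - ax) * ex + (py - ay) * ey + (pz - az) * ez) / ee : 0.0;
  t = std::min(std::max(t, 0.0), 1.0);
  return std::sqrt(sq(px - ax - t * ex) + sq(py - ay - t * ey) +
                   sq(pz - az - t * ez));
}

// first contact of segment p->q with a capsule: distance along the segment to
// the capsule axis is convex in the segment parameter, so ternary search finds
// the minimum and bisection refines the first crossing.
static bool seg_hit_cap(double px, double py, double pz,
                        double dxs, double dys, double dzs,
                        double ax, double ay, double az,
                        double bx, double by, double bz, double r,
                        double& thit) {
  auto f = [&](double t) {
    return pt_seg_d(px + t * dxs, py + t * dys, pz + t * dzs,
                    ax, ay, az, bx, by, bz) - r;
  };
  if (f(0.0) <= 0.0) { thit = 0.0; return true; }
  double lo = 0.0, hi = 1.0;
  for (int it = 0; it < 60; ++it) {
    const double m1 = lo + (hi - lo) / 3.0, m2 = hi - (hi - lo) / 3.0;
    if (f(m1) < f(m2)) hi = m2; else lo = m1;
  }
  double tmin = 0.5 * (lo + hi);
  if (f(tmin) > 0.0) {
    if (f(1.0) > 0.0) return false;
    tmin = 1.0;
  }
  // bisect on [0, tmin]: f(0) > 0 >= f(tmin)
  double a0 = 0.0, b0 = tmin;
  for (int it = 0; it < 60; ++it) {
    const double m = 0.5 * (a0 + b0);
    if (f(m) > 0.0) a0 = m; else b0 = m;
  }
  thit = b0;
  return true;
}

// segment test against all solids and their periodic images; positions are
// given in cell coordinates (x already wrapped into [0, width))
static bool seg_hit_all(double px, double py, double pz,
                        double dxs, double dys, double dzs,
                        const NumericMatrix& cyl, const NumericMatrix& cap,
                        double width, double& tbest, double* contact) {
  tbest = 2.0;
  double t;
  for (int s = 0; s < cyl.nrow(); ++s)
    for (int im = -1; im <= 1; ++im)
      if (seg_hit_cyl(px, py, pz, dxs, dys, dzs,
                      cyl(s, 0) + im * width, cyl(s, 1), cyl(s, 2),
                      cyl(s, 3), cyl(s, 4), t))
        if (t < tbest) tbest = t;
  for (int s = 0; s < cap.nrow(); ++s)
    for (int im = -1; im <= 1; ++im)
      if (seg_hit_cap(px, py, pz, dxs, dys, dzs,
                      cap(s, 0) + im * width, cap(s, 1), cap(s, 2),
                      cap(s, 3) + im * width, cap(s, 4), cap(s, 5),
                      cap(s, 6), t))
        if (t < tbest) tbest = t;
  if (tbest <= 1.0) {
    contact[0] = px + tbest * dxs;
    contact[1] = py + tbest * dys;
    contact[2] = pz + tbest * dzs;
    return true;
  }
  return false;
}

// [[Rcpp::export]]
NumericVector gf_signed_distance(NumericMatrix pts,
                                 NumericMatrix cyl, NumericMatrix cap,
                                 double width) {
  NumericVector out(pts.nrow());
  for (int r = 0; r < pts.nrow(); ++r) {
    const double x = pmod(pts(r, 0), width), y = pts(r, 1), z = pts(r, 2);
    double dmin = R_PosInf;
    for (int s = 0; s < cyl.nrow(); ++s) {
      for (int im = -1; im <= 1; ++im) {
        const double dxr = std::sqrt(sq(x - cyl(s, 0) - im * width) +
                                     sq(y - cyl(s, 1))) - cyl(s, 2);
        const double dzr = std::max(cyl(s, 3) - z, z - cyl(s, 4));
        double d;
        if (dxr <= 0.0 && dzr <= 0.0) d = std::max(dxr, dzr);
        else d = std::sqrt(sq(std::max(dxr, 0.0)) + sq(std::max(dzr, 0.0)));
        if (d < dmin) dmin = d;
      }
    }
    for (int s = 0; s < cap.nrow(); ++s) {
      for (int im = -1; im <= 1; ++im) {
        const double d = pt_seg_d(x, y, z,
                                  cap(s, 0) + im * width, cap(s, 1), cap(s, 2),
                                  cap(s, 3) + im * width, cap(s, 4), cap(s, 5))
                         - cap(s, 6);
        if (d < dmin) dmin = d;
      }
    }
    out[r] = dmin;
  }
  return out;
}

// [[Rcpp::export]]
List gf_segment_hit(NumericVector p, NumericVector q,
                    NumericMatrix cyl, NumericMatrix cap, double width) {
  double contact[3], t;
  const double px = pmod(p[0], width);
  const bool hit = seg_hit_all(px, p[1], p[2],
                               q[0] - p[0], q[1] - p[1], q[2] - p[2],
                               cyl, cap, width, t, contact);
  return List::create(_["captured"] = hit, _["t"] = hit ? t : NA_REAL,
                      _["contact"] = hit
                        ? NumericVector::create(p[0] + t * (q[0] - p[0]),
                                                p[1] + t * (q[1] - p[1]),
                                                p[2] + t * (q[2] - p[2]))
                        : NumericVector::create(NA_REAL, NA_REAL, NA_REAL));
}

// ---------------------------------------------------------------------------
// agent transport (Euler-Maruyama)
// ---------------------------------------------------------------------------

// splitmix64 + xoshiro256** : deterministic, platform-independent RNG
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  bool have_spare = false;
  double spare = 0.0;
  double norm() {  // Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u1 = 0.0;
    while (u1 <= 0.0) u1 = unif();
    const double u2 = unif();
    const double m = std::sqrt(-2.0 * std::log(u1));
    spare = m * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return m * std::cos(2.0 * M_PI * u2);
  }
};

// advance one ensemble; positions in tiled coordinates, width W = n_tiles * cw
static void run_steps(const InterpGrid& g, double cw, double W,
                      double Ly, double Lz,
                      const NumericMatrix& cyl, const NumericMatrix& cap,
                      std::vector<double>& X, std::vector<double>& Y,
                      std::vector<double>& Z, std::vector<int>& st,
                      int nsteps, double dt, double sig, Rng& rng,
                      bool reflect_inlet) {
  const int n = (int)st.size();
  double vv[3], contact[3], t;
  for (int step = 0; step < nsteps; ++step) {
    int nact = 0;
    for (int a = 0; a < n; ++a) {
      // consume RNG draws for every agent so trajectories do not depend on
      // the fate of other agents
      const double g1 = sig > 0 ? rng.norm() : 0.0;
      const double g2 = sig > 0 ? rng.norm() : 0.0;
      const double g3 = sig > 0 ? rng.norm() : 0.0;
      if (st[a] != 0) continue;
      const double xm = pmod(X[a], cw);
      g.vel(xm, Y[a], Z[a], vv);
      double dxs = vv[0] * dt + sig * g1;
      double dys = vv[1] * dt + sig * g2;
      double dzs = vv[2] * dt + sig * g3;
      if (seg_hit_all(xm, Y[a], Z[a], dxs, dys, dzs, cyl, cap, cw, t, contact)) {
        st[a] = 1;  // captured
        X[a] = X[a] + t * dxs; Y[a] += t * dys; Z[a] += t * dzs;
        continue;
      }
      double xn = X[a] + dxs, yn = Y[a] + dys, zn = Z[a] + dzs;
      xn = pmod(xn, W);
      if (yn > Ly) { st[a] = 2; X[a] = xn; Y[a] = yn; Z[a] = zn; continue; }
      if (yn < 0 && reflect_inlet) yn = -yn;
      if (zn < 0) zn = -zn;
      if (zn > Lz) zn = 2 * Lz - zn;
      X[a] = xn; Y[a] = yn; Z[a] = zn;
      ++nact;
    }
    if (nact == 0) break;
  }
}

// [[Rcpp::export]]
List gf_step_agents(NumericVector xc, NumericVector yc, NumericVector zc,
                    NumericVector u, NumericVector v, NumericVector w,
                    double cell_width, int n_tiles, double Ly, double Lz,
                    NumericMatrix cyl, NumericMatrix cap,
                    NumericMatrix pos, IntegerVector status,
                    int nsteps, double dt, double variance, double seed,
                    bool reflect_inlet) {
  InterpGrid g;
  g.xc = xc.begin(); g.yc = yc.begin(); g.zc = zc.begin();
  g.u = u.begin(); g.v = v.begin(); g.w = w.begin();
  g.nx = xc.size(); g.ny = yc.size(); g.nz = zc.size();
  g.width = cell_width; g.dxg = cell_width / g.nx; g.x0 = 0.0;
  const int n = pos.nrow();
  std::vector<double> X(n), Y(n), Z(n);
  std::vector<int> st(n);
  for (int a = 0; a < n; ++a) {
    X[a] = pos(a, 0); Y[a] = pos(a, 1); Z[a] = pos(a, 2);
    st[a] = status[a];
  }
  Rng rng((uint64_t)seed);
  run_steps(g, cell_width, n_tiles * cell_width, Ly, Lz, cyl, cap,
            X, Y, Z, st, nsteps, dt, std::sqrt(variance * dt), rng,
            reflect_inlet);
  NumericMatrix out(n, 3);
  IntegerVector sto(n);
  for (int a = 0; a < n; ++a) {
    out(a, 0) = X[a]; out(a, 1) = Y[a]; out(a, 2) = Z[a];
    sto[a] = st[a];
  }
  return List::create(_["positions"] = out, _["status"] = sto);
}

// [[Rcpp::export]]
NumericMatrix gf_capture_reps(NumericVector xc, NumericVector yc, NumericVector zc,
                              NumericVector u, NumericVector v, NumericVector w,
                              double cell_width, int n_tiles,
                              double Ly, double Lz,
                              NumericMatrix cyl, NumericMatrix cap,
                              int n_agents, double dt, double max_time,
                              double variance, NumericVector sheet,
                              NumericVector seeds, bool reflect_inlet) {
  InterpGrid g;
  g.xc = xc.begin(); g.yc = yc.begin(); g.zc = zc.begin();
  g.u = u.begin(); g.v = v.begin(); g.w = w.begin();
  g.nx = xc.size(); g.ny = yc.size(); g.nz = zc.size();
  g.width = cell_width; g.dxg = cell_width / g.nx; g.x0 = 0.0;
  const int n_reps = seeds.size();
  const int nsteps = (int)std::ceil(max_time / dt);
  const double W = n_tiles * cell_width;
  NumericMatrix out(n_reps, 3);  // captured, exited, active fractions
  for (int rep = 0; rep < n_reps; ++rep) {
    Rng rng((uint64_t)seeds[rep]);
    std::vector<double> X(n_agents), Y(n_agents), Z(n_agents);
    std::vector<int> st(n_agents, 0);
    for (int a = 0; a < n_agents; ++a) {
      X[a] = sheet[0] + (sheet[1] - sheet[0]) * rng.unif();
      Y[a] = sheet[2];
      Z[a] = sheet[3] + (sheet[4] - sheet[3]) * rng.unif();
    }
    run_steps(g, cell_width, W, Ly, Lz, cyl, cap, X, Y, Z, st,
              nsteps, dt, std::sqrt(variance * dt), rng, reflect_inlet);
    int cap_n = 0, ex_n = 0, act_n = 0;
    for (int a = 0; a < n_agents; ++a) {
      if (st[a] == 1) ++cap_n; else if (st[a] == 2) ++ex_n; else ++act_n;
    }
    out(rep, 0) = (double)cap_n / n_agents;
    out(rep, 1) = (double)ex_n / n_agents;
    out(rep, 2) = (double)act_n / n_agents;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
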