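// Explicit central-difference plane-strain FE kernel.
//
// One-point reduced-integration bilinear quads with Flanagan-Belytschko
// hourglass control (viscous-stiffness combined form), constant-strain
// triangles, total-Lagrangian kinematics. Materials: compressible
// neo-Hookean (matched to E, nu) and one-term Ogden with quasilinear
// viscoelastic relaxation of the deviatoric stress carried in the
// co-rotational (polar-rotation-neutralised) frame. The head outer edge
// can be kinematically coupled to a rotating reference point; impact
// runs use a node-on-rigid-line penalty contact instead.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Elem {
  int nn;                 // 3 or 4
  int idx[4];
  double b[4][2];         // reference shape gradients
  double gamma[4];        // hourglass vector (quads)
  double V0;
  int mtype;              // 0 elastic, 1 ogden-qlv
  double rho, mu, K, alpha, g1, g2, tau1, tau2, cd;
  double hg_k, hg_c;      // hourglass stiffness / viscosity coefficients
  // state
  double Jprev;
  double Sprev[4], r1[4], r2[4];   // co-rotational deviatoric stress memory
  double Fprev[4], Pprev[4];
  bool state_init;
};

static inline double det2(double a, double b, double c, double d) {
  return a * d - b * c;
}

// x^n for small positive integer n (constitutive exponents are typically
// small integers; falls back to pow otherwise)
static inline double fastpow(double x, double a) {
  int n = (int)a;
  if ((double)n == a && n > 0 && n <= 12) {
    double r = 1.0, b = x;
    while (n) { if (n & 1) r *= b; b *= b; n >>= 1; }
    return r;
  }
  return std::pow(x, a);
}

// [[Rcpp::export]]
List explicit_solve_cpp(NumericMatrix nodes0,
                        IntegerMatrix quads, IntegerMatrix tris,
                        IntegerVector mat_type, NumericMatrix mat_par,
                        NumericVector mass,
                        IntegerVector presc, NumericVector theta_steps,
                        double rpx, double rpy,
                        double dt, int nsteps,
                        int save_every, int peak_every,
                        double hg_stiff, double hg_visc, double bulk_visc,
                        bool contact, double plane_px, double plane_py,
                        double plane_nx, double plane_ny, double kpen,
                        NumericMatrix v0, double t0,
                        IntegerVector track_nodes, NumericVector track_w) {
  const int N = nodes0.nrow();
  const int Q = quads.nrow(), T = tris.nrow(), E = Q + T;

  std::vector<Elem> el(E);
  for (int e = 0; e < E; ++e) {
    Elem &q = el[e];
    q.mtype = mat_type[e];
    q.rho = mat_par(e, 0); q.mu = mat_par(e, 1); q.K = mat_par(e, 2);
    q.alpha = mat_par(e, 3); q.g1 = mat_par(e, 4); q.g2 = mat_par(e, 5);
    q.tau1 = mat_par(e, 6); q.tau2 = mat_par(e, 7); q.cd = mat_par(e, 8);
    q.Jprev = 1.0;
    for (int k = 0; k < 4; ++k) {
      q.Sprev[k] = q.r1[k] = q.r2[k] = 0.0;
      q.Fprev[k] = (k == 0 || k == 3) ? 1.0 : 0.0;  // F stored xx,xy,yx,yy
      q.Pprev[k] = 0.0;
    }
    q.state_init = false;
    if (e < Q) {
      q.nn = 4;
      for (int a = 0; a < 4; ++a) q.idx[a] = quads(e, a);
      double X[4], Y[4];
      for (int a = 0; a < 4; ++a) { X[a] = nodes0(q.idx[a], 0); Y[a] = nodes0(q.idx[a], 1); }
      // 1-pt: dN/dxi = {-1,1,1,-1}/4, dN/deta = {-1,-1,1,1}/4
      const double dxi[4]  = {-0.25, 0.25, 0.25, -0.25};
      const double deta[4] = {-0.25, -0.25, 0.25, 0.25};
      double J11 = 0, J12 = 0, J21 = 0, J22 = 0;
      for (int a = 0; a < 4; ++a) {
        J11 += X[a] * dxi[a];  J12 += X[a] * deta[a];
        J21 += Y[a] * dxi[a];  J22 += Y[a] * deta[a];
      }
      double dj = det2(J11, J12, J21, J22);
      q.V0 = 4.0 * dj;
      double i11 = J22 / dj, i12 = -J12 / dj, i21 = -J21 / dj, i22 = J11 / dj;
      for (int a = 0; a < 4; ++a) {
        q.b[a][0] = dxi[a] * i11 + deta[a] * i21;
        q.b[a][1] = dxi[a] * i12 + deta[a] * i22;
      }
      const double h[4] = {1.0, -1.0, 1.0, -1.0};
      double hX = 0, hY = 0;
      for (int a = 0; a < 4; ++a) { hX += h[a] * X[a]; hY += h[a] * Y[a]; }
      double bb = 0;
      for (int a = 0; a < 4; ++a) {
        q.gamma[a] = h[a] - hX * q.b[a][0] - hY * q.b[a][1];
        bb += q.b[a][0] * q.b[a][0] + q.b[a][1] * q.b[a][1];
      }
      q.hg_k = hg_stiff * q.mu * q.V0 * bb;
      q.hg_c = hg_visc * q.rho * q.cd * std::sqrt(std::fabs(q.V0)) * 0.25;
    } else {
      q.nn = 3;
      for (int a = 0; a < 3; ++a) q.idx[a] = tris(e - Q, a);
      q.idx[3] = q.idx[2];
      double X[3], Y[3];
      for (int a = 0; a < 3; ++a) { X[a] = nodes0(q.idx[a], 0); Y[a] = nodes0(q.idx[a], 1); }
      double A2 = (X[1] - X[0]) * (Y[2] - Y[0]) - (X[2] - X[0]) * (Y[1] - Y[0]);
      q.V0 = 0.5 * A2;
      q.b[0][0] = (Y[1] - Y[2]) / A2; q.b[0][1] = (X[2] - X[1]) / A2;
      q.b[1][0] = (Y[2] - Y[0]) / A2; q.b[1][1] = (X[0] - X[2]) / A2;
      q.b[2][0] = (Y[0] - Y[1]) / A2; q.b[2][1] = (X[1] - X[0]) / A2;
      for (int k = 0; k < 4; ++k) q.gamma[k] = 0.0;
      q.hg_k = q.hg_c = 0.0;
    }
  }

  std::vector<double> X0(N), Y0(N), x(N), y(N), vx(N), vy(N),
      fx(N), fy(N), m(N);
  for (int i = 0; i < N; ++i) {
    X0[i] = nodes0(i, 0); Y0[i] = nodes0(i, 1);
    x[i] = X0[i]; y[i] = Y0[i]; m[i] = mass[i];
    vx[i] = v0(i, 0); vy[i] = v0(i, 1);
  }
  std::vector<char> is_presc(N, 0);
  for (int k = 0; k < presc.size(); ++k) is_presc[presc[k]] = 1;

  const int n_frames = nsteps / save_every + 1;
  NumericVector frF(E * 4 * n_frames), frS(E * 4 * n_frames);
  NumericVector frame_t(n_frames);
  NumericMatrix energy(n_frames, 5);  // KE, Wint, Wext, Whg, t
  NumericMatrix peaks(E, 3);          // MSS, MPS(eps1 max), VM
  NumericMatrix peak_t(E, 3);
  NumericMatrix pmin(E, 2);           // signed minima: eps2 min, shear comp min
  NumericVector acm_series(n_frames);
  NumericMatrix vcm_series(track_nodes.size() > 0 ? nsteps : 0, 2);
  NumericVector contact_force(contact ? nsteps : 0);
  double acm_peak = 0.0, hg_energy = 0.0, Wint = 0.0, Wext = 0.0;
  double peak_total_energy = 0.0;
  int frame_i = 0, status = 0;
  double status_time = NA_REAL;
  int bad_elem = -1;

  std::vector<double> vxp(vx), vyp(vy);  // previous half-step velocity
  // prescribed node motion at step s: rotation by theta_steps[s] about RP
  auto set_presc = [&](int s, std::vector<double> &px_, std::vector<double> &py_) {
    double c = std::cos(theta_steps[s]), sn = std::sin(theta_steps[s]);
    for (int k = 0; k < presc.size(); ++k) {
      int i = presc[k];
      double dx = X0[i] - rpx, dy = Y0[i] - rpy;
      px_[i] = rpx + c * dx - sn * dy;
      py_[i] = rpy + sn * dx + c * dy;
    }
  };
  if (presc.size() > 0) set_presc(0, x, y);  // start at theta_steps[0]
  std::vector<double> fcx, fcy;
  if (contact) { fcx.assign(N, 0.0); fcy.assign(N, 0.0); }

  for (int s = 0; s < nsteps; ++s) {
    // ---- forces at configuration x^s ------------------------------------
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    double dWint = 0.0;
    for (int e = 0; e < E; ++e) {
      Elem &q = el[e];
      double F11 = 0, F12 = 0, F21 = 0, F22 = 0;
      for (int a = 0; a < q.nn; ++a) {
        F11 += x[q.idx[a]] * q.b[a][0]; F12 += x[q.idx[a]] * q.b[a][1];
        F21 += y[q.idx[a]] * q.b[a][0]; F22 += y[q.idx[a]] * q.b[a][1];
      }
      double J = det2(F11, F12, F21, F22);
      if (!(J > 0.0)) { status = 1; status_time = t0 + s * dt; bad_elem = e; break; }
      double sxx, syy, sxy, szz;   // Cauchy stress
      if (q.mtype == 0) {
        // compressible neo-Hookean, plane strain
        double B11 = F11 * F11 + F12 * F12;
        double B22 = F21 * F21 + F22 * F22;
        double B12 = F11 * F21 + F12 * F22;
        double Jm23 = 1.0 / std::cbrt(J * J);
        double Bb11 = Jm23 * B11, Bb22 = Jm23 * B22, Bb12 = Jm23 * B12,
               Bb33 = Jm23;
        double tr3 = (Bb11 + Bb22 + Bb33) / 3.0;
        double muJ = q.mu / J;
        double p = q.K * (J - 1.0);
        sxx = muJ * (Bb11 - tr3) + p;
        syy = muJ * (Bb22 - tr3) + p;
        szz = muJ * (Bb33 - tr3) + p;
        sxy = muJ * Bb12;
      } else {
        // Ogden principal stresses + QLV co-rotational relaxation
        double C11 = F11 * F11 + F21 * F21;
        double C22 = F12 * F12 + F22 * F22;
        double C12 = F11 * F12 + F21 * F22;
        double tr = C11 + C22;
        double disc = std::sqrt(0.25 * (C11 - C22) * (C11 - C22) + C12 * C12);
        double l1s = 0.5 * tr + disc, l2s = 0.5 * tr - disc;
        if (l2s < 1e-12) l2s = 1e-12;
        double lam1 = std::sqrt(l1s), lam2 = std::sqrt(l2s);
        double Jm13 = 1.0 / std::cbrt(J);
        double lb1 = lam1 * Jm13, lb2 = lam2 * Jm13, lb3 = Jm13;
        double p1 = fastpow(lb1, q.alpha), p2 = fastpow(lb2, q.alpha),
               p3 = fastpow(lb3, q.alpha);
        double mean3 = (p1 + p2 + p3) / 3.0;
        double fac = 2.0 * q.mu / (q.alpha * J);
        double d1 = fac * (p1 - mean3), d2 = fac * (p2 - mean3),
               d3 = fac * (p3 - mean3);
        // Lagrangian principal direction of C for l1s
        double n1x, n1y;
        if (std::fabs(C12) > 1e-30) { n1x = l1s - C22; n1y = C12; }
        else if (C11 >= C22) { n1x = 1; n1y = 0; }
        else { n1x = 0; n1y = 1; }
        double nn = std::sqrt(n1x * n1x + n1y * n1y);
        n1x /= nn; n1y /= nn;
        // spatial directions: m1 = F N1 / |F N1|, m2 perpendicular
        double m1x = F11 * n1x + F12 * n1y, m1y = F21 * n1x + F22 * n1y;
        double mn = std::sqrt(m1x * m1x + m1y * m1y);
        m1x /= mn; m1y /= mn;
        double m2x = -m1y, m2y = m1x;
        // spatial deviatoric instantaneous stress
        double Dxx = d1 * m1x * m1x + d2 * m2x * m2x;
        double Dyy = d1 * m1y * m1y + d2 * m2y * m2y;
        double Dxy = d1 * m1x * m1y + d2 * m2x * m2y;
        double Dzz = d3;
        // co-rotational frame via polar rotation of F
        double rc = F11 + F22, rs = F21 - F12;
        double rn = std::sqrt(rc * rc + rs * rs);
        rc /= rn; rs /= rn;    // R = [[rc, -rs],[rs, rc]]
        // Shat = R^T D R
        double Sh_xx = rc * rc * Dxx + 2 * rc * rs * Dxy + rs * rs * Dyy;
        double Sh_yy = rs * rs * Dxx - 2 * rc * rs * Dxy + rc * rc * Dyy;
        double Sh_xy = rc * rs * (Dyy - Dxx) + (rc * rc - rs * rs) * Dxy;
        double Sh[4] = {Sh_xx, Sh_yy, Sh_xy, Dzz};
        if (!q.state_init) {
          // initialise memory consistent with history S(t<=0) = 0
          q.state_init = true;
          for (int k = 0; k < 4; ++k) q.Sprev[k] = 0.0;
        }
        double ex1 = std::exp(-dt / q.tau1), ex2 = std::exp(-dt / q.tau2);
        double f1 = (q.tau1 / dt) * (1.0 - ex1), f2 = (q.tau2 / dt) * (1.0 - ex2);
        double Sv[4];
        double ginf = 1.0 - q.g1 - q.g2;
        for (int k = 0; k < 4; ++k) {
          double dS = Sh[k] - q.Sprev[k];
          q.r1[k] = ex1 * q.r1[k] + f1 * dS;
          q.r2[k] = ex2 * q.r2[k] + f2 * dS;
          Sv[k] = ginf * Sh[k] + q.g1 * q.r1[k] + q.g2 * q.r2[k];
          q.Sprev[k] = Sh[k];
        }
        // rotate back: Sdev = R Sv R^T
        double Vxx = rc * rc * Sv[0] - 2 * rc * rs * Sv[2] + rs * rs * Sv[1];
        double Vyy = rs * rs * Sv[0] + 2 * rc * rs * Sv[2] + rc * rc * Sv[1];
        double Vxy = rc * rs * (Sv[0] - Sv[1]) + (rc * rc - rs * rs) * Sv[2];
        double p = q.K * (J - 1.0);
        sxx = Vxx + p; syy = Vyy + p; sxy = Vxy; szz = Sv[3] + p;
      }
      // bulk viscosity (linear, volumetric strain-rate damping)
      if (bulk_visc > 0.0 && s > 0) {
        double trD = (J - q.Jprev) / (dt * J);
        double le = std::sqrt(std::fabs(q.V0));
        double qv = bulk_visc * q.rho * q.cd * le * trD;
        if (trD < 0.0) { sxx += qv; syy += qv; szz += qv; }
      }
      q.Jprev = J;
      // nominal stress P = J sigma F^{-T} (in-plane block)
      double iF11 = F22 / J, iF12 = -F12 / J, iF21 = -F21 / J, iF22 = F11 / J;
      // F^{-T} entries: (iF11, iF21; iF12, iF22)
      double P11 = J * (sxx * iF11 + sxy * iF12);
      double P12 = J * (sxx * iF21 + sxy * iF22);
      double P21 = J * (sxy * iF11 + syy * iF12);
      double P22 = J * (sxy * iF21 + syy * iF22);
      for (int a = 0; a < q.nn; ++a) {
        fx[q.idx[a]] -= q.V0 * (P11 * q.b[a][0] + P12 * q.b[a][1]);
        fy[q.idx[a]] -= q.V0 * (P21 * q.b[a][0] + P22 * q.b[a][1]);
      }
      // stress-power internal energy (trapezoidal in F)
      double Fc[4] = {F11, F12, F21, F22};
      double Pc[4] = {P11, P12, P21, P22};
      if (s > 0) {
        double dd = 0;
        for (int k = 0; k < 4; ++k)
          dd += 0.5 * (Pc[k] + q.Pprev[k]) * (Fc[k] - q.Fprev[k]);
        dWint += q.V0 * dd;
      }
      for (int k = 0; k < 4; ++k) { q.Fprev[k] = Fc[k]; q.Pprev[k] = Pc[k]; }
      // hourglass control (quads)
      if (q.nn == 4 && (q.hg_k > 0 || q.hg_c > 0)) {
        double qx = 0, qy = 0, qvx = 0, qvy = 0;
        for (int a = 0; a < 4; ++a) {
          int i = q.idx[a];
          qx += q.gamma[a] * (x[i] - X0[i]);
          qy += q.gamma[a] * (y[i] - Y0[i]);
          qvx += q.gamma[a] * vxp[i];
          qvy += q.gamma[a] * vyp[i];
        }
        double gx = q.hg_k * qx + q.hg_c * qvx;
        double gy = q.hg_k * qy + q.hg_c * qvy;
        for (int a = 0; a < 4; ++a) {
          fx[q.idx[a]] -= gx * q.gamma[a];
          fy[q.idx[a]] -= gy * q.gamma[a];
        }
        hg_energy += dt * (gx * qvx + gy * qvy);
      }
      // save frame fields
      if (s % save_every == 0) {
        int off = (frame_i * 4) * E + e;
        frF[off] = F11; frF[off + E] = F12; frF[off + 2 * E] = F21; frF[off + 3 * E] = F22;
        frS[off] = sxx; frS[off + E] = syy; frS[off + 2 * E] = sxy; frS[off + 3 * E] = szz;
      }
      // running peak metrics
      if (s % peak_every == 0) {
        double C11 = F11 * F11 + F21 * F21;
        double C22 = F12 * F12 + F22 * F22;
        double C12 = F11 * F12 + F21 * F22;
        double tr = C11 + C22;
        double disc = std::sqrt(0.25 * (C11 - C22) * (C11 - C22) + C12 * C12);
        double eps1 = 0.5 * std::log(std::max(0.5 * tr + disc, 1e-12));
        double eps2 = 0.5 * std::log(std::max(0.5 * tr - disc, 1e-12));
        double mss = eps1 - eps2;
        double vm = std::sqrt(0.5 * ((sxx - syy) * (sxx - syy) +
                                     (syy - szz) * (syy - szz) +
                                     (szz - sxx) * (szz - sxx)) + 3 * sxy * sxy);
        double tnow = t0 + s * dt;
        if (mss > peaks(e, 0)) { peaks(e, 0) = mss; peak_t(e, 0) = tnow; }
        if (eps1 > peaks(e, 1)) { peaks(e, 1) = eps1; peak_t(e, 1) = tnow; }
        if (vm > peaks(e, 2)) { peaks(e, 2) = vm; peak_t(e, 2) = tnow; }
        if (eps2 < pmin(e, 0)) pmin(e, 0) = eps2;
        double shr = 0.5 * ((F12 + F21));  // engineering-shear proxy, signed
        if (shr < pmin(e, 1)) pmin(e, 1) = shr;
      }
    }
    if (status != 0) break;

    // ---- contact --------------------------------------------------------
    double fc_tot = 0.0;
    if (contact) {
      std::fill(fcx.begin(), fcx.end(), 0.0);
      std::fill(fcy.begin(), fcy.end(), 0.0);
      for (int i = 0; i < N; ++i) {
        double gap = (x[i] - plane_px) * plane_nx + (y[i] - plane_py) * plane_ny;
        if (gap < 0) {
          double fmag = -kpen * gap;
          fcx[i] = fmag * plane_nx;
          fcy[i] = fmag * plane_ny;
          fx[i] += fcx[i];
          fy[i] += fcy[i];
          fc_tot += fmag;
        }
      }
      contact_force[s] = fc_tot;
    }

    // ---- integrate ------------------------------------------------------
    double dWext = 0.0;
    for (int i = 0; i < N; ++i) {
      if (is_presc[i]) continue;
      double ax = fx[i] / m[i], ay = fy[i] / m[i];
      double nvx = vxp[i] + dt * ax, nvy = vyp[i] + dt * ay;
      x[i] += dt * nvx; y[i] += dt * nvy;
      vx[i] = nvx; vy[i] = nvy;
      if (contact && (fcx[i] != 0.0 || fcy[i] != 0.0))
        dWext += (fcx[i] * 0.5 * (nvx + vxp[i]) +
                  fcy[i] * 0.5 * (nvy + vyp[i])) * dt;
    }
    if (presc.size() > 0) {
      double c = std::cos(theta_steps[s + 1]), sn = std::sin(theta_steps[s + 1]);
      for (int k = 0; k < presc.size(); ++k) {
        int i = presc[k];
        double dx0 = X0[i] - rpx, dy0 = Y0[i] - rpy;
        double nx_ = rpx + c * dx0 - sn * dy0;
        double ny_ = rpy + sn * dx0 + c * dy0;
        double nvx = (nx_ - x[i]) / dt, nvy = (ny_ - y[i]) / dt;
        double axp = (nvx - vxp[i]) / dt, ayp = (nvy - vyp[i]) / dt;
        double rxf = m[i] * axp - fx[i], ryf = m[i] * ayp - fy[i];
        double vbx = 0.5 * (nvx + vxp[i]), vby = 0.5 * (nvy + vyp[i]);
        dWext += (rxf * vbx + ryf * vby) * dt;
        x[i] = nx_; y[i] = ny_;
        vx[i] = nvx; vy[i] = nvy;
      }
    }
    Wint += dWint;
    Wext += dWext;

    // tracked (brain) CM kinematics: velocity series (differentiated at
    // a fixed physical window on the R side) plus the raw per-step peak
    if (track_nodes.size() > 0) {
      double vx_cm = 0, vy_cm = 0, ax_cm = 0, ay_cm = 0;
      for (int k = 0; k < track_nodes.size(); ++k) {
        int i = track_nodes[k];
        vx_cm += track_w[k] * vx[i];
        vy_cm += track_w[k] * vy[i];
        ax_cm += track_w[k] * (vx[i] - vxp[i]) / dt;
        ay_cm += track_w[k] * (vy[i] - vyp[i]) / dt;
      }
      vcm_series(s, 0) = vx_cm;
      vcm_series(s, 1) = vy_cm;
      double ar = std::sqrt(ax_cm * ax_cm + ay_cm * ay_cm);
      if (ar > acm_peak) acm_peak = ar;
    }
    for (int i = 0; i < N; ++i) { vxp[i] = vx[i]; vyp[i] = vy[i]; }

    // ---- frames / energies ---------------------------------------------
    if (s % save_every == 0) {
      double KE = 0;
      for (int i = 0; i < N; ++i)
        KE += 0.5 * m[i] * (vx[i] * vx[i] + vy[i] * vy[i]);
      frame_t[frame_i] = t0 + s * dt;
      energy(frame_i, 0) = KE;
      energy(frame_i, 1) = Wint + hg_energy;
      energy(frame_i, 2) = Wext;
      energy(frame_i, 3) = hg_energy;
      energy(frame_i, 4) = t0 + s * dt;
      double tot = std::fabs(KE) + std::fabs(Wint + hg_energy);
      if (tot > peak_total_energy) peak_total_energy = tot;
      acm_series[frame_i] = acm_peak;
      ++frame_i;
      if (!std::isfinite(KE)) { status = 2; status_time = t0 + s * dt; break; }
    }
  }

  NumericMatrix vel_final(N, 2), pos_final(N, 2);
  for (int i = 0; i < N; ++i) {
    vel_final(i, 0) = vx[i]; vel_final(i, 1) = vy[i];
    pos_final(i, 0) = x[i];  pos_final(i, 1) = y[i];
  }
  return List::create(
    _["frames_F"] = frF, _["frames_stress"] = frS,
    _["vel_final"] = vel_final, _["pos_final"] = pos_final,
    _["frame_times"] = frame_t, _["n_frames"] = frame_i,
    _["energy"] = energy,
    _["peaks"] = peaks, _["peak_times"] = peak_t, _["signed_minima"] = pmin,
    _["acm_peak"] = acm_peak, _["acm_series"] = acm_series,
    _["vcm_series"] = vcm_series,
    _["contact_force"] = contact_force,
    _["Wint"] = Wint, _["Wext"] = Wext, _["hg_energy"] = hg_energy,
    _["peak_total_energy"] = peak_total_energy,
    _["status"] = status, _["status_time"] = status_time,
    _["bad_elem"] = bad_elem + 1);
}
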