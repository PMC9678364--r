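// Compiled hot path: total potential energy and analytic gradient of the
// assembled network (stretching, bending, motor/linker springs, boundary
// repulsion).  The excluded-volume term, which is optional and off by
// default, is evaluated in R and added by the wrapper.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct SysRef {
  const int *si, *sj, *b1, *b2, *b3;
  const double *l0;
  int ns, nb, np;
  const int *sp_i1, *sp_i2, *sp_j1, *sp_j2, *sp_kind;
  const double *sp_f1, *sp_f2, *sp_K, *sp_l0;
  double K_str, K_bend;
  int geom_shape;
  double geomR, geomH2, eps, lam, a0;
};

// total energy and gradient into gx/gy/gz (must be zeroed by caller);
// returns total energy
static double energy_core(const double *px, const double *py,
                          const double *pz, int nv, const SysRef &S,
                          double *gx, double *gy, double *gz,
                          bool want_grad,
                          double *parts /* 5: str bend mot lnk bdy */) {
  double U_str = 0, U_bend = 0, U_mot = 0, U_lnk = 0, U_bdy = 0;
  for (int k = 0; k < S.ns; ++k) {
    int i = S.si[k] - 1, j = S.sj[k] - 1;
    double dx = px[j] - px[i], dy = py[j] - py[i], dz = pz[j] - pz[i];
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dl = l - S.l0[k];
    U_str += 0.5 * S.K_str * dl * dl;
    if (want_grad && l > 1e-12) {
      double c = S.K_str * dl / l;
      gx[j] += c * dx; gy[j] += c * dy; gz[j] += c * dz;
      gx[i] -= c * dx; gy[i] -= c * dy; gz[i] -= c * dz;
    }
  }
  for (int k = 0; k < S.nb; ++k) {
    int i = S.b1[k] - 1, j = S.b2[k] - 1, m = S.b3[k] - 1;
    double ux = px[j] - px[i], uy = py[j] - py[i], uz = pz[j] - pz[i];
    double vx = px[m] - px[j], vy = py[m] - py[j], vz = pz[m] - pz[j];
    double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double lv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (lu < 1e-12 || lv < 1e-12) continue;
    double dot = ux * vx + uy * vy + uz * vz;
    double co = dot / (lu * lv);
    if (co > 1.0) co = 1.0; else if (co < -1.0) co = -1.0;
    U_bend += S.K_bend * (1.0 - co);
    if (want_grad) {
      double iluv = 1.0 / (lu * lv);
      double cu = co / (lu * lu), cv = co / (lv * lv);
      double dcux = vx * iluv - cu * ux, dcuy = vy * iluv - cu * uy,
             dcuz = vz * iluv - cu * uz;
      double dcvx = ux * iluv - cv * vx, dcvy = uy * iluv - cv * vy,
             dcvz = uz * iluv - cv * vz;
      gx[i] += S.K_bend * dcux; gy[i] += S.K_bend * dcuy;
      gz[i] += S.K_bend * dcuz;
      gx[j] += S.K_bend * (dcvx - dcux);
      gy[j] += S.K_bend * (dcvy - dcuy);
      gz[j] += S.K_bend * (dcvz - dcuz);
      gx[m] -= S.K_bend * dcvx; gy[m] -= S.K_bend * dcvy;
      gz[m] -= S.K_bend * dcvz;
    }
  }
  for (int k = 0; k < S.np; ++k) {
    int i1 = S.sp_i1[k] - 1, i2 = S.sp_i2[k] - 1;
    int j1 = S.sp_j1[k] - 1, j2 = S.sp_j2[k] - 1;
    double f1 = S.sp_f1[k], f2 = S.sp_f2[k];
    double ax = (1 - f1) * px[i1] + f1 * px[i2];
    double ay = (1 - f1) * py[i1] + f1 * py[i2];
    double az = (1 - f1) * pz[i1] + f1 * pz[i2];
    double bx2 = (1 - f2) * px[j1] + f2 * px[j2];
    double by2 = (1 - f2) * py[j1] + f2 * py[j2];
    double bz2 = (1 - f2) * pz[j1] + f2 * pz[j2];
    double dx = bx2 - ax, dy = by2 - ay, dz = bz2 - az;
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dl = l - S.sp_l0[k];
    double u = 0.5 * S.sp_K[k] * dl * dl;
    if (S.sp_kind[k] == 0) U_mot += u; else U_lnk += u;
    if (want_grad && l > 1e-12) {
      double c = S.sp_K[k] * dl / l;
      double fx = c * dx, fy = c * dy, fz = c * dz;
      gx[j1] += (1 - f2) * fx; gy[j1] += (1 - f2) * fy;
      gz[j1] += (1 - f2) * fz;
      gx[j2] += f2 * fx; gy[j2] += f2 * fy; gz[j2] += f2 * fz;
      gx[i1] -= (1 - f1) * fx; gy[i1] -= (1 - f1) * fy;
      gz[i1] -= (1 - f1) * fz;
      gx[i2] -= f1 * fx; gy[i2] -= f1 * fy; gz[i2] -= f1 * fz;
    }
  }
  const double ilam = 1.0 / S.lam;
  for (int k = 0; k < S.ns; ++k) {
    int i = S.si[k] - 1, j = S.sj[k] - 1;
    double sxs[3] = {px[i], px[j], 0.5 * (px[i] + px[j])};
    double sys_[3] = {py[i], py[j], 0.5 * (py[i] + py[j])};
    double szs[3] = {pz[i], pz[j], 0.5 * (pz[i] + pz[j])};
    for (int s = 0; s < 3; ++s) {
      double x = sxs[s], y = sys_[s], z = szs[s];
      double gxx = 0, gyy = 0, gzz = 0;
      if (S.geom_shape == 0) {
        double r = std::sqrt(x * x + y * y);
        double uw = S.eps * std::exp(-(S.geomR - r - S.a0) * ilam);
        U_bdy += uw;
        if (r > 1e-9) { gxx += uw * ilam * x / r; gyy += uw * ilam * y / r; }
        double ut = S.eps * std::exp(-(S.geomH2 - z - S.a0) * ilam);
        double ub = S.eps * std::exp(-(z + S.geomH2 - S.a0) * ilam);
        U_bdy += ut + ub;
        gzz += (ut - ub) * ilam;
      } else {
        double r = std::sqrt(x * x + y * y + z * z);
        double u = S.eps * std::exp(-(S.geomR - r - S.a0) * ilam);
        U_bdy += u;
        if (r > 1e-9) {
          double c = u * ilam / r;
          gxx += c * x; gyy += c * y; gzz += c * z;
        }
      }
      if (want_grad) {
        double wi = (s == 0) ? 1.0 : (s == 2 ? 0.5 : 0.0);
        double wj = (s == 1) ? 1.0 : (s == 2 ? 0.5 : 0.0);
        gx[i] += wi * gxx; gy[i] += wi * gyy; gz[i] += wi * gzz;
        gx[j] += wj * gxx; gy[j] += wj * gyy; gz[j] += wj * gzz;
      }
    }
  }
  if (parts) {
    parts[0] = U_str; parts[1] = U_bend; parts[2] = U_mot;
    parts[3] = U_lnk; parts[4] = U_bdy;
  }
  return U_str + U_bend + U_mot + U_lnk + U_bdy;
}

static SysRef make_sysref(IntegerVector &si, IntegerVector &sj,
                          NumericVector &l0, IntegerVector &b1,
                          IntegerVector &b2, IntegerVector &b3,
                          IntegerVector &sp_i1, IntegerVector &sp_i2,
                          NumericVector &sp_f1, IntegerVector &sp_j1,
                          IntegerVector &sp_j2, NumericVector &sp_f2,
                          NumericVector &sp_K, NumericVector &sp_l0,
                          IntegerVector &sp_kind, double K_str,
                          double K_bend, int geom_shape, double geomR,
                          double geomH2, double eps, double lam,
                          double a0) {
  SysRef S;
  S.si = si.begin(); S.sj = sj.begin(); S.l0 = l0.begin();
  S.b1 = b1.begin(); S.b2 = b2.begin(); S.b3 = b3.begin();
  S.ns = si.size(); S.nb = b1.size(); S.np = sp_i1.size();
  S.sp_i1 = sp_i1.begin(); S.sp_i2 = sp_i2.begin();
  S.sp_j1 = sp_j1.begin(); S.sp_j2 = sp_j2.begin();
  S.sp_kind = sp_kind.begin();
  S.sp_f1 = sp_f1.begin(); S.sp_f2 = sp_f2.begin();
  S.sp_K = sp_K.begin(); S.sp_l0 = sp_l0.begin();
  S.K_str = K_str; S.K_bend = K_bend; S.geom_shape = geom_shape;
  S.geomR = geomR; S.geomH2 = geomH2; S.eps = eps; S.lam = lam;
  S.a0 = a0;
  return S;
}

// [[Rcpp::export(name = ".lbfgs_min_cpp")]]
List lbfgs_min_cpp(NumericMatrix P,
                   IntegerVector si, IntegerVector sj, NumericVector l0,
                   IntegerVector b1, IntegerVector b2, IntegerVector b3,
                   IntegerVector sp_i1, IntegerVector sp_i2,
                   NumericVector sp_f1,
                   IntegerVector sp_j1, IntegerVector sp_j2,
                   NumericVector sp_f2,
                   NumericVector sp_K, NumericVector sp_l0,
                   IntegerVector sp_kind,
                   double K_str, double K_bend, int geom_shape,
                   double geomR, double geomH2,
                   double eps, double lam, double a0,
                   double tol, int maxit) {
  SysRef S = make_sysref(si, sj, l0, b1, b2, b3, sp_i1, sp_i2, sp_f1,
                         sp_j1, sp_j2, sp_f2, sp_K, sp_l0, sp_kind,
                         K_str, K_bend, geom_shape, geomR, geomH2,
                         eps, lam, a0);
  const int nv = P.nrow();
  const int n = 3 * nv;
  std::vector<double> x(n);
  for (int i = 0; i < nv; ++i) {
    x[3 * i] = P(i, 0); x[3 * i + 1] = P(i, 1); x[3 * i + 2] = P(i, 2);
  }
  std::vector<double> gx(nv), gy(nv), gz(nv);
  auto eval = [&](const std::vector<double> &xx, std::vector<double> &g)
      -> double {
    std::vector<double> tx(nv), ty(nv), tz(nv);
    for (int i = 0; i < nv; ++i) {
      tx[i] = xx[3 * i]; ty[i] = xx[3 * i + 1]; tz[i] = xx[3 * i + 2];
    }
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    std::fill(gz.begin(), gz.end(), 0.0);
    double U = energy_core(tx.data(), ty.data(), tz.data(), nv, S,
                           gx.data(), gy.data(), gz.data(), true, nullptr);
    for (int i = 0; i < nv; ++i) {
      g[3 * i] = gx[i]; g[3 * i + 1] = gy[i]; g[3 * i + 2] = gz[i];
    }
    return U;
  };
  const int m = 8;
  std::vector<std::vector<double>> sk(m, std::vector<double>(n)),
      yk(m, std::vector<double>(n));
  std::vector<double> rho(m), alpha(m);
  std::vector<double> g(n), gprev(n), xprev(n), d(n), q(n);
  double U = eval(x, g);
  int nev = 1, mem = 0, head = 0;
  double bestU = U;
  std::vector<double> bestx = x;
  bool converged = false;
  for (int it = 0; it < maxit; ++it) {
    double gmax = 0;
    for (int i = 0; i < n; ++i) gmax = std::max(gmax, std::fabs(g[i]));
    if (gmax <= tol) { converged = true; break; }
    // two-loop recursion
    q = g;
    for (int k = 0; k < mem; ++k) {
      int idx = (head - 1 - k + m * 4) % m;
      double a_ = rho[idx] * std::inner_product(sk[idx].begin(),
                                                sk[idx].end(), q.begin(),
                                                0.0);
      alpha[idx] = a_;
      for (int i = 0; i < n; ++i) q[i] -= a_ * yk[idx][i];
    }
    double gamma = 1.0;
    if (mem > 0) {
      int last = (head - 1 + m) % m;
      double yy = std::inner_product(yk[last].begin(), yk[last].end(),
                                     yk[last].begin(), 0.0);
      double sy = 1.0 / rho[last];
      if (yy > 0) gamma = sy / yy;
    } else {
      gamma = 1.0 / std::max(1.0, gmax);  // conservative first step
    }
    for (int i = 0; i < n; ++i) q[i] *= gamma;
    // second loop (oldest to newest)
    for (int k = mem - 1; k >= 0; --k) {
      int idx = (head - 1 - k + m * 4) % m;
      double b_ = rho[idx] * std::inner_product(yk[idx].begin(),
                                                yk[idx].end(), q.begin(),
                                                0.0);
      for (int i = 0; i < n; ++i) q[i] += (alpha[idx] - b_) * sk[idx][i];
    }
    for (int i = 0; i < n; ++i) d[i] = -q[i];
    double gd = std::inner_product(g.begin(), g.end(), d.begin(), 0.0);
    if (gd > -1e-16) {  // not a descent direction: reset
      mem = 0; head = 0;
      for (int i = 0; i < n; ++i) d[i] = -g[i] / std::max(1.0, gmax);
      gd = std::inner_product(g.begin(), g.end(), d.begin(), 0.0);
    }
    // clamp step so no coordinate moves more than 25 nm at unit step
    double dmax = 0;
    for (int i = 0; i < n; ++i) dmax = std::max(dmax, std::fabs(d[i]));
    double smax = dmax > 25.0 ? 25.0 / dmax : 1.0;
    double step = std::min(1.0, smax);
    xprev = x; gprev = g;
    double Unew = U;
    bool ok = false;
    for (int ls = 0; ls < 30; ++ls) {
      for (int i = 0; i < n; ++i) x[i] = xprev[i] + step * d[i];
      Unew = eval(x, g);
      ++nev;
      if (Unew <= U + 1e-4 * step * gd) { ok = true; break; }
      step *= 0.5;
    }
    if (!ok) { x = xprev; g = gprev; break; }
    // memory update
    int idx = head;
    double sy = 0;
    for (int i = 0; i < n; ++i) {
      sk[idx][i] = x[i] - xprev[i];
      yk[idx][i] = g[i] - gprev[i];
      sy += sk[idx][i] * yk[idx][i];
    }
    if (sy > 1e-12) {
      rho[idx] = 1.0 / sy;
      head = (head + 1) % m;
      if (mem < m) ++mem;
    }
    U = Unew;
    if (U < bestU) { bestU = U; bestx = x; }
    if (nev >= maxit) break;
  }
  if (!converged && bestU < U) { x = bestx; U = eval(x, g); ++nev; }
  NumericMatrix Pout(nv, 3);
  for (int i = 0; i < nv; ++i) {
    Pout(i, 0) = x[3 * i]; Pout(i, 1) = x[3 * i + 1];
    Pout(i, 2) = x[3 * i + 2];
  }
  double gmax = 0;
  for (int i = 0; i < n; ++i) gmax = std::max(gmax, std::fabs(g[i]));
  return List::create(_["P"] = Pout, _["U"] = U, _["gmax"] = gmax,
                      _["evals"] = nev,
                      _["converged"] = converged || gmax <= tol);
}

// [[Rcpp::export(name = ".energy_gradient_cpp")]]
List energy_gradient_cpp(NumericMatrix P,
                         IntegerVector si, IntegerVector sj,
                         NumericVector l0,
                         IntegerVector b1, IntegerVector b2,
                         IntegerVector b3,
                         IntegerVector sp_i1, IntegerVector sp_i2,
                         NumericVector sp_f1,
                         IntegerVector sp_j1, IntegerVector sp_j2,
                         NumericVector sp_f2,
                         NumericVector sp_K, NumericVector sp_l0,
                         IntegerVector sp_kind, // 0 motor, 1 linker
                         double K_str, double K_bend,
                         int geom_shape,        // 0 oblate, 1 sphere
                         double geomR, double geomH2,
                         double eps, double lam, double a0,
                         bool want_grad) {
  SysRef S = make_sysref(si, sj, l0, b1, b2, b3, sp_i1, sp_i2, sp_f1,
                         sp_j1, sp_j2, sp_f2, sp_K, sp_l0, sp_kind,
                         K_str, K_bend, geom_shape, geomR, geomH2,
                         eps, lam, a0);
  const int nv = P.nrow();
  std::vector<double> px(nv), py(nv), pz(nv), gx(nv), gy(nv), gz(nv);
  for (int i = 0; i < nv; ++i) {
    px[i] = P(i, 0); py[i] = P(i, 1); pz[i] = P(i, 2);
  }
  double parts[5];
  energy_core(px.data(), py.data(), pz.data(), nv, S,
              gx.data(), gy.data(), gz.data(), want_grad, parts);
  NumericMatrix G(want_grad ? nv : 1, 3);
  if (want_grad)
    for (int i = 0; i < nv; ++i) {
      G(i, 0) = gx[i]; G(i, 1) = gy[i]; G(i, 2) = gz[i];
    }
  // spring tensions (recomputed cheaply)
  const int np = S.np;
  NumericVector tension(np);
  for (int k = 0; k < np; ++k) {
    int i1 = S.sp_i1[k] - 1, i2 = S.sp_i2[k] - 1;
    int j1 = S.sp_j1[k] - 1, j2 = S.sp_j2[k] - 1;
    double f1 = S.sp_f1[k], f2 = S.sp_f2[k];
    double dx = (1 - f2) * px[j1] + f2 * px[j2] -
                ((1 - f1) * px[i1] + f1 * px[i2]);
    double dy = (1 - f2) * py[j1] + f2 * py[j2] -
                ((1 - f1) * py[i1] + f1 * py[i2]);
    double dz = (1 - f2) * pz[j1] + f2 * pz[j2] -
                ((1 - f1) * pz[i1] + f1 * pz[i2]);
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    tension[k] = S.sp_K[k] * (l - S.sp_l0[k]);
  }
  return List::create(_["U_str"] = parts[0], _["U_bend"] = parts[1],
                      _["U_motor"] = parts[2], _["U_linker"] = parts[3],
                      _["U_bdy"] = parts[4], _["G"] = G,
                      _["tension"] = tension);
}
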