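#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Penalized network energy
//   E = sum_j W(lambda_j) + sum_k A_k * Phi(J_k),  Phi(J) = exp(-Q (J - b))
// with W the fiber energy of effective stretch (two constitutive families)
// and J the oriented deformed/reference area ratio of each triangle.
// Positions are a flat vector (x1, y1, x2, y2, ...); the gradient is exact.

namespace {

// exponent clamp: keeps the penalty finite during aggressive line-search
// trial steps; a converged solution must never sit at the clamp
const double EXP_CAP = 500.0;

inline double ipow(double x, int k) {
  double r = 1.0;
  for (int i = 0; i < k; ++i) r *= x;
  return r;
}

// fiber force S(lambda); family 1: lam^k - 1; family 2: lam^k - lam^(k-2)
inline double fiber_S(int family, int k, double lam) {
  if (family == 1) return ipow(lam, k) - 1.0;
  return ipow(lam, k) - ipow(lam, k - 2);
}

// fiber energy W(lambda), antiderivative of S with W(1) = 0
inline double fiber_W(int family, int k, double lam) {
  if (family == 1)
    return ipow(lam, k + 1) / (k + 1.0) - lam + k / (k + 1.0);
  return ipow(lam, k + 1) / (k + 1.0) - ipow(lam, k - 1) / (k - 1.0)
       + 2.0 / ((k - 1.0) * (k + 1.0));
}

struct NetRef {
  const int *ei, *ej;        // 0-based edge endpoints
  const double *l0;
  int E;
  const int *ta, *tb, *tc;   // 0-based triangle vertices (CCW in reference)
  const double *A0;          // positive reference areas
  int K;
  int family, k;
  double Q, b;
};

// energy and (optionally) gradient; returns energy, sets clamped flag
double net_eval(const NetRef &net, const double *pos, double *grad,
                bool *clamped) {
  double E = 0.0;
  if (clamped) *clamped = false;
  for (int e = 0; e < net.E; ++e) {
    const int i = net.ei[e], j = net.ej[e];
    const double dx = pos[2 * i] - pos[2 * j];
    const double dy = pos[2 * i + 1] - pos[2 * j + 1];
    const double r = std::sqrt(dx * dx + dy * dy);
    const double lam = r / net.l0[e];
    E += fiber_W(net.family, net.k, lam);
    if (grad && r > 0.0) {
      const double coef = fiber_S(net.family, net.k, lam) / (net.l0[e] * r);
      grad[2 * i]     += coef * dx;
      grad[2 * i + 1] += coef * dy;
      grad[2 * j]     -= coef * dx;
      grad[2 * j + 1] -= coef * dy;
    }
  }
  for (int t = 0; t < net.K; ++t) {
    const int a = net.ta[t], b = net.tb[t], c = net.tc[t];
    const double ax = pos[2 * a], ay = pos[2 * a + 1];
    const double bx = pos[2 * b], by = pos[2 * b + 1];
    const double cx = pos[2 * c], cy = pos[2 * c + 1];
    const double twoA = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    const double J = twoA / (2.0 * net.A0[t]);
    double arg = -net.Q * (J - net.b);
    if (arg > EXP_CAP) {
      arg = EXP_CAP;
      if (clamped) *clamped = true;
    }
    if (arg < -34.0) continue;  // Phi < 1.7e-15: below double resolution
    const double phi = std::exp(arg);
    E += net.A0[t] * phi;
    if (grad && arg < EXP_CAP) {
      // d(A0 * phi)/dx = A0 * phi' * dJ/dx, dJ/dx = d(twoA)/dx / (2 A0)
      const double coef = -net.Q * phi * 0.5;
      grad[2 * a]     += coef * (by - cy);
      grad[2 * a + 1] += coef * (cx - bx);
      grad[2 * b]     += coef * (cy - ay);
      grad[2 * b + 1] += coef * (ax - cx);
      grad[2 * c]     += coef * (ay - by);
      grad[2 * c + 1] += coef * (bx - ax);
    }
  }
  return E;
}

NetRef make_net(const IntegerMatrix &edges, const NumericVector &l0,
                const IntegerMatrix &tris, const NumericVector &A0,
                int family, int k, double Q, double b,
                std::vector<int> &buf) {
  const int E = edges.nrow(), K = tris.nrow();
  buf.resize(2 * E + 3 * K);
  for (int e = 0; e < E; ++e) {
    buf[e] = edges(e, 0) - 1;
    buf[E + e] = edges(e, 1) - 1;
  }
  for (int t = 0; t < K; ++t) {
    buf[2 * E + t] = tris(t, 0) - 1;
    buf[2 * E + K + t] = tris(t, 1) - 1;
    buf[2 * E + 2 * K + t] = tris(t, 2) - 1;
  }
  NetRef net;
  net.ei = buf.data(); net.ej = buf.data() + E;
  net.l0 = REAL(l0); net.E = E;
  net.ta = buf.data() + 2 * E;
  net.tb = buf.data() + 2 * E + K;
  net.tc = buf.data() + 2 * E + 2 * K;
  net.A0 = REAL(A0); net.K = K;
  net.family = family; net.k = k; net.Q = Q; net.b = b;
  return net;
}

} // namespace

// [[Rcpp::export(name = ".net_energy_cpp")]]
double net_energy_cpp(NumericVector pos, IntegerMatrix edges, NumericVector l0,
                      IntegerMatrix tris, NumericVector A0,
                      int family, int k, double Q, double b) {
  std::vector<int> buf;
  NetRef net = make_net(edges, l0, tris, A0, family, k, Q, b, buf);
  return net_eval(net, REAL(pos), nullptr, nullptr);
}

// [[Rcpp::export(name = ".net_energy_grad_cpp")]]
List net_energy_grad_cpp(NumericVector pos, IntegerMatrix edges,
                         NumericVector l0, IntegerMatrix tris,
                         NumericVector A0, int family, int k,
                         double Q, double b) {
  std::vector<int> buf;
  NetRef net = make_net(edges, l0, tris, A0, family, k, Q, b, buf);
  NumericVector grad(pos.size());
  bool clamped = false;
  double E = net_eval(net, REAL(pos), REAL(grad), &clamped);
  return List::create(_["energy"] = E, _["gradient"] = grad,
                      _["clamped"] = clamped);
}

// Polak-Ribiere+ nonlinear conjugate gradient with a strong-Wolfe line
// search (bracket + interpolated zoom, Armijo backtracking as fallback).
// Fixed DOFs are enforced by zeroing their gradient and direction
// components (they never move). grad_tol is tested on the root-mean-square
// gradient over free DOFs (scale-free across mesh sizes).
// [[Rcpp::export(name = ".nlcg_cpp")]]
List nlcg_cpp(NumericVector pos0, LogicalVector free_dof,
              IntegerMatrix edges, NumericVector l0,
              IntegerMatrix tris, NumericVector A0,
              int family, int k, double Q, double b,
              double grad_tol, int max_iter, int restart_period,
              double c1, double c2, double step0) {
  const int n = pos0.size();
  std::vector<int> buf;
  NetRef net = make_net(edges, l0, tris, A0, family, k, Q, b, buf);

  std::vector<double> x(REAL(pos0), REAL(pos0) + n);
  std::vector<double> g(n), gnew(n), d(n), xt(n), gt(n);
  std::vector<char> freev(n);
  int n_free = 0;
  for (int i = 0; i < n; ++i) {
    freev[i] = free_dof[i] ? 1 : 0;
    if (freev[i]) ++n_free;
  }

  long n_eval = 0;
  bool clamped = false;

  auto eval = [&](const double *xx, double *gg) {
    std::fill(gg, gg + n, 0.0);
    double f = net_eval(net, xx, gg, &clamped);
    for (int i = 0; i < n; ++i)
      if (!freev[i]) gg[i] = 0.0;
    ++n_eval;
    return f;
  };
  auto dot = [&](const std::vector<double> &u, const std::vector<double> &v) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += u[i] * v[i];
    return s;
  };
  auto grms = [&](const std::vector<double> &gg) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += gg[i] * gg[i];
    return std::sqrt(s / std::max(1, n_free));
  };

  double f = eval(x.data(), g.data());
  for (int i = 0; i < n; ++i) d[i] = -g[i];
  double gTd = -dot(g, g);
  double alpha_prev = -1.0, gTd_prev = gTd;

  int iter = 0;
  bool converged = grms(g) <= grad_tol;

  // phi(a) = f(x + a d); evaluates into (xt, gt)
  auto phi = [&](double a, double &dphi) {
    for (int i = 0; i < n; ++i) xt[i] = x[i] + a * d[i];
    double fa = eval(xt.data(), gt.data());
    dphi = R_finite(fa) ? dot(gt, d) : R_PosInf;
    return fa;
  };

  while (!converged && iter < max_iter) {
    ++iter;
    if (gTd >= 0.0) {
      for (int i = 0; i < n; ++i) d[i] = -g[i];
      gTd = -dot(g, g);
      alpha_prev = -1.0;
      if (gTd == 0.0) break;
    }
    const double phi0 = f, dphi0 = gTd;

    // initial trial step: keep the directional decrease rate of last step
    double alpha;
    if (alpha_prev > 0.0) {
      alpha = alpha_prev * gTd_prev / gTd;
      if (!(alpha > 0.0) || !R_finite(alpha)) alpha = alpha_prev;
      alpha = std::min(std::max(alpha, 0.1 * alpha_prev), 10.0 * alpha_prev);
    } else {
      double dinf = 0.0;
      for (int i = 0; i < n; ++i) dinf = std::max(dinf, std::fabs(d[i]));
      alpha = (dinf > 0.0) ? step0 / dinf : 1.0;
    }

    bool ok = false;
    double a = alpha, fa = phi0, dphia = dphi0;

    // bracketing phase
    double lo = 0.0, flo = phi0, dplo = dphi0;
    double hi = -1.0, fhi = 0.0;
    double ap = 0.0, fp = phi0;
    for (int ls = 0; ls < 30; ++ls) {
      fa = phi(a, dphia);
      if (!R_finite(fa)) { a = ap + 0.25 * (a - ap); continue; }
      if (fa > phi0 + c1 * a * dphi0 || (ls > 0 && fa >= fp)) {
        lo = ap; flo = fp; hi = a; fhi = fa;
        dplo = (ap == 0.0) ? dphi0 : dplo;
        break;
      }
      if (std::fabs(dphia) <= -c2 * dphi0) { ok = true; break; }
      if (dphia >= 0.0) {
        lo = a; flo = fa; dplo = dphia; hi = ap; fhi = fp;
        break;
      }
      ap = a; fp = fa; dplo = dphia;
      a *= 2.0;
    }

    // zoom phase with safeguarded quadratic interpolation
    if (!ok && hi >= 0.0) {
      for (int z = 0; z < 30; ++z) {
        const double span = hi - lo;
        double trial;
        const double denom = fhi - flo - dplo * span;
        if (denom != 0.0 && R_finite(denom))
          trial = lo - 0.5 * dplo * span * span / denom;
        else
          trial = lo + 0.5 * span;
        const double lo_s = std::min(lo, hi), hi_s = std::max(lo, hi);
        const double margin = 0.1 * std::fabs(span);
        if (!R_finite(trial) || trial < lo_s + margin || trial > hi_s - margin)
          trial = 0.5 * (lo + hi);
        a = trial;
        fa = phi(a, dphia);
        if (!R_finite(fa) || fa > phi0 + c1 * a * dphi0 || fa >= flo) {
          hi = a; fhi = fa;
        } else {
          if (std::fabs(dphia) <= -c2 * dphi0) { ok = true; break; }
          if (dphia * (hi - lo) >= 0.0) { hi = lo; fhi = flo; }
          lo = a; flo = fa; dplo = dphia;
        }
        if (std::fabs(hi - lo) < 1e-14 * (1.0 + std::fabs(lo))) break;
      }
      if (!ok && lo > 0.0 && flo < phi0) {
        // best sufficient-decrease point found: accept it
        a = lo;
        fa = phi(a, dphia);
        ok = R_finite(fa) && fa < phi0;
      }
    }

    if (!ok) {
      // Armijo backtracking fallback: accept any sufficient decrease
      a = alpha;
      for (int bt = 0; bt < 40 && !ok; ++bt) {
        fa = phi(a, dphia);
        if (R_finite(fa) && fa <= phi0 + c1 * a * dphi0) ok = true;
        else a *= 0.5;
      }
    }
    if (!ok) {
      // no decrease possible along d; restart once, else we are at a
      // numerical stationary point
      bool was_sd = (alpha_prev < 0.0);
      if (was_sd) break;
      for (int i = 0; i < n; ++i) d[i] = -g[i];
      gTd = -dot(g, g);
      alpha_prev = -1.0;
      continue;
    }

    // accept the step (xt, gt hold the last phi evaluation at a)
    std::swap(x, xt);
    std::swap(gnew, gt);
    f = fa;
    alpha_prev = a;
    gTd_prev = dphia;

    double beta = 0.0;
    if (iter % restart_period != 0) {
      const double gg = dot(g, g);
      if (gg > 0.0) {
        double num = 0.0;
        for (int i = 0; i < n; ++i) num += gnew[i] * (gnew[i] - g[i]);
        beta = std::max(0.0, num / gg);
      }
    }
    for (int i = 0; i < n; ++i) d[i] = -gnew[i] + beta * d[i];
    std::swap(g, gnew);
    gTd = dot(g, d);
    if (grms(g) <= grad_tol) converged = true;
    if (iter % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  // diagnostics at the final point (also refreshes the clamp flag there)
  double fr = eval(x.data(), gt.data());
  NumericVector out(n);
  std::copy(x.begin(), x.end(), REAL(out));
  return List::create(_["positions"] = out,
                      _["energy"] = fr,
                      _["grad_norm"] = grms(gt),
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["n_eval"] = (double)n_eval,
                      _["clamped"] = clamped);
}
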