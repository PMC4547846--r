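#include <Rcpp.h>
using namespace Rcpp;

// Finite-difference time integration of the 1D cortical gradient models on
// [0, L] with zero-flux boundaries. Two schemes: explicit Euler and
// semi-implicit (backward Euler on diffusion via a tridiagonal Thomas solve,
// explicit reaction). The source is a node-wise density vector whose
// trapezoidal integral equals the total influx S.

// model kinds (must match R side): 0 trans, 1 cis, 2 cluster, 3 combined
enum Kind { TRANS = 0, CIS = 1, CLUSTER = 2, COMBINED = 3 };

static inline double dcoef(double P, double D0, double Pstar, double h) {
  // concentration-dependent diffusion, Hill-type decreasing law
  return D0 / (1.0 + std::pow(P / Pstar, h));
}

// second-order zero-flux Laplacian (ghost-node reflection)
static void laplacian(const std::vector<double>& P, double dx,
                      std::vector<double>& out) {
  const int n = P.size();
  const double idx2 = 1.0 / (dx * dx);
  out[0] = 2.0 * (P[1] - P[0]) * idx2;
  for (int j = 1; j < n - 1; ++j)
    out[j] = (P[j - 1] - 2.0 * P[j] + P[j + 1]) * idx2;
  out[n - 1] = 2.0 * (P[n - 2] - P[n - 1]) * idx2;
}

// flux-form divergence with face diffusivities, zero-flux boundaries
static void divflux(const std::vector<double>& P, const std::vector<double>& Df,
                    double dx, std::vector<double>& out) {
  const int n = P.size();
  const double idx2 = 1.0 / (dx * dx);
  // Df[j] is the diffusivity at face j+1/2, length n-1
  out[0] = Df[0] * (P[1] - P[0]) * idx2 * 2.0;
  for (int j = 1; j < n - 1; ++j)
    out[j] = (Df[j] * (P[j + 1] - P[j]) - Df[j - 1] * (P[j] - P[j - 1])) * idx2;
  out[n - 1] = -Df[n - 2] * (P[n - 1] - P[n - 2]) * idx2 * 2.0;
}

// Full right-hand side of the simplified models.
static void rhs_simple(const std::vector<double>& P, double dx, double D,
                       double alpha, int kind, const NumericVector& src,
                       double D0, double Pstar, double h,
                       std::vector<double>& scratch, std::vector<double>& out) {
  const int n = P.size();
  if (kind == CLUSTER || kind == COMBINED) {
    std::vector<double>& Df = scratch;  // face diffusivities
    for (int j = 0; j < n - 1; ++j)
      Df[j] = dcoef(0.5 * (P[j] + P[j + 1]), D0, Pstar, h);
    divflux(P, Df, dx, out);
  } else {
    laplacian(P, dx, out);
    for (int j = 0; j < n; ++j) out[j] *= D;
  }
  if (kind == TRANS || kind == COMBINED)
    for (int j = 0; j < n; ++j) out[j] += src[j] - alpha * P[j] * P[j];
  else
    for (int j = 0; j < n; ++j) out[j] += src[j] - alpha * P[j];
}

// Thomas solve of (I + dt*diag(extra) - dt*L) x = rhs, where L is the
// (possibly concentration-dependent) diffusion operator with zero-flux
// boundaries and `extra` holds the linearly-implicit loss rates. The fixed
// point of this iteration satisfies the exact discrete steady-state
// equations, so dt only controls convergence, not accuracy.
static void implicit_step(std::vector<double>& P, const std::vector<double>& rhs,
                          const std::vector<double>& extra, double dt, double dx,
                          const std::vector<double>& Df,
                          std::vector<double>& cp, std::vector<double>& dp) {
  const int n = P.size();
  const double r = dt / (dx * dx);
  // row j: -r*Df[j-1]*x[j-1] + (1 + dt*extra[j] + r*(Df[j-1]+Df[j]))*x[j]
  //        - r*Df[j]*x[j+1]; boundary rows use reflected ghosts (factor 2)
  double b0 = 1.0 + dt * extra[0] + 2.0 * r * Df[0];
  double c0 = -2.0 * r * Df[0];
  cp[0] = c0 / b0;
  dp[0] = rhs[0] / b0;
  for (int j = 1; j < n - 1; ++j) {
    double a = -r * Df[j - 1];
    double b = 1.0 + dt * extra[j] + r * (Df[j - 1] + Df[j]);
    double c = -r * Df[j];
    double m = b - a * cp[j - 1];
    cp[j] = c / m;
    dp[j] = (rhs[j] - a * dp[j - 1]) / m;
  }
  double an = -2.0 * r * Df[n - 2];
  double bn = 1.0 + dt * extra[n - 1] + 2.0 * r * Df[n - 2];
  double m = bn - an * cp[n - 2];
  dp[n - 1] = (rhs[n - 1] - an * dp[n - 2]) / m;
  P[n - 1] = dp[n - 1];
  for (int j = n - 2; j >= 0; --j) P[j] = dp[j] - cp[j] * P[j + 1];
}

// [[Rcpp::export(name = ".cpp_solve_simplified")]]
List cpp_solve_simplified(NumericVector init, double dx, double D, double alpha,
                          int kind, NumericVector src, double dt, double rel_tol,
                          double max_time, int scheme, double D0, double Pstar,
                          double h, int check_every) {
  const int n = init.size();
  std::vector<double> P(init.begin(), init.end());
  std::vector<double> rate(n), scratch(n), Df(n - 1), cp(n), dp(n);
  std::vector<double> rhs(n), extra(n);
  double t = 0.0, resid = R_PosInf;
  long steps = 0;
  bool converged = false, unstable = false;
  std::vector<double> res_t, res_v;

  while (t < max_time) {
    for (int it = 0; it < check_every; ++it) {
      if (scheme == 0) {  // explicit Euler
        rhs_simple(P, dx, D, alpha, kind, src, D0, Pstar, h, scratch, rate);
        for (int j = 0; j < n; ++j) P[j] += dt * rate[j];
      } else {  // implicit diffusion and (linearized) decay, explicit source
        if (kind == CLUSTER || kind == COMBINED)
          for (int j = 0; j < n - 1; ++j)
            Df[j] = dcoef(0.5 * (P[j] + P[j + 1]), D0, Pstar, h);
        else
          std::fill(Df.begin(), Df.end(), D);
        if (kind == TRANS || kind == COMBINED)
          for (int j = 0; j < n; ++j) extra[j] = alpha * P[j];
        else
          for (int j = 0; j < n; ++j) extra[j] = alpha;
        for (int j = 0; j < n; ++j) rhs[j] = P[j] + dt * src[j];
        implicit_step(P, rhs, extra, dt, dx, Df, cp, dp);
      }
      t += dt;
      ++steps;
    }
    rhs_simple(P, dx, D, alpha, kind, src, D0, Pstar, h, scratch, rate);
    double mr = 0.0, mp = 0.0;
    for (int j = 0; j < n; ++j) {
      if (!std::isfinite(P[j])) { unstable = true; break; }
      mr = std::max(mr, std::fabs(rate[j]));
      mp = std::max(mp, P[j]);
    }
    if (unstable) break;
    resid = mr / std::max(mp, 1e-300);
    res_t.push_back(t);
    res_v.push_back(resid);
    if (resid < rel_tol) { converged = true; break; }
  }

  return List::create(_["values"] = NumericVector(P.begin(), P.end()),
                      _["converged"] = converged, _["unstable"] = unstable,
                      _["residual"] = resid, _["time"] = t,
                      _["steps"] = (double)steps,
                      _["residual_time"] = NumericVector(res_t.begin(), res_t.end()),
                      _["residual_value"] = NumericVector(res_v.begin(), res_v.end()));
}

// Detailed N-state model: columns of the state matrix are phospho-states
// 0..N; phosphorylation moves mass up the ladder at rate beta*Ptot, state i
// detaches at kappa[i].
static void rhs_multi(const std::vector<std::vector<double> >& P, double dx,
                      double D, double beta, const NumericVector& kappa,
                      const NumericVector& src,
                      std::vector<std::vector<double> >& out,
                      std::vector<double>& tot) {
  const int ns = P.size();
  const int n = P[0].size();
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    for (int i = 0; i < ns; ++i) s += P[i][j];
    tot[j] = s;
  }
  for (int i = 0; i < ns; ++i) laplacian(P[i], dx, out[i]);
  for (int j = 0; j < n; ++j) {
    const double bp = beta * tot[j];
    out[0][j] = D * out[0][j] + src[j] - bp * P[0][j] - kappa[0] * P[0][j];
    for (int i = 1; i < ns - 1; ++i)
      out[i][j] = D * out[i][j] + bp * (P[i - 1][j] - P[i][j]) - kappa[i] * P[i][j];
    out[ns - 1][j] = D * out[ns - 1][j] + bp * P[ns - 2][j] -
                     kappa[ns - 1] * P[ns - 1][j];
  }
}

// [[Rcpp::export(name = ".cpp_solve_detailed")]]
List cpp_solve_detailed(NumericMatrix init, double dx, double D, double beta,
                        NumericVector kappa, NumericVector src, double dt,
                        double rel_tol, double max_time, int scheme,
                        int check_every) {
  const int n = init.nrow();
  const int ns = init.ncol();
  std::vector<std::vector<double> > P(ns, std::vector<double>(n));
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < n; ++j) P[i][j] = init(j, i);
  std::vector<std::vector<double> > rate(ns, std::vector<double>(n));
  std::vector<double> tot(n), Df(n - 1, D), cp(n), dp(n), rhs(n), extra(n);
  double t = 0.0, resid = R_PosInf;
  long steps = 0;
  bool converged = false, unstable = false;
  std::vector<double> res_t, res_v;

  while (t < max_time) {
    for (int it = 0; it < check_every; ++it) {
      if (scheme == 0) {
        rhs_multi(P, dx, D, beta, kappa, src, rate, tot);
        for (int i = 0; i < ns; ++i)
          for (int j = 0; j < n; ++j) P[i][j] += dt * rate[i][j];
      } else {
        // implicit diffusion and loss (lagged beta*P), explicit gain terms;
        // species updated top-down so gains read the previous step's values
        for (int j = 0; j < n; ++j) {
          double s = 0.0;
          for (int i = 0; i < ns; ++i) s += P[i][j];
          tot[j] = s;
        }
        for (int i = ns - 1; i >= 0; --i) {
          if (i == 0) {
            for (int j = 0; j < n; ++j) {
              extra[j] = beta * tot[j] + kappa[0];
              rhs[j] = P[0][j] + dt * src[j];
            }
          } else if (i == ns - 1) {
            for (int j = 0; j < n; ++j) {
              extra[j] = kappa[ns - 1];
              rhs[j] = P[ns - 1][j] + dt * beta * tot[j] * P[ns - 2][j];
            }
          } else {
            for (int j = 0; j < n; ++j) {
              extra[j] = beta * tot[j] + kappa[i];
              rhs[j] = P[i][j] + dt * beta * tot[j] * P[i - 1][j];
            }
          }
          implicit_step(P[i], rhs, extra, dt, dx, Df, cp, dp);
        }
      }
      t += dt;
      ++steps;
    }
    rhs_multi(P, dx, D, beta, kappa, src, rate, tot);
    double mr = 0.0, mp = 0.0;
    for (int j = 0; j < n; ++j) mp = std::max(mp, tot[j]);
    for (int i = 0; i < ns; ++i)
      for (int j = 0; j < n; ++j) {
        if (!std::isfinite(P[i][j])) { unstable = true; }
        mr = std::max(mr, std::fabs(rate[i][j]));
      }
    if (unstable) break;
    resid = mr / std::max(mp, 1e-300);
    res_t.push_back(t);
    res_v.push_back(resid);
    if (resid < rel_tol) { converged = true; break; }
  }

  NumericMatrix out(n, ns);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < n; ++j) out(j, i) = P[i][j];
  return List::create(_["species"] = out, _["converged"] = converged,
                      _["unstable"] = unstable, _["residual"] = resid,
                      _["time"] = t, _["steps"] = (double)steps,
                      _["residual_time"] = NumericVector(res_t.begin(), res_t.end()),
                      _["residual_value"] = NumericVector(res_v.begin(), res_v.end()));
}
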