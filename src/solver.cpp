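#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Tridiagonal system with precomputed Thomas factorisation.
// Solves (d, u, l) x = b where d is the diagonal after factorisation.
struct Tridiag {
  std::vector<double> lower, diag, upper; // raw matrix
  std::vector<double> cp;                 // factorised superdiagonal
  std::vector<double> denom;              // factorised pivots (reciprocals)
  int n;

  void factor() {
    cp.assign(n, 0.0);
    denom.assign(n, 0.0);
    double piv = diag[0];
    if (piv == 0.0) stop("singular tridiagonal system");
    denom[0] = 1.0 / piv;
    cp[0] = upper[0] * denom[0];
    for (int i = 1; i < n; ++i) {
      piv = diag[i] - lower[i] * cp[i - 1];
      if (piv == 0.0) stop("singular tridiagonal system");
      denom[i] = 1.0 / piv;
      if (i < n - 1) cp[i] = upper[i] * denom[i];
    }
  }

  // in-place solve, b becomes x
  void solve(std::vector<double>& b) const {
    b[0] *= denom[0];
    for (int i = 1; i < n; ++i)
      b[i] = (b[i] - lower[i] * b[i - 1]) * denom[i];
    for (int i = n - 2; i >= 0; --i)
      b[i] -= cp[i] * b[i + 1];
  }
};

// y = (I + w*M) x for tridiagonal M given by (ml, md, mu)
static void tri_apply(const std::vector<double>& ml,
                      const std::vector<double>& md,
                      const std::vector<double>& mu,
                      double w, const std::vector<double>& x,
                      std::vector<double>& y) {
  int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    double acc = (1.0 + w * md[i]) * x[i];
    if (i > 0) acc += w * ml[i] * x[i - 1];
    if (i < n - 1) acc += w * mu[i] * x[i + 1];
    y[i] = acc;
  }
}

// Crank-Nicolson integrator (with backward-Euler startup steps to damp the
// non-smooth initial condition) for the three-layer diffusion system with a
// well-mixed blood compartment and local TFV -> TFV-DP conversion.
//
// Layer layout: cells 0..ng-1 gel, ng..ng+ne-1 epithelium, rest stroma.
// Units: lengths cm, time hr, diffusivities cm^2/hr, concentrations ng/mL.
//
// [[Rcpp::export(name = ".cn_solver")]]
List cn_solver(int ng, int ne, int ns,
               double dxg, double dxe, double dxs,
               double Dg, double De, double Ds,
               double phi_ge, double phi_es,
               double kD, double kB, double kL,
               double C0, double VB_ml, double area_cm2,
               double kon, double koff, double neff_e, double neff_s,
               double dt, int n_steps, IntegerVector out_steps,
               int rannacher_steps) {
  const int N = ng + ne + ns;
  if (N < 3) stop("need at least one cell per layer");

  // assemble tridiagonal M (dc/dt = M c)
  std::vector<double> ml(N, 0.0), md(N, 0.0), mu(N, 0.0);
  std::vector<double> dx(N), sink(N);
  for (int i = 0; i < N; ++i) {
    if (i < ng)            { dx[i] = dxg; sink[i] = kD; }
    else if (i < ng + ne)  { dx[i] = dxe; sink[i] = 0.0; }
    else                   { dx[i] = dxs; sink[i] = kB; }
  }
  // face between cells i and i+1: flux J = (phi*c_i - c_{i+1}) / R
  for (int i = 0; i < N - 1; ++i) {
    double phi, R;
    if (i == ng - 1) {                 // gel | epithelium
      phi = phi_ge;
      R = phi_ge * (0.5 * dxg) / Dg + (0.5 * dxe) / De;
    } else if (i == ng + ne - 1) {     // epithelium | stroma
      phi = phi_es;
      R = phi_es * (0.5 * dxe) / De + (0.5 * dxs) / Ds;
    } else {
      phi = 1.0;
      double Dl = (i < ng) ? Dg : (i < ng + ne ? De : Ds);
      R = dx[i] / Dl;
    }
    double invR = 1.0 / R;
    md[i]     -= phi * invR / dx[i];
    mu[i]     += invR / dx[i];
    ml[i + 1] += phi * invR / dx[i + 1];
    md[i + 1] -= invR / dx[i + 1];
  }
  for (int i = 0; i < N; ++i) md[i] -= sink[i];

  // factorise CN matrix (I - dt/2 M) and BE half-step matrix (I - dt/2 M)
  // used twice per dt during the Rannacher startup
  Tridiag Acn; Acn.n = N;
  Acn.lower.assign(N, 0.0); Acn.diag.assign(N, 0.0); Acn.upper.assign(N, 0.0);
  const double h2 = 0.5 * dt;
  for (int i = 0; i < N; ++i) {
    Acn.lower[i] = -h2 * ml[i];
    Acn.diag[i]  = 1.0 - h2 * md[i];
    Acn.upper[i] = -h2 * mu[i];
  }
  Acn.factor();
  Tridiag Abe = Acn; // same matrix: BE with step dt/2 equals I - (dt/2) M
  Abe.factor();

  // state
  std::vector<double> c(N, 0.0), cold(N), rhs(N);
  for (int i = 0; i < ng; ++i) c[i] = C0;
  std::vector<double> dp(ne + ns, 0.0);
  double Cb = 0.0, loss_dil = 0.0, loss_clr = 0.0;

  const int n_out = out_steps.size();
  NumericMatrix out_gel(n_out, ng), out_epi(n_out, ne), out_str(n_out, ns);
  NumericMatrix out_dpe(n_out, ne), out_dps(n_out, ns);
  NumericVector out_blood(n_out), out_ldil(n_out), out_lclr(n_out);

  auto stroma_sum = [&](const std::vector<double>& v) {
    double s = 0.0;
    for (int i = ng + ne; i < N; ++i) s += v[i];
    return s * dxs;
  };
  auto gel_sum = [&](const std::vector<double>& v) {
    double s = 0.0;
    for (int i = 0; i < ng; ++i) s += v[i];
    return s * dxg;
  };

  auto record = [&](int k) {
    for (int i = 0; i < ng; ++i) out_gel(k, i) = std::max(c[i], 0.0);
    for (int i = 0; i < ne; ++i) {
      out_epi(k, i) = std::max(c[ng + i], 0.0);
      out_dpe(k, i) = std::max(dp[i], 0.0);
    }
    for (int i = 0; i < ns; ++i) {
      out_str(k, i) = std::max(c[ng + ne + i], 0.0);
      out_dps(k, i) = std::max(dp[ne + i], 0.0);
    }
    out_blood[k] = std::max(Cb, 0.0);
    out_ldil[k] = loss_dil;
    out_lclr[k] = loss_clr;
  };

  int k_out = 0;
  if (k_out < n_out && out_steps[k_out] == 0) record(k_out++);

  const double neg_tol = -1e-9 * (C0 > 0 ? C0 : 1.0);
  const double a_dp = kon + koff;

  for (int step = 1; step <= n_steps; ++step) {
    cold = c;
    double Sold = kB * area_cm2 * stroma_sum(c) / VB_ml;
    double Cb_old = Cb;

    if (step <= rannacher_steps) {
      // two backward-Euler half-steps of size dt/2 (Rannacher smoothing of
      // the discontinuous initial condition); BE is an M-matrix scheme and
      // preserves non-negativity exactly.  Per half-step h the discrete
      // tissue budget is m_new - m_old = -h * sum(sink * c_new * dx), so
      // implicit-endpoint loss accumulation keeps the ledger exact.
      const double hh = 0.5 * dt;
      for (int half = 0; half < 2; ++half) {
        rhs = c;
        Abe.solve(rhs);
        c = rhs;
        double Snew = kB * area_cm2 * stroma_sum(c) / VB_ml;
        Cb = (Cb + hh * Snew) / (1.0 + hh * kL);
        for (int i = 0; i < ne + ns; ++i) {
          double neff = (i < ne) ? neff_e : neff_s;
          dp[i] = (dp[i] + hh * kon * neff * c[ng + i]) / (1.0 + hh * a_dp);
        }
        loss_dil += area_cm2 * hh * kD * gel_sum(c);
        loss_clr += VB_ml * hh * kL * Cb;
      }
      (void)Sold; (void)Cb_old;
    } else {
      // Crank-Nicolson: (I - dt/2 M) c_new = (I + dt/2 M) c_old
      tri_apply(ml, md, mu, h2, c, rhs);
      Acn.solve(rhs);
      c = rhs;
      double Snew = kB * area_cm2 * stroma_sum(c) / VB_ml;
      Cb = (Cb_old * (1.0 - h2 * kL) + h2 * (Sold + Snew)) / (1.0 + h2 * kL);
      for (int i = 0; i < ne + ns; ++i) {
        double neff = (i < ne) ? neff_e : neff_s;
        dp[i] = (dp[i] * (1.0 - h2 * a_dp) +
                 h2 * kon * neff * (cold[ng + i] + c[ng + i])) /
                (1.0 + h2 * a_dp);
      }
      loss_dil += area_cm2 * h2 * kD * (gel_sum(cold) + gel_sum(c));
      loss_clr += VB_ml * h2 * kL * (Cb_old + Cb);
    }

    double cmin = 0.0;
    for (int i = 0; i < N; ++i) if (c[i] < cmin) cmin = c[i];
    if (cmin < neg_tol)
      stop("solver failure: negative concentration %g at step %d (t = %g hr)",
           cmin, step, step * dt);
    if (!std::isfinite(c[0]) || !std::isfinite(c[N - 1]) || !std::isfinite(Cb))
      stop("solver failure: non-finite state at step %d (t = %g hr)",
           step, step * dt);

    if (k_out < n_out && out_steps[k_out] == step) record(k_out++);
  }

  if (k_out != n_out) stop("internal error: missed output samples");

  return List::create(
    _["tfv_gel"] = out_gel, _["tfv_epi"] = out_epi, _["tfv_stroma"] = out_str,
    _["dp_epi"] = out_dpe, _["dp_stroma"] = out_dps,
    _["blood_tfv"] = out_blood,
    _["loss_dilution"] = out_ldil, _["loss_clearance"] = out_lclr);
}
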