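#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Tridiagonal (Thomas) solve: sub a, diag b, sup c, rhs d; solution left in d.
// The backward-Euler FV matrices below are irreducibly diagonally dominant
// M-matrices, so no pivoting is needed.
static void thomas(std::vector<double> &a, std::vector<double> &b,
                   std::vector<double> &c, std::vector<double> &d, int n) {
  for (int i = 1; i < n; ++i) {
    double m = a[i] / b[i - 1];
    b[i] -= m * c[i - 1];
    d[i] -= m * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

// One backward-Euler step of h_i dx/dt = div(D grad x) - k_i x + q_i on a
// 1D cell-centred mesh. g holds the N-1 interior face conductances
// (harmonic mean of the two half-cell resistances, units m/s); the bottom
// boundary is zero-flux, the top either zero-flux or Dirichlet at x_top with
// conductance g_top = D_top / (h_top/2).
static void be_step(std::vector<double> &x, const std::vector<double> &h,
                    const std::vector<double> &g, const std::vector<double> &k,
                    const std::vector<double> &q, double dt, bool dirichlet_top,
                    double g_top, double x_top) {
  int n = (int)x.size();
  std::vector<double> a(n, 0.0), b(n, 0.0), c(n, 0.0), d(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double gl = (i > 0) ? g[i - 1] : 0.0;
    double gr = (i < n - 1) ? g[i] : 0.0;
    b[i] = h[i] / dt + gl + gr + h[i] * k[i];
    if (i > 0) a[i] = -gl;
    if (i < n - 1) c[i] = -gr;
    d[i] = h[i] * x[i] / dt + h[i] * q[i];
  }
  if (dirichlet_top) {
    b[n - 1] += g_top;
    d[n - 1] += g_top * x_top;
  }
  thomas(a, b, c, d, n);
  x = d;
}

static void clip_negative(std::vector<double> &x, double tol,
                          const char *species) {
  for (size_t i = 0; i < x.size(); ++i) {
    if (x[i] < 0.0) {
      if (x[i] >= -tol)
        x[i] = 0.0;
      else
        stop("negative %s concentration %.3e at cell %d exceeds tolerance",
             species, x[i], (int)i + 1);
    }
  }
}

//' @title Low-level two-domain finite-volume integrator
//' @description Advances the coupled oxygen/glucose/VEGF/cell system with
//'   implicit diffusion and semi-implicit (linearised, positivity-preserving)
//'   reactions. Called by [fv_step()] and [simulate_well()]; not intended for
//'   direct use.
//' @param widths cell widths (m), gel cells first
//' @param ngel number of gel cells
//' @param c0,s0,v0,n0 initial fields (modeling units)
//' @param par parameter vector in canonical order (see R wrappers)
//' @param c_top ambient oxygen Dirichlet value (kg/m3)
//' @param c_dirichlet apply the oxygen Dirichlet condition at the top face?
//' @param dt time step (s)
//' @param t_end final time (s); a non-multiple of dt gets a shortened last step
//' @param save_every save cadence in steps
//' @param neg_tol clip tolerance for small negative values
//' @return list of saved times and field matrices
//' @keywords internal
// [[Rcpp::export]]
List fv_core(NumericVector widths, int ngel, NumericVector c0, NumericVector s0,
             NumericVector v0, NumericVector n0, NumericVector par,
             double c_top, bool c_dirichlet, double dt, double t_end,
             int save_every, double neg_tol = 1e-12) {
  int N = widths.size();
  if (ngel < 1 || ngel >= N) stop("ngel must lie strictly inside the mesh");
  const double Dcg = par["D_c_gel"], Dcm = par["D_c_med"], Mc = par["M_c"],
               chalf = par["c_half"], Dsg = par["D_s_gel"],
               Dsm = par["D_s_med"], Ms = par["M_s"], shalf = par["s_half"],
               A = par["A"], Dvg = par["D_v_gel"], Dvm = par["D_v_med"],
               Kv = par["K_v"], alpha = par["alpha"], beta = par["beta"],
               ctau = par["c_tau"], ntau = par["n_tau"], d0 = par["delta_0"],
               dc = par["delta_c"], ds = par["delta_s"];

  std::vector<double> h(widths.begin(), widths.end());
  std::vector<double> c(c0.begin(), c0.end()), s(s0.begin(), s0.end()),
      v(v0.begin(), v0.end()), n(n0.begin(), n0.end());

  // per-cell diffusivities and face conductances per species
  auto conduct = [&](double Dg, double Dm) {
    std::vector<double> g(N - 1);
    for (int i = 0; i < N - 1; ++i) {
      double Di = (i < ngel) ? Dg : Dm;
      double Dj = (i + 1 < ngel) ? Dg : Dm;
      g[i] = 1.0 / (0.5 * h[i] / Di + 0.5 * h[i + 1] / Dj);
    }
    return g;
  };
  std::vector<double> gc = conduct(Dcg, Dcm), gs = conduct(Dsg, Dsm),
                      gv = conduct(Dvg, Dvm);
  double gc_top = ((N - 1 < ngel) ? Dcg : Dcm) / (0.5 * h[N - 1]);

  int nfull = (int)std::floor(t_end / dt + 1e-9);
  double rem = t_end - nfull * dt;
  bool partial = rem > 1e-9 * dt;
  int nsteps = nfull + (partial ? 1 : 0);
  if (save_every < 1) save_every = 1;

  std::vector<double> times;
  std::vector<std::vector<double>> Csav, Ssav, Vsav, Nsav;
  double t = 0.0;
  auto save = [&]() {
    times.push_back(t);
    Csav.push_back(c);
    Ssav.push_back(s);
    Vsav.push_back(v);
    Nsav.push_back(n);
  };
  save();

  std::vector<double> kc(N, 0.0), ks(N, 0.0), kv(N, 0.0), qz(N, 0.0),
      qv(N, 0.0);
  for (int i = 0; i < N; ++i) kv[i] = Kv;

  for (int step = 1; step <= nsteps; ++step) {
    double dts = (partial && step == nsteps) ? rem : dt;
    // reaction coefficients linearised about the state at the start of the
    // step: sinks enter the implicit diagonal (positivity-preserving),
    // the VEGF source is explicit and nonnegative.
    for (int i = 0; i < ngel; ++i) {
      kc[i] = Mc * n[i] / (c[i] + chalf);
      ks[i] = Ms * n[i] / (s[i] + shalf) * (1.0 + A * chalf / (c[i] + chalf));
      qv[i] = n[i] * (alpha * c[i] + beta * std::exp(-c[i] / ctau)) /
              (1.0 + n[i] / ntau);
    }
    std::vector<double> cold = c, sold = s;
    be_step(c, h, gc, kc, qz, dts, c_dirichlet, gc_top, c_top);
    be_step(s, h, gs, ks, qz, dts, false, 0.0, 0.0);
    be_step(v, h, gv, kv, qv, dts, false, 0.0, 0.0);
    for (int i = 0; i < ngel; ++i) {
      double del = d0 + dc * chalf / (cold[i] + chalf) +
                   ds * shalf / (sold[i] + shalf);
      n[i] /= (1.0 + dts * del);
    }
    clip_negative(c, neg_tol, "oxygen");
    clip_negative(s, neg_tol, "glucose");
    clip_negative(v, neg_tol, "VEGF");
    t += dts;
    if (step % save_every == 0 || step == nsteps) save();
  }

  int nsave = (int)times.size();
  NumericMatrix Cm(nsave, N), Sm(nsave, N), Vm(nsave, N), Nm(nsave, N);
  for (int r = 0; r < nsave; ++r)
    for (int i = 0; i < N; ++i) {
      Cm(r, i) = Csav[r][i];
      Sm(r, i) = Ssav[r][i];
      Vm(r, i) = Vsav[r][i];
      Nm(r, i) = Nsav[r][i];
    }
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["c"] = Cm, _["s"] = Sm, _["v"] = Vm, _["n"] = Nm,
                      _["partial_last_step"] = partial);
}
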