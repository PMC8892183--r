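// Closed-loop 1D-0D cardiovascular solver.
//
// 1D arterial segments: mass/momentum balance in (A, Q) with the
// elastic-viscoelastic tube law, flat-parabolic friction, axial gravity
// source, solved by the two-step explicit predictor-corrector
// (MacCormack) scheme; bifurcations and terminal/root couplings by the
// method of characteristics (Newton on outgoing Riemann invariants with
// mass + total-pressure conservation).
//
// 0D side: RLC(R) Windkessel compartments with Stevino hydrostatic
// generators on venous links, a non-linear legs-vein law, Mynard-type
// non-ideal diode valves, four time-varying-elastance chambers,
// 2-element pulmonary Windkessels, a three-layer coronary
// microcirculation, and the short-term regulation loops.
//
// Units: 1D internals in SI (Pa, m, m^3/s); 0D internals in clinical
// units (mmHg, ml, s). All exchanges convert explicitly.

#include <Rcpp.h>
#include <cmath>
#include <cstdio>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const double PA_MMHG = 133.322;
static const double GRAV = 9.81;

// ---------------------------------------------------------------------
// 1D vessel machinery
// ---------------------------------------------------------------------

struct Vessel {
  int n = 0;                 // nodes
  double dx = 0, beta = 0, gamma = 0, proj = 0, pref = 0;
  std::vector<double> A0, sA0, dA0dx;
  std::vector<double> A0f, sA0f;   // face reference areas
  std::vector<double> A, Q;          // state
  std::vector<double> Ap, Qp;        // predictor
  std::vector<double> visc;          // frozen viscoelastic source
  std::string name;
  // connectivity
  int inlet_bc = 0;    // 0 root(aortic valve) 1 junction-child 2 driver
  int outlet_bc = 0;   // 0 junction-parent 1 terminal-bed 2 driver
  // boundary star states from the characteristic/coupling solves; they
  // serve as ghost states for the next interior update and as the
  // interface fluxes handed to the 0D side
  double a_star_in = 0, q_star_in = 0, a_star_out = 0, q_star_out = 0;
  bool star_init = false;
  int term_comp = -1;  // arteriole index, or -2/-3 coronary L/R
  double term_Z = 0;   // SI terminal characteristic impedance
  double z_prox = 0;
};

struct Blood {
  double rho = 1050, mu = 0.004, chi = 1.1, kfric = 0;
  // kfric = 2*(zeta+2)*pi*nu
};

static inline double wspeed(const Vessel& v, const Blood& b, int i, double A) {
  return std::sqrt(v.beta / (2.0 * b.rho * v.A0[i])) * std::pow(A, 0.25);
}
static inline double ptube(const Vessel& v, int i, double A) {
  return v.pref + v.beta * (std::sqrt(A) - v.sA0[i]) / v.A0[i];
}
static inline double flux2(const Vessel& v, const Blood& b, int i,
                           double A, double Q) {
  return b.chi * Q * Q / A + v.beta * std::pow(A, 1.5) / (3.0 * b.rho * v.A0[i]);
}
static inline double srcQ(const Vessel& v, const Blood& b, int i,
                          double A, double Q, double sinal) {
  double geo = (v.beta / b.rho) * v.dA0dx[i] *
    ((2.0 / 3.0) * std::pow(A, 1.5) / (v.A0[i] * v.A0[i]) -
     A / (2.0 * std::pow(v.A0[i], 1.5)));
  double fric = -b.kfric * Q / A;
  double grav = GRAV * A * sinal * v.proj;
  return geo + fric + grav + v.visc[i];
}

// frozen viscoelastic momentum source from the previous step's Q
static void viscoelastic_source(Vessel& v, const Blood& b) {
  int n = v.n;
  if (v.gamma <= 0) { std::fill(v.visc.begin(), v.visc.end(), 0.0); return; }
  std::vector<double> g(n), qx(n);
  for (int i = 0; i < n; ++i)
    g[i] = v.gamma / (v.A0[i] * std::sqrt(v.A[i]));
  for (int i = 0; i < n; ++i) {
    double t;
    if (i == 0) t = (g[1] * (v.Q[1] - v.Q[0])) / (v.dx * v.dx);
    else if (i == n - 1) t = (-g[n - 2] * (v.Q[n - 1] - v.Q[n - 2])) / (v.dx * v.dx);
    else t = (0.5 * (g[i + 1] + g[i]) * (v.Q[i + 1] - v.Q[i]) -
              0.5 * (g[i] + g[i - 1]) * (v.Q[i] - v.Q[i - 1])) / (v.dx * v.dx);
    v.visc[i] = (v.A[i] / b.rho) * t;
  }
}

// Two-step Richtmyer (Lax-Wendroff) finite-volume update of the cell
// averages. Interior face fluxes come from half-step states; boundary
// face fluxes are the star states of the characteristic/coupling
// solves, so the vessel volume budget telescopes exactly to the star
// flows (conservation to rounding) while the boundary cells receive
// genuine conservative updates (no spurious boundary reflection).
static inline double flux2f(const Vessel& v, const Blood& b, int j,
                            double A, double Q) {
  return b.chi * Q * Q / A + v.beta * std::pow(A, 1.5) / (3.0 * b.rho * v.A0f[j]);
}
static void advance_1d(Vessel& v, const Blood& b, double dt, double sinal) {
  int n = v.n;
  if (!v.star_init) {
    v.a_star_in = v.A[0]; v.q_star_in = v.Q[0];
    v.a_star_out = v.A[n - 1]; v.q_star_out = v.Q[n - 1];
    v.star_init = true;
  }
  viscoelastic_source(v, b);
  std::vector<double> F1(n), F2(n), S(n);
  for (int i = 0; i < n; ++i) {
    F1[i] = v.Q[i];
    F2[i] = flux2(v, b, i, v.A[i], v.Q[i]);
    S[i] = srcQ(v, b, i, v.A[i], v.Q[i], sinal);
  }
  double r = dt / v.dx;
  std::vector<double> G1(n + 1), G2(n + 1);
  for (int j = 1; j < n; ++j) {
    double Ah = 0.5 * (v.A[j - 1] + v.A[j]) - 0.5 * r * (F1[j] - F1[j - 1]);
    double Qh = 0.5 * (v.Q[j - 1] + v.Q[j]) - 0.5 * r * (F2[j] - F2[j - 1]) +
      0.25 * dt * (S[j - 1] + S[j]);
    if (Ah <= 0 || !std::isfinite(Ah))
      stop("negative or non-finite area in vessel '%s' (state error)", v.name.c_str());
    G1[j] = Qh;
    G2[j] = flux2f(v, b, j, Ah, Qh);
  }
  // boundary faces carry the star fluxes
  G1[0] = v.q_star_in;
  G2[0] = flux2f(v, b, 0, v.a_star_in, v.q_star_in);
  G1[n] = v.q_star_out;
  G2[n] = flux2f(v, b, n, v.a_star_out, v.q_star_out);
  for (int i = 0; i < n; ++i) {
    v.A[i] -= r * (G1[i + 1] - G1[i]);
    v.Q[i] += -r * (G2[i + 1] - G2[i]) + dt * S[i];
    if (v.A[i] <= 0 || !std::isfinite(v.A[i]))
      stop("negative or non-finite area in vessel '%s' (state error)", v.name.c_str());
  }
}

// Outgoing Riemann invariants taken from the boundary cell averages,
// advanced by the velocity source (gravity + friction) over the travel
// distance from the cell center to the boundary face.
static inline double Winv(const Vessel& v, const Blood& b, int i, int sgn) {
  double c = wspeed(v, b, i, v.A[i]);
  double c0 = wspeed(v, b, i, v.A0[i]);
  return v.Q[i] / v.A[i] + sgn * 4.0 * (c - c0);
}
static inline double Wplus(const Vessel& v, const Blood& b, double sinal,
                           double dt) {
  (void)dt;
  int i = v.n - 1;
  double c = wspeed(v, b, i, v.A[i]);
  double Su = GRAV * sinal * v.proj - b.kfric * v.Q[i] / (v.A[i] * v.A[i]);
  return Winv(v, b, i, +1) + Su * (0.5 * v.dx / std::max(c, 1e-6));
}
static inline double Wminus(const Vessel& v, const Blood& b, double sinal,
                            double dt) {
  (void)dt;
  int i = 0;
  double c = wspeed(v, b, i, v.A[i]);
  double Su = GRAV * sinal * v.proj - b.kfric * v.Q[i] / (v.A[i] * v.A[i]);
  return Winv(v, b, i, -1) + Su * (0.5 * v.dx / std::max(c, 1e-6));
}

// face-based tube law and wave speed for the star solves
static inline double ptube_f(const Vessel& v, int j, double A) {
  return v.pref + v.beta * (std::sqrt(A) - v.sA0f[j]) / v.A0f[j];
}
static inline double wspeed_f(const Vessel& v, const Blood& b, int j, double A) {
  return std::sqrt(v.beta / (2.0 * b.rho * v.A0f[j])) * std::pow(A, 0.25);
}

// commit helpers: store the boundary star state; it becomes the ghost
// state of the next interior update and the interface flux of the step.
static inline void commit_inlet(Vessel& v, double A_star, double Q_star,
                                double dt) {
  (void)dt;
  v.a_star_in = A_star; v.q_star_in = Q_star;
}
static inline void commit_outlet(Vessel& v, double A_star, double Q_star,
                                 double dt) {
  (void)dt;
  v.a_star_out = A_star; v.q_star_out = Q_star;
}

// Solve inlet boundary for prescribed flow Q_b: A from u(A)*A = Q_b
static void inlet_flow_bc(Vessel& v, const Blood& b, double Qb,
                          double sinal, double dt) {
  double W = Wminus(v, b, sinal, dt);
  double A = v.a_star_in > 0 ? v.a_star_in : v.A[0];
  for (int it = 0; it < 60; ++it) {
    double c = wspeed_f(v, b, 0, A), c0 = wspeed_f(v, b, 0, v.A0f[0]);
    double u = W + 4.0 * (c - c0);
    double f = A * u - Qb;
    double df = u + c;
    double step = f / df;
    A -= step;
    if (A <= 0) A = 1e-8;
    if (std::fabs(step) < 1e-14 * std::max(A, 1e-12)) break;
  }
  commit_inlet(v, A, Qb, dt);
}

// Outlet boundary coupled to an external pressure through an impedance:
// p(A) = pd + Z * A * u(A); Z = 0 gives a prescribed-pressure outlet.
static void outlet_impedance_bc(Vessel& v, const Blood& b, double pd, double Z,
                                double sinal, double dt) {
  double W = Wplus(v, b, sinal, dt);
  int j = v.n;
  double A = v.a_star_out > 0 ? v.a_star_out : v.A[v.n - 1];
  for (int it = 0; it < 60; ++it) {
    double c = wspeed_f(v, b, j, A), c0 = wspeed_f(v, b, j, v.A0f[j]);
    double u = W - 4.0 * (c - c0);
    double f = ptube_f(v, j, A) - pd - Z * A * u;
    double dp = b.rho * c * c / A;
    double df = dp - Z * (u - c);
    double step = f / df;
    A -= step;
    if (A <= 0) A = 1e-8;
    if (std::fabs(step) < 1e-14 * std::max(A, 1e-12)) break;
  }
  double c = wspeed_f(v, b, j, A), c0 = wspeed_f(v, b, j, v.A0f[j]);
  commit_outlet(v, A, A * (W - 4.0 * (c - c0)), dt);
}

static void outlet_closed_bc(Vessel& v, const Blood& b, double sinal,
                             double dt) {
  int j = v.n;
  double W = Wplus(v, b, sinal, dt);
  double c0 = wspeed_f(v, b, j, v.A0f[j]);
  double c = c0 + W / 4.0;                       // u = 0
  double k = std::sqrt(v.beta / (2.0 * b.rho * v.A0f[j]));
  double A = std::pow(c / k, 4.0);
  commit_outlet(v, A, 0.0, dt);
}
static void inlet_closed_bc(Vessel& v, const Blood& b, double sinal,
                            double dt) {
  double W = Wminus(v, b, sinal, dt);
  double c0 = wspeed_f(v, b, 0, v.A0f[0]);
  double c = c0 - W / 4.0;
  double k = std::sqrt(v.beta / (2.0 * b.rho * v.A0f[0]));
  double A = std::pow(c / k, 4.0);
  commit_inlet(v, A, 0.0, dt);
}
static void inlet_pressure_bc(Vessel& v, const Blood& b, double pb,
                              double sinal, double dt) {
  double W = Wminus(v, b, sinal, dt);
  // invert the face tube law for A
  double s = (pb - v.pref) * v.A0f[0] / v.beta + v.sA0f[0];
  double A = s > 0 ? s * s : 1e-8;
  double c = wspeed_f(v, b, 0, A), c0 = wspeed_f(v, b, 0, v.A0f[0]);
  commit_inlet(v, A, A * (W + 4.0 * (c - c0)), dt);
}

// Junction: one parent outlet, m children inlets. Mass + total-pressure
// conservation with outgoing invariants (Newton, small dense solve).
struct Junction { int parent; std::vector<int> children; };

static void gauss_solve(std::vector<std::vector<double> >& Jm,
                        std::vector<double>& rhs) {
  int m = (int)rhs.size();
  for (int k = 0; k < m; ++k) {
    int piv = k;
    for (int r2 = k + 1; r2 < m; ++r2)
      if (std::fabs(Jm[r2][k]) > std::fabs(Jm[piv][k])) piv = r2;
    std::swap(Jm[k], Jm[piv]); std::swap(rhs[k], rhs[piv]);
    double d = Jm[k][k];
    if (d == 0) stop("junction Newton: singular Jacobian");
    for (int r2 = k + 1; r2 < m; ++r2) {
      double f = Jm[r2][k] / d;
      for (int c2 = k; c2 < m; ++c2) Jm[r2][c2] -= f * Jm[k][c2];
      rhs[r2] -= f * rhs[k];
    }
  }
  for (int k = m - 1; k >= 0; --k) {
    double s = rhs[k];
    for (int c2 = k + 1; c2 < m; ++c2) s -= Jm[k][c2] * rhs[c2];
    rhs[k] = s / Jm[k][k];
  }
}

static double junction_solve(std::vector<Vessel>& V, const Blood& b,
                             const Junction& J, double sinal, double dt) {
  Vessel& p = V[J.parent];
  int m = (int)J.children.size();
  int jp = p.n;                        // parent outlet face
  double Wp = Wplus(p, b, sinal, dt);
  std::vector<double> Wc(m);
  for (int k = 0; k < m; ++k) Wc[k] = Wminus(V[J.children[k]], b, sinal, dt);
  // unknowns x = [A_p, A_c1..A_cm] (face star areas)
  std::vector<double> x(m + 1);
  x[0] = p.a_star_out > 0 ? p.a_star_out : p.A[p.n - 1];
  for (int k = 0; k < m; ++k) {
    Vessel& c = V[J.children[k]];
    x[k + 1] = c.a_star_in > 0 ? c.a_star_in : c.A[0];
  }
  double scaleQ = std::max(std::fabs(p.q_star_out), 1e-6);
  double resid = 0;
  for (int it = 0; it <= 50; ++it) {
    double Apar = x[0];
    double cp = wspeed_f(p, b, jp, Apar), c0p = wspeed_f(p, b, jp, p.A0f[jp]);
    double up = Wp - 4.0 * (cp - c0p);
    double pp = ptube_f(p, jp, Apar) + 0.5 * b.rho * up * up;
    std::vector<double> r(m + 1, 0.0);
    std::vector<std::vector<double> > Jm(m + 1, std::vector<double>(m + 1, 0.0));
    r[0] = Apar * up;
    Jm[0][0] = up - cp;
    for (int k = 0; k < m; ++k) {
      Vessel& c = V[J.children[k]];
      double Ak = x[k + 1];
      double ck = wspeed_f(c, b, 0, Ak), c0k = wspeed_f(c, b, 0, c.A0f[0]);
      double uk = Wc[k] + 4.0 * (ck - c0k);
      r[0] -= Ak * uk;
      Jm[0][k + 1] = -(uk + ck);
      double pk = ptube_f(c, 0, Ak) + 0.5 * b.rho * uk * uk;
      r[k + 1] = pp - pk;
      Jm[k + 1][0] = b.rho * (cp * cp - up * cp) / Apar;
      Jm[k + 1][k + 1] = -b.rho * (ck * ck + uk * ck) / Ak;
    }
    resid = std::fabs(r[0]) / scaleQ;
    for (int k = 1; k <= m; ++k)
      resid = std::max(resid, std::fabs(r[k]) / (b.rho * 1e4));
    if (resid < 2e-13) break;
    if (it == 50) {
      if (resid > 1e-9)
        stop("junction Newton did not converge in 50 iterations at vessel '%s' (residual %g)",
             p.name.c_str(), resid);
      break;
    }
    gauss_solve(Jm, r);
    for (int k = 0; k <= m; ++k) {
      x[k] -= r[k];
      if (x[k] <= 0) x[k] = 1e-8;
    }
  }
  // commit the star states (boundary face fluxes of the next update)
  double Apar = x[0];
  double cp = wspeed_f(p, b, jp, Apar), c0p = wspeed_f(p, b, jp, p.A0f[jp]);
  double up = Wp - 4.0 * (cp - c0p);
  commit_outlet(p, Apar, Apar * up, dt);
  for (int k = 0; k < m; ++k) {
    Vessel& c = V[J.children[k]];
    double Ak = x[k + 1];
    double ck = wspeed_f(c, b, 0, Ak), c0k = wspeed_f(c, b, 0, c.A0f[0]);
    double uk = Wc[k] + 4.0 * (ck - c0k);
    commit_inlet(c, Ak, Ak * uk, dt);
  }
  return resid;
}

static void cfl_check(const std::vector<Vessel>& V, const Blood& b, double dt) {
  for (size_t iv = 0; iv < V.size(); ++iv) {
    const Vessel& v = V[iv];
    double m = 0;
    for (int i = 0; i < v.n; ++i) {
      double c = wspeed(v, b, i, v.A[i]);
      double u = std::fabs(v.Q[i] / v.A[i]);
      m = std::max(m, u + c);
    }
    if (dt > v.dx / m)
      stop("CFL violation in vessel '%s': dt = %g exceeds dx/(|u|+c) = %g; reduce dt below %g",
           v.name.c_str(), dt, v.dx / m, v.dx / m);
  }
}

static Vessel build_vessel(const List& spec, const Blood& b, double dx_target,
                           double pref) {
  Vessel v;
  v.name = as<std::string>(spec["name"]);
  double L = as<double>(spec["length"]);
  double rp = as<double>(spec["r_prox"]);
  double rd = as<double>(spec["r_dist"]);
  v.beta = as<double>(spec["beta"]);
  v.gamma = as<double>(spec["gamma_visc"]);
  v.proj = as<double>(spec["proj"]);
  v.pref = pref;
  int ncell = std::max(2, (int)std::ceil(L / dx_target));
  v.n = ncell;                      // cell averages
  v.dx = L / ncell;
  v.A0.resize(v.n); v.sA0.resize(v.n); v.dA0dx.resize(v.n);
  v.A0f.resize(v.n + 1); v.sA0f.resize(v.n + 1);
  v.A.resize(v.n); v.Q.assign(v.n, 0.0);
  v.Ap.resize(v.n + 1); v.Qp.resize(v.n + 1); v.visc.assign(v.n, 0.0);
  double dr = (rd - rp) / L;
  for (int i = 0; i < v.n; ++i) {
    double x = (i + 0.5) / ncell;
    double r = rp + (rd - rp) * x;
    v.A0[i] = M_PI * r * r;
    v.sA0[i] = std::sqrt(v.A0[i]);
    v.dA0dx[i] = 2.0 * M_PI * r * dr;
  }
  for (int j = 0; j <= v.n; ++j) {
    double x = (double)j / ncell;
    double r = rp + (rd - rp) * x;
    v.A0f[j] = M_PI * r * r;
    v.sA0f[j] = std::sqrt(v.A0f[j]);
  }
  return v;
}

// initialize A so that the tube pressure equals p_init everywhere
static void init_area(Vessel& v, double p_init) {
  for (int i = 0; i < v.n; ++i) {
    double s = (p_init - v.pref) * v.A0[i] / v.beta + v.sA0[i];
    v.A[i] = s > 0 ? s * s : v.A0[i];
  }
}

// ---------------------------------------------------------------------
// Single-vessel and bifurcation drivers (solver verification fixtures)
// ---------------------------------------------------------------------

static void apply_end_bc(Vessel& v, const Blood& b, const List& bc, bool inlet,
                         double t, double sinal, double dt) {
  std::string type = as<std::string>(bc["type"]);
  if (type == "closed") {
    if (inlet) inlet_closed_bc(v, b, sinal, dt); else outlet_closed_bc(v, b, sinal, dt);
  } else if (type == "flow") {
    NumericVector qt = bc["Q"];
    NumericVector tt = bc["t"];
    // linear interpolation in time
    double Qb = qt[qt.size() - 1];
    if (t <= tt[0]) Qb = qt[0];
    else {
      for (int i = 1; i < tt.size(); ++i)
        if (t <= tt[i]) {
          double w = (t - tt[i - 1]) / (tt[i] - tt[i - 1]);
          Qb = qt[i - 1] * (1 - w) + qt[i] * w;
          break;
        }
    }
    if (inlet) inlet_flow_bc(v, b, Qb, sinal, dt);
    else stop("flow outlet not supported");
  } else if (type == "pressure") {
    double pb = as<double>(bc["p"]);
    if (inlet) inlet_pressure_bc(v, b, pb, sinal, dt);
    else outlet_impedance_bc(v, b, pb, 0.0, sinal, dt);
  } else if (type == "impedance") {
    double pd = as<double>(bc["p"]);
    double Z = as<double>(bc["Z"]);
    outlet_impedance_bc(v, b, pd, Z, sinal, dt);
  } else if (type == "matched") {
    int j = v.n;
    double Z = b.rho * wspeed_f(v, b, j, v.A0f[j]) / v.A0f[j];
    double pd = as<double>(bc["p"]);
    outlet_impedance_bc(v, b, pd, Z, sinal, dt);
  } else stop("unknown boundary type '%s'", type.c_str());
}

// [[Rcpp::export]]
List cpp_run_vessel(List spec, List inlet, List outlet, double dt, int nsteps,
                    double alpha, double p_init, int record_every,
                    double rho, double mu, double chi, double zeta) {
  Blood b; b.rho = rho; b.mu = mu; b.chi = chi;
  b.kfric = 2.0 * (zeta + 2.0) * M_PI * (mu / rho);
  Vessel v = build_vessel(spec, b, as<double>(spec["dx"]), as<double>(spec["pref"]));
  init_area(v, p_init);
  double sinal = std::sin(alpha);
  std::vector<double> times;
  std::vector<std::vector<double> > Arec, Qrec, Prec;
  for (int s = 0; s <= nsteps; ++s) {
    double t = s * dt;
    if (s % record_every == 0) {
      times.push_back(t);
      std::vector<double> Ar(v.n), Qr(v.n), Pr(v.n);
      for (int i = 0; i < v.n; ++i) {
        Ar[i] = v.A[i]; Qr[i] = v.Q[i]; Pr[i] = ptube(v, i, v.A[i]);
      }
      Arec.push_back(Ar); Qrec.push_back(Qr); Prec.push_back(Pr);
    }
    if (s == nsteps) break;
    cfl_check(std::vector<Vessel>{v}, b, dt);
    advance_1d(v, b, dt, sinal);
    apply_end_bc(v, b, inlet, true, t + dt, sinal, dt);
    apply_end_bc(v, b, outlet, false, t + dt, sinal, dt);
    // re-run using the persistent object (apply_end_bc modified copy? no:
    // v is local and passed by reference; fine)
  }
  int nt = (int)times.size();
  NumericMatrix Am(nt, v.n), Qm(nt, v.n), Pm(nt, v.n);
  for (int r2 = 0; r2 < nt; ++r2)
    for (int i = 0; i < v.n; ++i) {
      Am(r2, i) = Arec[r2][i]; Qm(r2, i) = Qrec[r2][i]; Pm(r2, i) = Prec[r2][i];
    }
  NumericVector x(v.n);
  for (int i = 0; i < v.n; ++i) x[i] = i * v.dx;
  return List::create(_["time"] = wrap(times), _["x"] = x, _["A"] = Am,
                      _["Q"] = Qm, _["p"] = Pm, _["dx"] = v.dx,
                      _["A0"] = wrap(v.A0));
}

// [[Rcpp::export]]
List cpp_run_bifurcation(List parent, List children, List inlet, double outlet_p,
                         double dt, int nsteps, double p_init, int record_every,
                         double rho, double mu, double chi, double zeta) {
  Blood b; b.rho = rho; b.mu = mu; b.chi = chi;
  b.kfric = 2.0 * (zeta + 2.0) * M_PI * (mu / rho);
  std::vector<Vessel> V;
  V.push_back(build_vessel(parent, b, as<double>(parent["dx"]), as<double>(parent["pref"])));
  int m = children.size();
  Junction J; J.parent = 0;
  for (int k = 0; k < m; ++k) {
    List ch = children[k];
    V.push_back(build_vessel(ch, b, as<double>(ch["dx"]), as<double>(ch["pref"])));
    J.children.push_back(k + 1);
  }
  for (size_t i = 0; i < V.size(); ++i) init_area(V[i], p_init);
  std::vector<double> times, massdef, qparent;
  std::vector<std::vector<double> > Pmid;  // parent mid + children mid
  for (int s = 0; s <= nsteps; ++s) {
    double t = s * dt;
    if (s % record_every == 0) {
      times.push_back(t);
      std::vector<double> row;
      row.push_back(ptube(V[0], V[0].n / 2, V[0].A[V[0].n / 2]));
      row.push_back(V[0].Q[V[0].n / 2]);
      for (int k = 1; k <= m; ++k) {
        row.push_back(ptube(V[k], V[k].n / 2, V[k].A[V[k].n / 2]));
        row.push_back(V[k].Q[V[k].n / 2]);
      }
      Pmid.push_back(row);
      double md = V[0].q_star_out;
      for (int k = 1; k <= m; ++k) md -= V[k].q_star_in;
      massdef.push_back(std::fabs(md));
      qparent.push_back(std::fabs(V[0].q_star_out));
    }
    if (s == nsteps) break;
    cfl_check(V, b, dt);
    for (size_t i = 0; i < V.size(); ++i) advance_1d(V[i], b, dt, 0.0);
    junction_solve(V, b, J, 0.0, dt);
    apply_end_bc(V[0], b, inlet, true, t + dt, 0.0, dt);
    for (int k = 1; k <= m; ++k) {
      int j = V[k].n;
      double Z = b.rho * wspeed_f(V[k], b, j, V[k].A0f[j]) / V[k].A0f[j];
      outlet_impedance_bc(V[k], b, outlet_p, Z, 0.0, dt);
    }
  }
  int nt = (int)times.size(), nc = (int)Pmid[0].size();
  NumericMatrix M(nt, nc);
  for (int r2 = 0; r2 < nt; ++r2)
    for (int c2 = 0; c2 < nc; ++c2) M(r2, c2) = Pmid[r2][c2];
  return List::create(_["time"] = wrap(times), _["mid"] = M,
                      _["mass_defect"] = wrap(massdef),
                      _["q_parent"] = wrap(qparent));
}

// ---------------------------------------------------------------------
// Closed-loop model
// ---------------------------------------------------------------------

struct Effector { double val = 0, basal = 0, Gs = 0, Gp = 0, Gcp = 0,
    tau = 1, lo = -1e30, hi = 1e30; };

struct ChamberP { double Emax, Emin, Vu, onset, kc, kr; bool ventricle; };

struct CardValve { double Amax, Amin, Ko, Kc, dpo, dpc, leff, Rv; };

struct CoroLayer { double Za, Rc1, Rc2, Zv, Ca, Cc, Cv, w; };

// full mutable state advanced by the Heun scheme
struct OdeState {
  std::vector<double> Vc, qc;     // compartment volumes, outflows
  double Vch[4];                  // ra rv la lv
  double qv[4], zv[4];            // cardiac valves: tri pul mit aor
  std::vector<double> vvz;        // venous valve openings
  std::vector<double> Vcor;       // coronary volumes (a,c,v per layer)
  // regulation
  double hr, se_lv, se_rv, sr, svu, sc, xaut;
  double ema_aff, ema_ra, ema_cbf, ema_svc, ema_hart;
};

struct Model {
  Blood b;
  std::vector<Vessel> V;
  std::vector<Junction> J;
  int root_vessel = 0;
  double pref = 0;                 // Pa

  // compartments
  int nc = 0;
  std::vector<std::string> cid;
  std::vector<double> R, L, C, z, Vu0, height;
  std::vector<int> down;           // >=0 comp, -1 ra, -2 la
  std::vector<int> pextsrc;        // 0 ambient 1 intrathoracic 2 intracranial
  std::vector<int> kind;           // 0 arteriole 1 cap 2 venule 3 vein 4..6 cavae 7 pa 8 pv
  std::vector<bool> hlink, is_headart, r_ctrl, vu_ctrl, c_ctrl;
  int legs_vein = -1; double nlC0 = 0, nlDV = 0;
  int svc_idx = -1;
  std::vector<int> vvalve;         // venous valve index per comp (-1 none)
  std::vector<CardValve> vvparams; // venous valve params
  CardValve cv[4];
  ChamberP ch[4];
  double Vu_ch[4];

  // coronary
  bool coro = false;
  CoroLayer coroL[2][3];
  int coro_term[2] = {-1, -1};     // vessel indices of L/R coronary

  // regulation
  bool reg_enabled = true, aut_enabled = true;
  double nu = 7, nu_cp = 7, aff_tau = 2, cbf_tau = 4;
  Effector eHR, eElv, eErv, eR, eVu, eC;
  double Gcp_r = 0, Gcp_vu = 0, Gcp_c = 0;
  double Gaut = 20, taut = 10, Crelmin = 0.5, Crelmax = 2.2;
  double Rcsf = 480, If = 0.00583, h_head_ra = 0.31;

  double pit_sup = -4, dpit = 3;
  double hr0 = 68;

  // afferent sites: (vessel, node)
  std::vector<std::pair<int,int> > aff_nodes;
  std::vector<int> cbf_vessels;    // terminal flow sums to CBF

  // record sites
  std::vector<std::pair<int,int> > sites;
  std::vector<std::string> site_names;

  // captured targets
  bool captured = false;
  double p_target = 90, cp_target = 7, cbf_ref = 12, hart_pt0 = 70;
  double rhead_scale = 1.0;

  double total_volume = 5700;
};

static inline double e_act(const ChamberP& c, double tb, double RR) {
  double tau = tb - c.onset; tau -= std::floor(tau);
  double Tc = c.kc * std::sqrt(RR) / RR;
  double Tr = c.kr * std::sqrt(RR) / RR;
  if (c.ventricle) {
    if (tau < Tc) return 0.5 * (1.0 - std::cos(M_PI * tau / Tc));
    if (tau < Tc + Tr) return 0.5 * (1.0 + std::cos(M_PI * (tau - Tc) / Tr));
    return 0.0;
  }
  double Ta = Tc + Tr;
  if (tau < Ta) return 0.5 * (1.0 - std::cos(2.0 * M_PI * tau / Ta));
  return 0.0;
}

static inline double valveB(double Acm2, double rho) {
  double A = std::max(Acm2, 1e-6) * 1e-4;
  return (rho / (2.0 * A * A)) * 1e-12 / PA_MMHG;
}
static inline double valveL(double Acm2, double leff, double rho) {
  double A = std::max(Acm2, 1e-6) * 1e-4;
  return (rho * (leff * 1e-2) / A) * 1e-6 / PA_MMHG;
}

struct Deriv {
  std::vector<double> dVc, dqc;
  double dVch[4], dqv[4], dzv[4];
  std::vector<double> dvvz, dVcor;
  double dhr, dse_lv, dse_rv, dsr, dsvu, dsc, dxaut;
  double dema_aff, dema_ra, dema_cbf, dema_svc, dema_hart;
};

class Engine {
public:
  Model M;
  OdeState S;
  double t = 0, tbeat = 0, RR = 1;
  double alpha = 0;                 // rad
  double p_ic = 8;
  // frozen 1D inputs per step
  std::vector<double> qterm;        // ml/s per compartment (arteriole inflow)
  double p_root_mmHg = 80;
  double cbf_inst = 0;
  double coro_pterm[2] = {80, 80};  // mmHg at coronary terminals

  // per-beat accumulators
  double acc_p = 0, acc_plv = 0, acc_sv = 0, acc_T = 0;
  std::vector<double> beat_t, beat_RR, beat_map, beat_sv, beat_plv;
  std::vector<double> beat_alpha;

  double max_iface_resid = 0;
  // conservation audit: fluxes accounted at the 1D-0D interfaces (ml)
  double acc_in_1d = 0, acc_out_1d = 0, acc_lv_out = 0, acc_art_in = 0;

  Engine(const List& ml) { parse(ml); }

  void parse(const List& ml) {
    List bl = ml["blood"];
    M.b.rho = as<double>(bl["density"]);
    M.b.mu = as<double>(bl["viscosity"]);
    M.b.chi = as<double>(bl["chi"]);
    double zeta = as<double>(bl["zeta"]);
    M.b.kfric = 2.0 * (zeta + 2.0) * M_PI * (M.b.mu / M.b.rho);
    M.total_volume = as<double>(bl["total_volume"]);
    M.pref = as<double>(ml["pref_pa"]);

    // vessels
    List vl = ml["vessels"];
    double dxt = as<double>(ml["dx"]);
    for (int i = 0; i < vl.size(); ++i) {
      List vs = vl[i];
      Vessel v = build_vessel(vs, M.b, dxt, M.pref);
      v.term_comp = as<int>(vs["term_comp"]);
      v.z_prox = as<double>(vs["z_prox"]);
      M.V.push_back(v);
    }
    qterm.assign(M.V.size(), 0.0);
    List jl = ml["junctions"];
    for (int i = 0; i < jl.size(); ++i) {
      List js = jl[i];
      Junction J; J.parent = as<int>(js["parent"]);
      IntegerVector chl = js["children"];
      for (int k = 0; k < chl.size(); ++k) J.children.push_back(chl[k]);
      M.J.push_back(J);
    }
    M.root_vessel = as<int>(ml["root_vessel"]);

    // terminal impedances (SI)
    NumericVector tz = ml["term_Z"];
    for (int i = 0; i < (int)M.V.size(); ++i) M.V[i].term_Z = tz[i];

    // compartments
    List cl = ml["compartments"];
    M.nc = cl.size();
    for (int i = 0; i < M.nc; ++i) {
      List cs = cl[i];
      M.cid.push_back(as<std::string>(cs["id"]));
      M.R.push_back(as<double>(cs["R"]));
      M.L.push_back(as<double>(cs["L"]));
      M.C.push_back(as<double>(cs["C"]));
      M.z.push_back(as<double>(cs["z"]));
      M.height.push_back(as<double>(cs["height"]));
      M.down.push_back(as<int>(cs["down"]));
      M.pextsrc.push_back(as<int>(cs["pextsrc"]));
      M.kind.push_back(as<int>(cs["kind"]));
      M.vvalve.push_back(as<int>(cs["vvalve"]));
      M.Vu0.push_back(0.0);
      M.hlink.push_back(false);
      M.is_headart.push_back(as<bool>(cs["is_headart"]));
      M.r_ctrl.push_back(as<bool>(cs["r_ctrl"]));
      M.vu_ctrl.push_back(as<bool>(cs["vu_ctrl"]));
      M.c_ctrl.push_back(as<bool>(cs["c_ctrl"]));
      if (as<bool>(cs["nonlinear"])) {
        M.legs_vein = i;
        M.nlC0 = as<double>(cs["nlC0"]);
        M.nlDV = as<double>(cs["nlDV"]);
      }
      if (M.kind[i] == 4) M.svc_idx = i;
    }
    // hydrostatic link flags: either endpoint venous/caval or drains a chamber
    for (int i = 0; i < M.nc; ++i) {
      bool venous_i = M.kind[i] >= 3 && M.kind[i] <= 6;
      bool venous_d = false;
      if (M.down[i] >= 0) {
        int k = M.kind[M.down[i]];
        venous_d = k >= 3 && k <= 6;
      } else venous_d = true;   // into a chamber
      M.hlink[i] = venous_i || venous_d;
    }

    List chl = ml["chambers"];
    const char* cn[4] = {"ra", "rv", "la", "lv"};
    for (int k = 0; k < 4; ++k) {
      List cc = chl[cn[k]];
      M.ch[k].Emax = as<double>(cc["E_max"]);
      M.ch[k].Emin = as<double>(cc["E_min"]);
      M.ch[k].Vu = as<double>(cc["V_u"]);
      M.ch[k].onset = as<double>(cc["onset_frac"]);
      M.ch[k].kc = as<double>(cc["k_contract"]);
      M.ch[k].kr = as<double>(cc["k_relax"]);
      M.ch[k].ventricle = as<std::string>(cc["kind"]) == "ventricle";
      S.Vch[k] = as<double>(cc["volume"]);
    }

    List cvl = ml["cardiac_valves"];
    const char* vn[4] = {"tricuspid", "pulmonary", "mitral", "aortic"};
    for (int k = 0; k < 4; ++k) {
      List vv = cvl[vn[k]];
      M.cv[k].Amax = as<double>(vv["A_max"]); M.cv[k].Amin = as<double>(vv["A_min"]);
      M.cv[k].Ko = as<double>(vv["K_open"]); M.cv[k].Kc = as<double>(vv["K_close"]);
      M.cv[k].dpo = 0; M.cv[k].dpc = 0;
      M.cv[k].leff = as<double>(vv["l_eff"]); M.cv[k].Rv = as<double>(vv["R_visc"]);
      S.qv[k] = 0; S.zv[k] = 0;
    }
    List vvl = ml["venous_valves"];
    for (int k = 0; k < vvl.size(); ++k) {
      List vv = vvl[k];
      CardValve p;
      p.Amax = as<double>(vv["A_max"]); p.Amin = as<double>(vv["A_min"]);
      p.Ko = as<double>(vv["K_open"]); p.Kc = as<double>(vv["K_close"]);
      p.dpo = 0; p.dpc = 0;
      p.leff = as<double>(vv["l_eff"]); p.Rv = as<double>(vv["R_visc"]);
      M.vvparams.push_back(p);
      S.vvz.push_back(1.0);
    }

    // coronary
    M.coro = as<bool>(ml["coro_enabled"]);
    if (M.coro) {
      List col = ml["coronary"];
      for (int d = 0; d < 2; ++d) {
        List dd = col[d];
        NumericVector Za = dd["Z_a"], Rc1 = dd["R_c1"], Rc2 = dd["R_c2"],
          Zv = dd["Z_v"], Ca = dd["C_a"], Cc = dd["C_c"], Cv = dd["C_v"],
          w = dd["w"];
        for (int l = 0; l < 3; ++l) {
          M.coroL[d][l].Za = Za[l]; M.coroL[d][l].Rc1 = Rc1[l];
          M.coroL[d][l].Rc2 = Rc2[l]; M.coroL[d][l].Zv = Zv[l];
          M.coroL[d][l].Ca = Ca[l]; M.coroL[d][l].Cc = Cc[l];
          M.coroL[d][l].Cv = Cv[l]; M.coroL[d][l].w = w[l];
        }
        M.coro_term[d] = as<int>(dd["term_vessel"]);
        NumericVector vi = dd["V_init"];
        for (int l = 0; l < 9; ++l) S.Vcor.push_back(vi[l]);
      }
    }

    // regulation
    List rg = ml["regulation"];
    M.reg_enabled = as<bool>(rg["enabled"]);
    M.hr0 = as<double>(ml["heart_rate"]);
    if (M.reg_enabled) {
      M.nu = as<double>(rg["nu"]); M.nu_cp = as<double>(rg["nu_cp"]);
      M.aff_tau = as<double>(rg["afferent_tau"]);
      List ef = rg["effectors"];
      auto mk = [&](const char* nm, double basal) {
        List e = ef[nm];
        Effector x; x.basal = basal; x.val = basal;
        x.Gs = as<double>(e["G_sym"]); x.Gp = as<double>(e["G_para"]);
        x.tau = as<double>(e["tau"]);
        x.lo = as<double>(e["lo"]); x.hi = as<double>(e["hi"]);
        return x;
      };
      M.eHR = mk("hr", M.hr0);
      M.eElv = mk("emax_lv", 1.0); M.eErv = mk("emax_rv", 1.0);
      M.eR = mk("r_art", 1.0); M.eVu = mk("vu_ven", 1.0); M.eC = mk("c_ven", 1.0);
      List cp = rg["cardiopulmonary"];
      M.Gcp_r = as<double>(cp["G_r_art"]);
      M.Gcp_vu = as<double>(cp["G_vu"]); M.Gcp_c = as<double>(cp["G_c"]);
      List au = rg["autoregulation"];
      M.aut_enabled = as<bool>(au["enabled"]);
      if (M.aut_enabled) {
        M.Gaut = as<double>(au["G_aut"]); M.taut = as<double>(au["tau_aut"]);
        M.Crelmin = as<double>(au["C_rel_min"]); M.Crelmax = as<double>(au["C_rel_max"]);
        M.cbf_tau = as<double>(au["cbf_tau"]);
      }
      List ic = rg["icp"];
      M.Rcsf = as<double>(ic["R_csf"]); M.If = as<double>(ic["I_f"]);
      M.h_head_ra = as<double>(ic["h_head_ra"]);
    } else {
      M.aut_enabled = false;
      M.eHR.basal = M.eHR.val = M.hr0;
      M.eElv.basal = M.eElv.val = 1; M.eErv.basal = M.eErv.val = 1;
      M.eR.basal = M.eR.val = 1; M.eVu.basal = M.eVu.val = 1;
      M.eC.basal = M.eC.val = 1;
    }
    List it = ml["intrathoracic"];
    M.pit_sup = as<double>(it["p_it_supine"]);
    M.dpit = as<double>(it["delta_p_it"]);

    // afferent / cbf / site registries
    List an = ml["aff_nodes"];
    for (int i = 0; i < an.size(); ++i) {
      IntegerVector p = an[i];
      M.aff_nodes.push_back(std::make_pair(p[0], p[1]));
    }
    IntegerVector cv2 = ml["cbf_vessels"];
    for (int i = 0; i < cv2.size(); ++i) M.cbf_vessels.push_back(cv2[i]);
    List st = ml["sites"];
    CharacterVector stn = st.names();
    for (int i = 0; i < st.size(); ++i) {
      IntegerVector p = st[i];
      M.sites.push_back(std::make_pair(p[0], p[1]));
      M.site_names.push_back(as<std::string>(stn[i]));
    }

    init_states(ml);
  }

  double pext_of(int src, double pit) const {
    if (src == 1) return pit;
    if (src == 2) return p_ic;
    return 0.0;
  }

  void init_states(const List& ml) {
    NumericVector pinit = ml["p_init"];
    NumericVector valloc = ml["volume_alloc"];  // per compartment (ml)
    alpha = as<double>(ml["alpha0"]) * M_PI / 180.0;
    double pit_a = M.pit_sup - M.dpit * std::sin(alpha);
    p_ic = M.Rcsf * M.If + 7.0;
    // 1D areas at p_init_1d
    double p1d = as<double>(ml["p_init_1d_pa"]);
    for (size_t i = 0; i < M.V.size(); ++i) init_area(M.V[i], p1d);
    // compartment volumes and unstressed volumes
    S.Vc.assign(M.nc, 0.0); S.qc.assign(M.nc, 0.0);
    for (int i = 0; i < M.nc; ++i) {
      double pe = pext_of(M.pextsrc[i], pit_a);
      double pt = pinit[i] - pe;
      S.Vc[i] = valloc[i];
      if (i == M.legs_vein) {
        double k = M_PI * M.nlC0 / (2.0 * M.nlDV);
        double stressed = (2.0 * M.nlDV / M_PI) * std::atan(k * std::max(pt, 0.0));
        if (pt < 0) stressed = M.nlC0 * pt;
        M.Vu0[i] = valloc[i] - stressed;
      } else {
        M.Vu0[i] = valloc[i] - M.C[i] * pt;
      }
      if (M.Vu0[i] < 0) M.Vu0[i] = 0;   // keep volumes physical
    }
    S.hr = M.hr0; S.se_lv = S.se_rv = S.sr = S.svu = S.sc = 1.0; S.xaut = 0;
    S.ema_aff = 90; S.ema_ra = 7; S.ema_cbf = 12; S.ema_svc = 7; S.ema_hart = 70;
    RR = 60.0 / M.hr0;
  }

  double comp_pressure(const OdeState& st, int i, double pit) const {
    double pe = pext_of(M.pextsrc[i], pit);
    double Vu = M.Vu0[i] * ((M.vu_ctrl[i]) ? st.svu : 1.0);
    if (i == M.legs_vein) {
      double C0 = M.nlC0 * ((M.c_ctrl[i]) ? st.sc : 1.0);
      double dv = st.Vc[i] - Vu;
      double k = M_PI * C0 / (2.0 * M.nlDV);
      if (dv >= 0) {
        double arg = std::min(dv / M.nlDV, 0.999) * M_PI / 2.0;
        return pe + std::tan(arg) / k;
      }
      return pe + dv / C0;
    }
    double C = M.C[i] * ((M.c_ctrl[i]) ? st.sc : 1.0);
    return pe + (st.Vc[i] - Vu) / C;
  }

  double chamber_p(const OdeState& st, int k, double pit, double tb,
                   double rr) const {
    double e = e_act(M.ch[k], tb, rr);
    double scale = 1.0;
    if (k == 1) scale = st.se_rv;      // rv
    if (k == 3) scale = st.se_lv;      // lv
    double Emax = M.ch[k].Emin + (M.ch[k].Emax * scale - M.ch[k].Emin) * e;
    return Emax * (st.Vch[k] - M.ch[k].Vu) + pit;
  }

  // full derivative of the 0D + regulation state
  void deriv(const OdeState& st, double tt, double tb, Deriv& d) const {
    double al = alpha;
    double sinal = std::sin(al);
    double pit = M.pit_sup - M.dpit * sinal;
    double hgrad = M.b.rho * GRAV * sinal / PA_MMHG;   // mmHg per metre

    d.dVc.assign(M.nc, 0.0); d.dqc.assign(M.nc, 0.0);
    d.dvvz.assign(S.vvz.size(), 0.0);
    d.dVcor.assign(S.Vcor.size(), 0.0);

    // pressures
    std::vector<double> p(M.nc);
    for (int i = 0; i < M.nc; ++i) p[i] = comp_pressure(st, i, pit);
    double pch[4];
    for (int k = 0; k < 4; ++k) pch[k] = chamber_p(st, k, pit, tb, RR);

    // inflows
    std::vector<double> qin(M.nc, 0.0);
    double qin_ra = 0, qin_la = 0;
    for (size_t iv = 0; iv < M.V.size(); ++iv)
      if (M.V[iv].term_comp >= 0) qin[M.V[iv].term_comp] += qterm[iv];

    // compartment momentum / flows
    for (int i = 0; i < M.nc; ++i) {
      double pdn = 0, zdn = 0;
      if (M.down[i] >= 0) { pdn = p[M.down[i]]; zdn = M.z[M.down[i]]; }
      else if (M.down[i] == -1) { pdn = pch[0]; zdn = 0; }
      else { pdn = pch[2]; zdn = 0; }
      double H = M.hlink[i] ? hgrad * (zdn - M.z[i]) : 0.0;
      double Reff = M.R[i];
      double rfac = 1.0;
      if (M.is_headart[i]) rfac = M.rhead_scale * rhead_dynamic(st);
      else if (M.r_ctrl[i]) rfac = st.sr + cp_dr(st);
      Reff *= rfac;
      double q;
      if (M.L[i] <= 0) {                          // algebraic (2-element WK)
        q = (p[i] - pdn + H) / Reff;
        d.dqc[i] = 0;
      } else {
        q = st.qc[i];
        double drive = p[i] - pdn + H - Reff * q;
        int vi = M.vvalve[i];
        // inertance follows the resistance scaling so the R/L rate of the
        // controlled arterioles stays bounded for the explicit scheme
        double Ltot = M.L[i] * std::max(1.0, rfac);
        if (vi >= 0) {
          const CardValve& vp = M.vvparams[vi];
          double zeta = st.vvz[vi];
          double Aeff = vp.Amin + zeta * (vp.Amax - vp.Amin);
          drive -= valveB(Aeff, M.b.rho) * q * std::fabs(q);
          Ltot += valveL(Aeff, vp.leff, M.b.rho);
          double dpv = p[i] - pdn + H - M.R[i] * q;
          d.dvvz[vi] = (1.0 - zeta) * vp.Ko * std::max(dpv - vp.dpo, 0.0) -
            zeta * vp.Kc * std::max(vp.dpc - dpv, 0.0);
        }
        d.dqc[i] = drive / Ltot;
      }
      // mass bookkeeping
      if (M.down[i] >= 0) qin[M.down[i]] += q;
      else if (M.down[i] == -1) qin_ra += q;
      else qin_la += q;
      d.dVc[i] -= q;
    }
    for (int i = 0; i < M.nc; ++i) d.dVc[i] += qin[i];

    // cardiac valves: tri(ra->rv) pul(rv->pa) mit(la->lv) aor(lv->root)
    double ppa = 0;
    int ipa = -1, ipv = -1;
    for (int i = 0; i < M.nc; ++i) {
      if (M.kind[i] == 7) ipa = i;
      if (M.kind[i] == 8) ipv = i;
    }
    ppa = ipa >= 0 ? p[ipa] : 0;
    double dps[4] = {pch[0] - pch[1], pch[1] - ppa, pch[2] - pch[3],
                     pch[3] - p_root_mmHg};
    for (int k = 0; k < 4; ++k) {
      const CardValve& vp = M.cv[k];
      double zeta = st.zv[k];
      double Aeff = vp.Amin + zeta * (vp.Amax - vp.Amin);
      double B = valveB(Aeff, M.b.rho);
      double Lv = valveL(Aeff, vp.leff, M.b.rho);
      double q = st.qv[k];
      d.dqv[k] = (dps[k] - B * q * std::fabs(q) - vp.Rv * q) / Lv;
      d.dzv[k] = (1.0 - zeta) * vp.Ko * std::max(dps[k] - vp.dpo, 0.0) -
        zeta * vp.Kc * std::max(vp.dpc - dps[k], 0.0);
    }
    // chamber volumes
    d.dVch[0] = qin_ra - st.qv[0];
    d.dVch[1] = st.qv[0] - st.qv[1];
    d.dVch[2] = qin_la - st.qv[2];
    d.dVch[3] = st.qv[2] - st.qv[3];
    if (ipa >= 0) d.dVc[ipa] += st.qv[1];

    // coronary districts
    if (M.coro) {
      int s = 0;
      for (int dd = 0; dd < 2; ++dd) {
        double pcav = (dd == 0) ? (pch[3] - pit) : (pch[1] - pit);
        for (int l = 0; l < 3; ++l) {
          const CoroLayer& cl = M.coroL[dd][l];
          double Va = st.Vcor[s], Vcc = st.Vcor[s + 1], Vv = st.Vcor[s + 2];
          double pa2 = Va / cl.Ca;
          double pim = cl.w * std::max(pcav, 0.0);
          double pc2 = Vcc / cl.Cc + pim;
          double pv2 = Vv / cl.Cv;
          double qa = (coro_pterm[dd] - pa2) / cl.Za;
          double q1 = (pa2 - pc2) / cl.Rc1;
          double q2 = (pc2 - pv2) / cl.Rc2;
          double qo = (pv2 - pch[0]) / cl.Zv;
          d.dVcor[s] = qa - q1;
          d.dVcor[s + 1] = q1 - q2;
          d.dVcor[s + 2] = q2 - qo;
          d.dVch[0] += qo;
          s += 3;
        }
      }
    }

    // regulation
    double aff = afferent_pressure();
    d.dema_aff = (aff - st.ema_aff) / M.aff_tau;
    d.dema_ra = (pch[0] - st.ema_ra) / M.aff_tau;
    d.dema_cbf = (cbf_inst - st.ema_cbf) / M.cbf_tau;
    double psvc = M.svc_idx >= 0 ? p[M.svc_idx] : pch[0];
    d.dema_svc = (psvc - st.ema_svc) / M.aff_tau;
    double phart = first_headart_pt(p, st);
    d.dema_hart = (phart - st.ema_hart) / M.cbf_tau;

    if (M.reg_enabled && M.captured) {
      double r = std::pow(std::max(st.ema_aff, 1e-6) / M.p_target, M.nu);
      double ns = 1.0 / (1.0 + r), np2 = r / (1.0 + r);
      double rc = std::pow(std::max(st.ema_ra, 1e-6) / M.cp_target, M.nu_cp);
      double ncs = 1.0 / (1.0 + rc);
      auto drv = [&](const Effector& e, double val, double gcp) {
        double target = e.basal + e.Gs * (ns - 0.5) - e.Gp * (np2 - 0.5) +
          gcp * (ncs - 0.5);
        return (target - val) / e.tau;
      };
      d.dhr = drv(M.eHR, st.hr, 0.0);
      d.dse_lv = drv(M.eElv, st.se_lv, 0.0);
      d.dse_rv = drv(M.eErv, st.se_rv, 0.0);
      d.dsr = drv(M.eR, st.sr, M.Gcp_r);
      d.dsvu = drv(M.eVu, st.svu, M.Gcp_vu);
      d.dsc = drv(M.eC, st.sc, M.Gcp_c);
      if (M.aut_enabled && M.cbf_vessels.size()) {
        double err = M.Gaut * (st.ema_cbf - M.cbf_ref) / M.cbf_ref;
        d.dxaut = (err - st.xaut) / M.taut;
      } else d.dxaut = 0;
    } else {
      d.dhr = d.dse_lv = d.dse_rv = d.dsr = d.dsvu = d.dsc = d.dxaut = 0;
    }
  }

  double cp_dr(const OdeState& st) const { return 0.0; }  // folded into sr drive

  double rhead_dynamic(const OdeState& st) const {
    if (!M.aut_enabled || !M.captured) return 1.0;
    double ca = ca_rel(st.xaut);
    double pt = std::max(st.ema_hart, 5.0);
    double s = (M.hart_pt0 / (ca * pt));
    s = s * s;
    return std::min(std::max(s, 0.2), 5.0);
  }
  double ca_rel(double x) const {
    double dil = M.Crelmax - 1.0, con = 1.0 - M.Crelmin;
    if (x < 0) return 1.0 + dil * std::tanh(-2.0 * con * x / dil);
    return 1.0 - con * std::tanh(2.0 * x);
  }

  double afferent_pressure() const {
    if (M.aff_nodes.empty()) return p_root_mmHg;
    double s = 0;
    for (size_t i = 0; i < M.aff_nodes.size(); ++i) {
      const Vessel& v = M.V[M.aff_nodes[i].first];
      int nd = M.aff_nodes[i].second;
      s += ptube(v, nd, v.A[nd]) / PA_MMHG;
    }
    return s / M.aff_nodes.size();
  }

  double first_headart_pt(const std::vector<double>& p, const OdeState& st) const {
    for (int i = 0; i < M.nc; ++i)
      if (M.is_headart[i]) return p[i];       // ambient external: p = p_tm
    return 70;
  }

  void heun_step(double dt, double tt) {
    Deriv d1, d2;
    deriv(S, tt, tbeat / RR, d1);
    OdeState Sp = S;
    axpy(Sp, d1, dt);
    double tb2 = (tbeat + dt) / RR; if (tb2 >= 1) tb2 -= 1;
    deriv(Sp, tt + dt, tb2 * 1.0, d2);
    // average
    Deriv dm = d1;
    avg(dm, d2);
    axpy(S, dm, dt);
    clamp_reg();
  }

  void axpy(OdeState& s2, const Deriv& d, double dt) const {
    for (int i = 0; i < M.nc; ++i) { s2.Vc[i] += dt * d.dVc[i]; s2.qc[i] += dt * d.dqc[i]; }
    for (int k = 0; k < 4; ++k) {
      s2.Vch[k] += dt * d.dVch[k];
      s2.qv[k] += dt * d.dqv[k];
      s2.zv[k] = std::min(std::max(s2.zv[k] + dt * d.dzv[k], 0.0), 1.0);
    }
    for (size_t k = 0; k < s2.vvz.size(); ++k)
      s2.vvz[k] = std::min(std::max(s2.vvz[k] + dt * d.dvvz[k], 0.0), 1.0);
    for (size_t k = 0; k < s2.Vcor.size(); ++k) s2.Vcor[k] += dt * d.dVcor[k];
    s2.hr += dt * d.dhr; s2.se_lv += dt * d.dse_lv; s2.se_rv += dt * d.dse_rv;
    s2.sr += dt * d.dsr; s2.svu += dt * d.dsvu; s2.sc += dt * d.dsc;
    s2.xaut += dt * d.dxaut;
    s2.ema_aff += dt * d.dema_aff; s2.ema_ra += dt * d.dema_ra;
    s2.ema_cbf += dt * d.dema_cbf; s2.ema_svc += dt * d.dema_svc;
    s2.ema_hart += dt * d.dema_hart;
  }
  void avg(Deriv& a, const Deriv& b2) const {
    for (size_t i = 0; i < a.dVc.size(); ++i) {
      a.dVc[i] = 0.5 * (a.dVc[i] + b2.dVc[i]);
      a.dqc[i] = 0.5 * (a.dqc[i] + b2.dqc[i]);
    }
    for (int k = 0; k < 4; ++k) {
      a.dVch[k] = 0.5 * (a.dVch[k] + b2.dVch[k]);
      a.dqv[k] = 0.5 * (a.dqv[k] + b2.dqv[k]);
      a.dzv[k] = 0.5 * (a.dzv[k] + b2.dzv[k]);
    }
    for (size_t k = 0; k < a.dvvz.size(); ++k)
      a.dvvz[k] = 0.5 * (a.dvvz[k] + b2.dvvz[k]);
    for (size_t k = 0; k < a.dVcor.size(); ++k)
      a.dVcor[k] = 0.5 * (a.dVcor[k] + b2.dVcor[k]);
    a.dhr = 0.5 * (a.dhr + b2.dhr); a.dse_lv = 0.5 * (a.dse_lv + b2.dse_lv);
    a.dse_rv = 0.5 * (a.dse_rv + b2.dse_rv); a.dsr = 0.5 * (a.dsr + b2.dsr);
    a.dsvu = 0.5 * (a.dsvu + b2.dsvu); a.dsc = 0.5 * (a.dsc + b2.dsc);
    a.dxaut = 0.5 * (a.dxaut + b2.dxaut);
    a.dema_aff = 0.5 * (a.dema_aff + b2.dema_aff);
    a.dema_ra = 0.5 * (a.dema_ra + b2.dema_ra);
    a.dema_cbf = 0.5 * (a.dema_cbf + b2.dema_cbf);
    a.dema_svc = 0.5 * (a.dema_svc + b2.dema_svc);
    a.dema_hart = 0.5 * (a.dema_hart + b2.dema_hart);
  }
  void clamp_reg() {
    auto cl = [](double v, const Effector& e) {
      return std::min(std::max(v, e.lo), e.hi);
    };
    S.hr = cl(S.hr, M.eHR); S.se_lv = cl(S.se_lv, M.eElv);
    S.se_rv = cl(S.se_rv, M.eErv); S.sr = cl(S.sr, M.eR);
    S.svu = cl(S.svu, M.eVu); S.sc = cl(S.sc, M.eC);
  }

  // update ICP from current means (slow variable)
  void update_icp() {
    double sinal = std::sin(alpha);
    if (!M.reg_enabled) { p_ic = M.Rcsf * M.If + S.ema_ra; return; }
    double grad = M.b.rho * GRAV * sinal / PA_MMHG;
    double cvp = S.ema_ra;
    double pd;
    if (sinal <= 1e-9 || S.ema_svc > 0) {
      pd = cvp - grad * M.h_head_ra;
    } else {
      double d0 = std::min(std::max(cvp, 0.0) / grad, M.h_head_ra);
      pd = -grad * (M.h_head_ra - d0);
    }
    p_ic = M.Rcsf * M.If + pd;
  }

  // one coupled step
  void step(double dt) {
    double sinal = std::sin(alpha);
    // 1: 1D interior
    for (size_t i = 0; i < M.V.size(); ++i) advance_1d(M.V[i], M.b, dt, sinal);
    // 2: junctions
    for (size_t j = 0; j < M.J.size(); ++j) {
      double r = junction_solve(M.V, M.b, M.J[j], sinal, dt);
      max_iface_resid = std::max(max_iface_resid, r);
    }
    // 3: root inlet from aortic valve flow (ml/s -> m3/s)
    inlet_flow_bc(M.V[M.root_vessel], M.b, S.qv[3] * 1e-6, sinal, dt);
    acc_in_1d += S.qv[3] * dt;
    {
      const Vessel& rv2 = M.V[M.root_vessel];
      p_root_mmHg = ptube_f(rv2, 0, rv2.a_star_in) / PA_MMHG;
    }
    // 4: terminals
    double pit = M.pit_sup - M.dpit * sinal;
    cbf_inst = 0;
    for (size_t iv = 0; iv < M.V.size(); ++iv) {
      Vessel& v = M.V[iv];
      if (v.term_comp >= 0) {
        double pd = comp_pressure(S, v.term_comp, pit) * PA_MMHG;
        outlet_impedance_bc(v, M.b, pd, v.term_Z, sinal, dt);
        qterm[iv] = v.q_star_out * 1e6;
        acc_out_1d += qterm[iv] * dt; acc_art_in += qterm[iv] * dt;
      } else if (v.term_comp == -2 || v.term_comp == -3) {
        int dd = (v.term_comp == -2) ? 0 : 1;
        // lump 3 layers into effective impedance: p = pd_eff + Z_eff Q
        double Gt = 0, Ssum = 0;
        int s0 = dd * 9;
        for (int l = 0; l < 3; ++l) {
          double pa2 = S.Vcor[s0 + 3 * l] / M.coroL[dd][l].Ca;
          Gt += 1.0 / M.coroL[dd][l].Za;
          Ssum += pa2 / M.coroL[dd][l].Za;
        }
        double Zeff_clin = 1.0 / Gt;                   // mmHg s/ml
        double pd_eff = Ssum / Gt;                     // mmHg
        double Zsi = Zeff_clin * PA_MMHG / 1e-6;
        outlet_impedance_bc(v, M.b, pd_eff * PA_MMHG, Zsi, sinal, dt);
        coro_pterm[dd] = ptube_f(v, v.n, v.a_star_out) / PA_MMHG;
        acc_out_1d += v.q_star_out * 1e6 * dt;
      }
    }
    for (size_t k = 0; k < M.cbf_vessels.size(); ++k) {
      const Vessel& v = M.V[M.cbf_vessels[k]];
      cbf_inst += v.q_star_out * 1e6;
    }
    update_icp();
    // 5: 0D + regulation
    heun_step(dt, t);
    // 6: beat bookkeeping
    double proot = p_root_mmHg;
    double plv = chamber_p(S, 3, pit, tbeat / RR, RR);
    acc_p += proot * dt; acc_plv += plv * dt; acc_sv += S.qv[3] * dt;
    acc_T += dt;
    tbeat += dt; t += dt;
    if (tbeat >= RR) {
      beat_t.push_back(t - tbeat);
      beat_RR.push_back(RR);
      beat_map.push_back(acc_p / acc_T);
      beat_sv.push_back(acc_sv);
      beat_plv.push_back(acc_plv / acc_T);
      beat_alpha.push_back(alpha * 180.0 / M_PI);
      acc_p = acc_plv = acc_sv = acc_T = 0;
      tbeat -= RR;
      double hr = std::min(std::max(S.hr, M.eHR.lo), M.eHR.hi);
      if (!M.reg_enabled || !M.captured) hr = M.hr0;
      RR = 60.0 / hr;
    }
  }

  double tree_volume() const {          // ml (node-rectangle measure,
    double s = 0;                        //  consistent with the budget)
    for (size_t iv = 0; iv < M.V.size(); ++iv) {
      const Vessel& v = M.V[iv];
      for (int i = 0; i < v.n; ++i) s += v.A[i] * v.dx;
    }
    return s * 1e6;
  }
  double total_volume() const {
    double s = tree_volume();
    for (int i = 0; i < M.nc; ++i) s += S.Vc[i];
    for (int k = 0; k < 4; ++k) s += S.Vch[k];
    for (size_t k = 0; k < S.Vcor.size(); ++k) s += S.Vcor[k];
    return s;
  }
};

// steady detection over the last nwin beats
static bool beats_steady(const std::vector<double>& map2,
                         const std::vector<double>& rr,
                         int nwin, double tol) {
  int n = (int)map2.size();
  if (n < nwin + 1) return false;
  double m0 = 0, r0 = 0;
  for (int i = n - nwin; i < n; ++i) { m0 += map2[i]; r0 += rr[i]; }
  m0 /= nwin; r0 /= nwin;
  for (int i = n - nwin; i < n; ++i) {
    if (std::fabs(map2[i] - m0) / m0 > tol) return false;
    if (std::fabs(rr[i] - r0) / r0 > tol) return false;
  }
  return true;
}

// [[Rcpp::export]]
List cpp_run_sim(List ml, List segments, List numerics) {
  Engine E(ml);
  double dt = as<double>(numerics["dt"]);
  double out_dt = as<double>(numerics["out_dt"]);
  int out_every = std::max(1, (int)std::round(out_dt / dt));
  int cfl_every = as<int>(numerics["cfl_every"]);

  // output columns
  std::vector<std::string> names;
  const char* core[] = {"time", "alpha", "p_it", "p_ic", "hr", "rr",
                        "n_sym", "n_para", "ncp_sym", "sc_r", "sc_vu", "sc_c",
                        "sc_emax_lv", "x_aut", "ca_rel", "rhead_scale",
                        "cbf", "cbf_ema", "V_1d", "V_total", "q_root"};
  for (int i = 0; i < 21; ++i) names.push_back(core[i]);
  for (size_t i = 0; i < E.M.site_names.size(); ++i) {
    names.push_back("p_" + E.M.site_names[i]);
    names.push_back("q_" + E.M.site_names[i]);
  }
  const char* chn[4] = {"ra", "rv", "la", "lv"};
  for (int k = 0; k < 4; ++k) {
    names.push_back(std::string("p_") + chn[k]);
    names.push_back(std::string("V_") + chn[k]);
  }
  const char* vnn[4] = {"tricuspid", "pulmonary", "mitral", "aortic"};
  for (int k = 0; k < 4; ++k) names.push_back(std::string("q_") + vnn[k]);
  for (int k = 0; k < 4; ++k) names.push_back(std::string("zeta_") + vnn[k]);
  for (int i = 0; i < E.M.nc; ++i) names.push_back("p_" + E.M.cid[i]);
  for (int i = 0; i < E.M.nc; ++i) names.push_back("V_" + E.M.cid[i]);
  for (int i = 0; i < E.M.nc; ++i) names.push_back("q_" + E.M.cid[i]);
  for (size_t k = 0; k < E.S.vvz.size(); ++k) {
    char bfr[32]; snprintf(bfr, sizeof(bfr), "vv_zeta_%d", (int)k + 1);
    names.push_back(bfr);
  }
  names.push_back("q_cor_left"); names.push_back("q_cor_right");
  names.push_back("q_cor_out"); names.push_back("V_cor");
  int ncol = (int)names.size();

  std::vector<double> buf;               // row-major
  std::vector<double> phase_times;
  double t_capture = -1;

  auto record = [&](void) {
    double sinal = std::sin(E.alpha);
    double pit = E.M.pit_sup - E.M.dpit * sinal;
    std::vector<double> row;
    row.reserve(ncol);
    double ns = 0.5, np2 = 0.5, ncs = 0.5;
    if (E.M.reg_enabled && E.M.captured) {
      double r = std::pow(std::max(E.S.ema_aff, 1e-6) / E.M.p_target, E.M.nu);
      ns = 1.0 / (1.0 + r); np2 = 1.0 - ns;
      double rc = std::pow(std::max(E.S.ema_ra, 1e-6) / E.M.cp_target, E.M.nu_cp);
      ncs = 1.0 / (1.0 + rc);
    }
    row.push_back(E.t);
    row.push_back(E.alpha * 180.0 / M_PI);
    row.push_back(pit);
    row.push_back(E.p_ic);
    row.push_back(E.S.hr);
    row.push_back(E.RR);
    row.push_back(ns); row.push_back(np2); row.push_back(ncs);
    row.push_back(E.S.sr); row.push_back(E.S.svu); row.push_back(E.S.sc);
    row.push_back(E.S.se_lv);
    row.push_back(E.S.xaut);
    row.push_back(E.ca_rel(E.S.xaut));
    row.push_back(E.M.rhead_scale * E.rhead_dynamic(E.S));
    row.push_back(E.cbf_inst); row.push_back(E.S.ema_cbf);
    row.push_back(E.tree_volume()); row.push_back(E.total_volume());
    row.push_back(E.S.qv[3]);
    for (size_t i = 0; i < E.M.sites.size(); ++i) {
      const Vessel& v = E.M.V[E.M.sites[i].first];
      int nd = E.M.sites[i].second;
      row.push_back(ptube(v, nd, v.A[nd]) / PA_MMHG);
      row.push_back(v.Q[nd] * 1e6);
    }
    for (int k = 0; k < 4; ++k) {
      row.push_back(E.chamber_p(E.S, k, pit, E.tbeat / E.RR, E.RR));
      row.push_back(E.S.Vch[k]);
    }
    for (int k = 0; k < 4; ++k) row.push_back(E.S.qv[k]);
    for (int k = 0; k < 4; ++k) row.push_back(E.S.zv[k]);
    for (int i = 0; i < E.M.nc; ++i)
      row.push_back(E.comp_pressure(E.S, i, pit));
    for (int i = 0; i < E.M.nc; ++i) row.push_back(E.S.Vc[i]);
    for (int i = 0; i < E.M.nc; ++i) row.push_back(E.S.qc[i]);
    for (size_t k = 0; k < E.S.vvz.size(); ++k) row.push_back(E.S.vvz[k]);
    double qcl = 0, qcr = 0, qco = 0, vcor = 0;
    if (E.M.coro) {
      for (int dd = 0; dd < 2; ++dd) {
        int s0 = dd * 9;
        for (int l = 0; l < 3; ++l) {
          double pa2 = E.S.Vcor[s0 + 3 * l] / E.M.coroL[dd][l].Ca;
          double qa = (E.coro_pterm[dd] - pa2) / E.M.coroL[dd][l].Za;
          if (dd == 0) qcl += qa; else qcr += qa;
          double pv2 = E.S.Vcor[s0 + 3 * l + 2] / E.M.coroL[dd][l].Cv;
          double pra = E.chamber_p(E.S, 0, pit, E.tbeat / E.RR, E.RR);
          qco += (pv2 - pra) / E.M.coroL[dd][l].Zv;
        }
      }
      for (size_t k = 0; k < E.S.Vcor.size(); ++k) vcor += E.S.Vcor[k];
    }
    row.push_back(qcl); row.push_back(qcr); row.push_back(qco); row.push_back(vcor);
    buf.insert(buf.end(), row.begin(), row.end());
  };

  long stepct = 0;
  record();
  for (int seg = 0; seg < segments.size(); ++seg) {
    List sg = segments[seg];
    std::string type = as<std::string>(sg["type"]);
    phase_times.push_back(E.t);
    if (type == "hold") {
      int min_beats = as<int>(sg["min_beats"]);
      int max_beats = as<int>(sg["max_beats"]);
      double tol = as<double>(sg["steady_tol"]);
      int nwin = as<int>(sg["steady_beats"]);
      bool capture = as<bool>(sg["capture"]);
      int start_beats = (int)E.beat_t.size();
      while (true) {
        if ((stepct++ % cfl_every) == 0) cfl_check(E.M.V, E.M.b, dt);
        E.step(dt);
        if (stepct % out_every == 0) record();
        int nb = (int)E.beat_t.size() - start_beats;
        if (nb >= max_beats) break;
        if (nb >= min_beats &&
            beats_steady(E.beat_map, E.beat_RR, nwin, tol) &&
            E.tbeat < dt * 1.5) break;
      }
      if (capture && !E.M.captured) {
        E.M.p_target = E.S.ema_aff;
        E.M.cp_target = E.S.ema_ra;
        E.M.cbf_ref = std::max(E.S.ema_cbf, 1e-6);
        E.M.hart_pt0 = E.S.ema_hart;
        E.M.eHR.basal = E.M.hr0;
        E.M.captured = true;
        t_capture = E.t;
      }
    } else {  // ramp
      double a_end = as<double>(sg["alpha_end"]) * M_PI / 180.0;
      double rate = as<double>(sg["rate"]) * M_PI / 180.0;  // rad/s
      double a0 = E.alpha;
      double T = std::fabs(a_end - a0) / rate;
      double t0 = E.t;
      while (E.t < t0 + T - 0.5 * dt) {
        double s = (E.t + dt - t0) / T;
        if (s > 1) s = 1;
        E.alpha = a0 + (a_end - a0) * 0.5 * (1.0 - std::cos(M_PI * s));
        if ((stepct++ % cfl_every) == 0) cfl_check(E.M.V, E.M.b, dt);
        E.step(dt);
        if (stepct % out_every == 0) record();
      }
      E.alpha = a_end;
    }
  }
  phase_times.push_back(E.t);

  int nrow = (int)(buf.size() / ncol);
  NumericMatrix out(nrow, ncol);
  for (int r2 = 0; r2 < nrow; ++r2)
    for (int c2 = 0; c2 < ncol; ++c2) out(r2, c2) = buf[(size_t)r2 * ncol + c2];
  colnames(out) = wrap(names);

  return List::create(
    _["signals"] = out,
    _["beat_times"] = wrap(E.beat_t),
    _["beat_RR"] = wrap(E.beat_RR),
    _["beat_map"] = wrap(E.beat_map),
    _["beat_sv"] = wrap(E.beat_sv),
    _["beat_plv"] = wrap(E.beat_plv),
    _["beat_alpha"] = wrap(E.beat_alpha),
    _["phase_times"] = wrap(phase_times),
    _["t_capture"] = t_capture,
    _["targets"] = List::create(
      _["p_target"] = E.M.p_target, _["cp_target"] = E.M.cp_target,
      _["cbf_ref"] = E.M.cbf_ref, _["hart_pt0"] = E.M.hart_pt0),
    _["max_junction_resid"] = E.max_iface_resid,
    _["audit"] = List::create(_["acc_in_1d"] = E.acc_in_1d,
                              _["acc_out_1d"] = E.acc_out_1d),
    _["final_hr"] = E.S.hr);
}
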