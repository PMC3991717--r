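// Adaptive Dormand-Prince RK45 integrator for the six-state whole-body
// contrast-agent model. States are tracked internally as amounts (mmol):
//   a[0] plasma, a[1] EES, a[2] hepatocyte, a[3] splenic IS,
//   a[4] bile sink, a[5] urine sink.
// Working in amounts makes mass conservation exact up to solver error and
// independent of the per-flux reference-volume convention.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Edge {
  bool present;
  int law;        // 0 linear, 1 Michaelis-Menten
  double k;       // 1/s (linear law)
  double vmax;    // mmol/L/s (MM law)
  double km;      // mmol/L (MM law)
  double vref;    // L, reference volume turning the rate law into mmol/s
};

struct Model {
  double Vp, Ve, Vh;
  double f_alb;           // albumin-bound fraction of plasma concentration
  Edge e[6];              // pe, ep, ph, hp, hb, pu
  double rate;            // current injection rate, mmol/s (piecewise const)
};

inline double law_flux(const Edge& ed, double conc) {
  if (conc < 0.0) conc = 0.0;  // guard solver under/overshoot
  if (!ed.present) return 0.0;
  if (ed.law == 0) return ed.k * conc * ed.vref;
  return ed.vmax * conc / (ed.km + conc) * ed.vref;
}

inline void rhs(const Model& m, const double* a, double* da) {
  const double Cp = a[0] / m.Vp;
  const double Ce = a[1] / m.Ve;
  const double Ch = a[2] / m.Vh;
  // plasma->EES diffusion is driven by the free (non albumin-bound) agent
  const double Jpe = law_flux(m.e[0], (1.0 - m.f_alb) * Cp);
  const double Jep = law_flux(m.e[1], Ce);
  const double Jph = law_flux(m.e[2], Cp);
  const double Jhp = law_flux(m.e[3], Ch);
  const double Jhb = law_flux(m.e[4], Ch);
  const double Jpu = law_flux(m.e[5], Cp);
  da[0] = m.rate - Jpe + Jep - Jph + Jhp - Jpu;
  da[1] = Jpe - Jep;
  da[2] = Jph - Jhp - Jhb;
  da[3] = 0.0;              // splenic IS exchanges nothing in any variant
  da[4] = Jhb;
  da[5] = Jpu;
}

// Dormand-Prince 5(4) tableau
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
             e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

const int NS = 6;

// integrate from t0 to t1 (rate constant over the segment), in place
void integrate_segment(const Model& m, double* y, double t0, double t1,
                       double rtol, double atol, double* h_io,
                       long* nstep_io, long max_steps) {
  if (t1 <= t0) return;
  double t = t0;
  double h = *h_io;
  if (h <= 0.0 || h > (t1 - t0)) h = (t1 - t0);
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS];
  double ytmp[NS], y5[NS];
  rhs(m, y, k1);
  while (t < t1) {
    if (t + h > t1) h = t1 - t;
    for (int i = 0; i < NS; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(m, ytmp, k2);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(m, ytmp, k3);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(m, ytmp, k4);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    rhs(m, ytmp, k5);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rhs(m, ytmp, k6);
    for (int i = 0; i < NS; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    rhs(m, y5, k7);  // FSAL
    double err = 0.0;
    for (int i = 0; i < NS; ++i) {
      double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / NS);
    if (!std::isfinite(err))
      stop("ODE integration failure: non-finite error estimate at t=%g", t);
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < NS; ++i) { y[i] = y5[i]; k1[i] = k7[i]; }
    } else {
      rhs(m, y, k1);  // refresh (k1 was overwritten only on acceptance)
    }
    double fac = 0.9 * std::pow(err > 1e-10 ? err : 1e-10, -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-12 * (t1 - t0))
      stop("ODE integration failure: step size underflow at t=%g", t);
    if (++(*nstep_io) > max_steps)
      stop("ODE integration failure: step budget exceeded at t=%g", t);
  }
  *h_io = h;
}

Model unpack(double Vp, double Ve, double Vh, double f_alb,
             const NumericMatrix& edges) {
  if (edges.nrow() != 6 || edges.ncol() != 5)
    stop("edge matrix must be 6 x 5 (present, law, k, vmax/km pair, vref)");
  Model m;
  m.Vp = Vp; m.Ve = Ve; m.Vh = Vh; m.f_alb = f_alb; m.rate = 0.0;
  for (int i = 0; i < 6; ++i) {
    m.e[i].present = edges(i, 0) != 0.0;
    m.e[i].law = (int)edges(i, 1);
    if (m.e[i].law == 0) {
      m.e[i].k = edges(i, 2); m.e[i].vmax = 0.0; m.e[i].km = 1.0;
    } else {
      m.e[i].k = 0.0; m.e[i].vmax = edges(i, 2); m.e[i].km = edges(i, 3);
    }
    m.e[i].vref = edges(i, 4);
  }
  return m;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".simulate_amounts")]]
NumericMatrix simulate_amounts(NumericVector times,
                               double Vp, double Ve, double Vh, double f_alb,
                               NumericMatrix edges,
                               double inj_start, double inj_end,
                               double inj_rate,
                               double rtol, double atol,
                               double max_steps) {
  const int nt = times.size();
  Model m = unpack(Vp, Ve, Vh, f_alb, edges);

  // breakpoints: injection edges split the integration so the step input is
  // never seen as a discontinuity by the error estimator
  std::vector<double> brk;
  if (inj_rate > 0.0) { brk.push_back(inj_start); brk.push_back(inj_end); }

  NumericMatrix out(nt, NS);
  double y[NS] = {0, 0, 0, 0, 0, 0};
  double t = 0.0, h = 0.0;
  long nstep = 0;
  const long msteps = (long)max_steps;
  for (int j = 0; j < nt; ++j) {
    double tj = times[j];
    if (tj < t) stop("output times must be sorted and non-negative");
    // advance across any breakpoints in (t, tj)
    for (size_t b = 0; b < brk.size(); ++b) {
      if (brk[b] > t && brk[b] < tj) {
        m.rate = (t >= inj_start && t < inj_end) ? inj_rate : 0.0;
        integrate_segment(m, y, t, brk[b], rtol, atol, &h, &nstep, msteps);
        t = brk[b];
        h = 0.0;  // restart step-size control at the discontinuity
      }
    }
    m.rate = (t >= inj_start && t < inj_end) ? inj_rate : 0.0;
    integrate_segment(m, y, t, tj, rtol, atol, &h, &nstep, msteps);
    t = tj;
    for (int i = 0; i < NS; ++i) {
      // clamp solver-level negative round-off to zero
      out(j, i) = (y[i] < 0.0 && y[i] > -1e-9) ? 0.0 : y[i];
    }
  }
  return out;
}
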