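// Fixed-step integrators for the single-compartment cell and the RLC
// reference circuit.  Gates use the exact exponential relaxation per step
// (exact for piecewise-constant V); the membrane voltage uses backward
// Euler, so the split scheme is unconditionally stable at dt = 0.01-0.05 ms.
//
// Units: mV, ms, nS, pF, pA for the cell; MOhm, pF, MH, nA, mV, ms for the
// RLC circuit (chosen so all time constants land in ms).

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Gate {
  double theta, k, tau0, tau1, phi, sigma0, sigma1, floorv;
  int expn;

  double xinf(double V) const {
    return floorv + (1.0 - floorv) / (1.0 + std::exp((theta - V) / k));
  }
  double tau(double V) const {
    const double e0 = std::exp((phi - V) / sigma0);
    const double e1 = std::exp((phi - V) / sigma1);
    return tau0 + (tau1 - tau0) / (e0 + e1);
  }
  // exact relaxation over dt at frozen V
  double relax(double x, double V, double dt) const {
    const double xi = xinf(V);
    return xi + (x - xi) * std::exp(-dt / tau(V));
  }
};

Gate parse_gate(const List& g) {
  Gate out;
  out.theta = as<double>(g["theta"]);
  out.k = as<double>(g["k"]);
  out.tau0 = as<double>(g["tau0"]);
  out.tau1 = as<double>(g["tau1"]);
  out.phi = as<double>(g["phi"]);
  out.sigma0 = as<double>(g["sigma0"]);
  out.sigma1 = as<double>(g["sigma1"]);
  out.floorv = as<double>(g["floor"]);
  out.expn = as<int>(g["exponent"]);
  return out;
}

struct Channel {
  double gmax;  // nS, total (density already scaled by area)
  Gate m;
  bool has_h;
  Gate h;

  double conductance(double mval, double hval) const {
    double mm = 1.0;
    for (int e = 0; e < m.expn; ++e) mm *= mval;
    return gmax * mm * (has_h ? hval : 1.0);
  }
};

std::vector<Channel> parse_channels(const List& channels) {
  std::vector<Channel> out;
  for (int i = 0; i < channels.size(); ++i) {
    List ch = channels[i];
    Channel c;
    c.gmax = as<double>(ch["gmax_nS"]);
    c.m = parse_gate(ch["m"]);
    c.has_h = ch.containsElementNamed("h") && !Rf_isNull(ch["h"]);
    if (c.has_h) c.h = parse_gate(ch["h"]);
    out.push_back(c);
  }
  return out;
}

}  // namespace

// Voltage clamp: command V is imposed exactly (ideal clamp); gates are
// relaxed against the command, and the reported current is the ionic
// channel current only (no capacitive component).
// [[Rcpp::export]]
List vc_integrate(NumericVector command, double dt, List channels, double EK) {
  const int n = command.size();
  std::vector<Channel> ch = parse_channels(channels);
  const int nc = static_cast<int>(ch.size());

  NumericVector current(n), gtot(n);
  NumericMatrix mtr(n, nc), htr(n, nc);
  std::vector<double> m(nc), h(nc);

  for (int c = 0; c < nc; ++c) {
    m[c] = ch[c].m.xinf(command[0]);
    h[c] = ch[c].has_h ? ch[c].h.xinf(command[0]) : 1.0;
  }
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      for (int c = 0; c < nc; ++c) {
        m[c] = ch[c].m.relax(m[c], command[i], dt);
        if (ch[c].has_h) h[c] = ch[c].h.relax(h[c], command[i], dt);
      }
    }
    double g = 0.0;
    for (int c = 0; c < nc; ++c) {
      g += ch[c].conductance(m[c], h[c]);
      mtr(i, c) = m[c];
      htr(i, c) = h[c];
    }
    gtot[i] = g;
    current[i] = g * (command[i] - EK);  // pA, outward positive
  }
  return List::create(_["current_pA"] = current, _["g_nS"] = gtot,
                      _["m"] = mtr, _["h"] = htr);
}

// Current clamp: cm_tot * dV/dt = -g_pas*(V - e_pas) - sum g_i*(V - EK) + I.
// Gates advance first (exponential relaxation at the previous voltage),
// then V by backward Euler with the updated conductances.
// [[Rcpp::export]]
List cc_integrate(NumericVector inject, double dt, double v0, double cm_pF,
                  double gpas_nS, double epas, List channels, double EK) {
  const int n = inject.size();
  std::vector<Channel> ch = parse_channels(channels);
  const int nc = static_cast<int>(ch.size());

  NumericVector V(n), gtot(n);
  NumericMatrix mtr(n, nc), htr(n, nc);
  std::vector<double> m(nc), h(nc);

  for (int c = 0; c < nc; ++c) {
    m[c] = ch[c].m.xinf(v0);
    h[c] = ch[c].has_h ? ch[c].h.xinf(v0) : 1.0;
  }
  double v = v0;
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      for (int c = 0; c < nc; ++c) {
        m[c] = ch[c].m.relax(m[c], v, dt);
        if (ch[c].has_h) h[c] = ch[c].h.relax(h[c], v, dt);
      }
      double g = 0.0;
      for (int c = 0; c < nc; ++c) g += ch[c].conductance(m[c], h[c]);
      const double a = dt / cm_pF;  // ms/pF: a*pA = mV
      v = (v + a * (gpas_nS * epas + g * EK + inject[i])) /
          (1.0 + a * (gpas_nS + g));
    }
    double g = 0.0;
    for (int c = 0; c < nc; ++c) {
      g += ch[c].conductance(m[c], h[c]);
      mtr(i, c) = m[c];
      htr(i, c) = h[c];
    }
    gtot[i] = g;
    V[i] = v;
  }
  return List::create(_["V_mV"] = V, _["g_nS"] = gtot,
                      _["m"] = mtr, _["h"] = htr);
}

// Parallel RLC circuit with leaky inductor (R_L in series with L) and
// electrode resistance Re in series with the whole node.
//   node:  C dVn/dt = I_in - Vn/R - I_L        (I_in from Re or drive)
//   coil:  L dI_L/dt = Vn - R_L * I_L
// Units: R, R_L, Re [MOhm], C [pF], L [MH], V [mV], I [nA], t [ms].
// mode: "voltage_ideal" (node clamped to drive), "voltage" (source clamped,
// seen through Re), "current" (drive current injected into the node).
// [[Rcpp::export]]
List rlc_integrate(NumericVector drive, double dt, std::string mode,
                   double R, double C, double L, double RL, double Re) {
  const int n = drive.size();
  NumericVector Vn(n), IL(n), IR(n), IC(n), Isrc(n), Vsrc(n);

  // dVn/dt [mV/ms] = 1000 * I_net[nA] / C[pF]
  // dIL/dt [nA/ms] = 1e-3 * (Vn - RL*IL) / L[MH]
  const double av = 1000.0 / C;
  const double ai = 1.0e-3 / L;

  double vn, il;
  if (mode == "voltage_ideal") {
    vn = drive[0];
    il = vn / RL;
  } else if (mode == "voltage") {
    vn = drive[0] / (1.0 + Re * (1.0 / R + 1.0 / RL));
    il = vn / RL;
  } else {  // current
    vn = drive[0] / (1.0 / R + 1.0 / RL);
    il = vn / RL;
  }

  const double tauL = L / (1.0e-3 * RL);  // ms
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      if (mode == "voltage_ideal") {
        vn = drive[i];
        const double target = vn / RL;
        il = target + (il - target) * std::exp(-dt / tauL);
      } else {
        // backward Euler on the linear 2x2 system
        double b1, a11;
        if (mode == "voltage") {
          a11 = 1.0 + dt * av * (1.0 / Re + 1.0 / R);
          b1 = vn + dt * av * drive[i] / Re;
        } else {
          a11 = 1.0 + dt * av * (1.0 / R);
          b1 = vn + dt * av * drive[i];
        }
        const double a12 = dt * av;
        const double a21 = -dt * ai;
        const double a22 = 1.0 + dt * ai * RL;
        const double det = a11 * a22 - a12 * a21;
        const double vn_new = (b1 * a22 - a12 * il) / det;
        const double il_new = (a11 * il - a21 * b1) / det;
        vn = vn_new;
        il = il_new;
      }
    }
    Vn[i] = vn;
    IL[i] = il;
    IR[i] = vn / R;
  }
  // capacitor current from the backward difference of the node voltage --
  // the same discretization the implicit update solves, so Kirchhoff's
  // current law holds to machine precision at every sample.
  for (int i = 0; i < n; ++i) {
    const double dv = (i == 0) ? 0.0 : (Vn[i] - Vn[i - 1]) / dt;
    IC[i] = C * dv * 1.0e-3;  // pF*mV/ms = pA -> nA
    Isrc[i] = IL[i] + IR[i] + IC[i];
    if (mode == "current") {
      Vsrc[i] = Vn[i] + drive[i] * Re;
    } else {
      Vsrc[i] = Vn[i] + Isrc[i] * Re;
    }
  }
  return List::create(_["Vn_mV"] = Vn, _["IL_nA"] = IL, _["IR_nA"] = IR,
                      _["IC_nA"] = IC, _["Isource_nA"] = Isrc,
                      _["Vsource_mV"] = Vsrc);
}
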