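// Semi-implicit multi-compartment cable integrator.
//
// State: membrane potential Vm per compartment (mV), gate variables and an
// optional calcium pool. Each step:
//   1. gates advance by the exponential-Euler closed form at the current Vm;
//   2. the membrane equation is solved implicitly with the ionic
//      conductances frozen at the new gate values (linear in V), together
//      with the axial coupling, via Hines elimination on the compartment
//      tree (parents ordered before children);
//   3. the calcium pool advances with the calcium current at the new Vm.
//
// Units: Vm mV, time ms, capacitance nF, axial conductance uS, membrane
// conductance densities mS/cm^2, areas cm^2, currents nA, calcium mM.
// Extracellular drive: Ve_i(t) = ve_unit_i (mV per uA) * wave_t (uA); the
// axial term uses Vi + Ve so only Ve differences drive the cable.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline double rate_eval_c(int form, double a, double v0, double b, double c,
                          double V) {
  switch (form) {
    case 1: {  // linoid with removable singularity
      double x = V - v0;
      if (std::fabs(x) < 1e-6) return a * b;
      return a * x / (1.0 - std::exp(-x / b));
    }
    case 2: return a * std::exp((V - v0) / b);
    case 3: return a / (1.0 + std::exp(-(V - v0) / b));
    case 4: return a;
    case 5: return c + a * std::exp(-((V - v0) / b) * ((V - v0) / b));
  }
  return NA_REAL;
}

struct Gate {
  int channel;     // owning channel index
  double exponent;
  int mode;        // 0 = alpha/beta, 1 = inf/tau
  int f1, f2;      // form codes
  double p1[4], p2[4];  // a, v0, b, c
  void inf_tau(double V, double& inf, double& tau) const {
    double r1 = rate_eval_c(f1, p1[0], p1[1], p1[2], p1[3], V);
    double r2 = rate_eval_c(f2, p2[0], p2[1], p2[2], p2[3], V);
    if (mode == 0) { inf = r1 / (r1 + r2); tau = 1.0 / (r1 + r2); }
    else { inf = r1; tau = r2; }
  }
};

struct Channel {
  double erev;      // mV; NaN => Nernst from calcium
  bool nernst;
  bool cadep;       // conductance scaled by a calcium factor
  double kd, hill;
  bool carries_ca;
  int gate_begin, gate_end;  // range into the gate array
};

} // namespace

// [[Rcpp::export(name = ".cable_step")]]
List cable_step(IntegerVector parent,       // 0-based, -1 for root
                NumericVector g_axial,      // uS to parent (0 for root)
                NumericVector cap_nF,
                NumericVector area_cm2,
                NumericMatrix dens,         // nchan x ncomp, mS/cm^2
                List chanspec,              // parsed registry (see R side)
                NumericVector v0,
                NumericMatrix gates0,       // ngate x ncomp
                NumericVector ca0,
                double dt, int nsteps,
                NumericVector ve_unit,      // mV per uA at each compartment
                NumericVector wave,         // uA, length nsteps + 1
                NumericVector iinj_nA,      // steady injected current per comp
                IntegerVector record,       // 0-based compartments to record
                List ca_params) {
  const int n = parent.size();
  const int nchan = dens.nrow();

  // ---- parse channel/gate spec ------------------------------------------
  NumericVector erev = chanspec["erev"];        // NaN => nernst
  IntegerVector cadep = chanspec["cadep"];
  NumericVector kd = chanspec["kd"];
  NumericVector hill = chanspec["hill"];
  IntegerVector carries = chanspec["carries_ca"];
  IntegerVector gchan = chanspec["gate_channel"];  // 0-based channel of gate
  NumericMatrix gp = chanspec["gate_params"];      // ngate x 11

  std::vector<Channel> chans(nchan);
  std::vector<Gate> gates(gchan.size());
  {
    std::vector<int> first(nchan, -1), last(nchan, -1);
    for (int g = 0; g < (int)gates.size(); ++g) {
      Gate& G = gates[g];
      G.channel = gchan[g];
      G.exponent = gp(g, 0);
      G.mode = (int)gp(g, 1);
      G.f1 = (int)gp(g, 2);
      for (int k = 0; k < 4; ++k) G.p1[k] = gp(g, 3 + k);
      G.f2 = (int)gp(g, 7);
      for (int k = 0; k < 4; ++k) G.p2[k] = gp(g, 8 + k);
      if (first[G.channel] < 0) first[G.channel] = g;
      last[G.channel] = g + 1;
    }
    for (int c = 0; c < nchan; ++c) {
      chans[c].nernst = NumericVector::is_na(erev[c]);
      chans[c].erev = chans[c].nernst ? 0.0 : erev[c];
      chans[c].cadep = cadep[c] != 0;
      chans[c].kd = kd[c];
      chans[c].hill = hill[c];
      chans[c].carries_ca = carries[c] != 0;
      chans[c].gate_begin = first[c] < 0 ? 0 : first[c];
      chans[c].gate_end = last[c] < 0 ? 0 : last[c];
    }
  }

  const double ca_k = as<double>(ca_params["k"]);
  const double ca_tau = as<double>(ca_params["tau"]);
  const double ca_rest = as<double>(ca_params["rest"]);
  const double ca_floor = as<double>(ca_params["floor"]);
  const double ca_cao = as<double>(ca_params["cao"]);
  const double ca_nf = as<double>(ca_params["nernst_factor"]);
  const double ca_efix = as<double>(ca_params["erev_fallback"]);
  bool have_ca = ca0.size() == n;

  // ---- state -------------------------------------------------------------
  std::vector<double> V(v0.begin(), v0.end());
  NumericMatrix gate_state = clone(gates0);
  std::vector<double> ca(n, ca_rest);
  if (have_ca) std::copy(ca0.begin(), ca0.end(), ca.begin());

  const int nrec = record.size();
  NumericMatrix trace(nrec, nsteps + 1);
  for (int r = 0; r < nrec; ++r) trace(r, 0) = V[record[r]];

  // children are ordered after parents; Hines arrays
  std::vector<double> diag(n), off(n), rhs(n), gsum(n), gesum(n), icad(n);

  for (int s = 0; s < nsteps; ++s) {
    double w_next = wave[s + 1];

    // gate update (exponential Euler at current V)
    for (size_t g = 0; g < gates.size(); ++g) {
      const Gate& G = gates[g];
      for (int i = 0; i < n; ++i) {
        if (dens(G.channel, i) == 0.0) continue;
        double inf, tau;
        G.inf_tau(V[i], inf, tau);
        gate_state(g, i) = inf + (gate_state(g, i) - inf) * std::exp(-dt / tau);
      }
    }

    // membrane conductances and driving terms
    for (int i = 0; i < n; ++i) { gsum[i] = 0.0; gesum[i] = 0.0; icad[i] = 0.0; }
    for (int c = 0; c < nchan; ++c) {
      const Channel& C = chans[c];
      for (int i = 0; i < n; ++i) {
        double d = dens(c, i);
        if (d == 0.0) continue;
        double open = 1.0;
        for (int g = C.gate_begin; g < C.gate_end; ++g) {
          double x = gate_state(g, i);
          double e = gates[g].exponent;
          open *= (e == 1.0) ? x : ((e == 2.0) ? x * x :
                   ((e == 3.0) ? x * x * x : ((e == 4.0) ? x * x * x * x
                                             : std::pow(x, e))));
        }
        if (C.cadep) {
          double u = std::pow(ca[i] / C.kd, C.hill);
          open *= u / (1.0 + u);
        }
        double E = C.erev;
        if (C.nernst)
          E = have_ca ? ca_nf * std::log(ca_cao / std::max(ca[i], ca_floor))
                      : ca_efix;
        double gabs = d * area_cm2[i] * 1e3 * open;  // uS
        gsum[i] += gabs;
        gesum[i] += gabs * E;
      }
    }

    // implicit solve: (C/dt + G + L) V_new = C/dt V + G*E + Iinj - L Ve
    for (int i = 0; i < n; ++i) {
      diag[i] = cap_nF[i] / dt + gsum[i];
      off[i] = -g_axial[i];
      rhs[i] = cap_nF[i] / dt * V[i] + gesum[i] + iinj_nA[i];
    }
    for (int i = 0; i < n; ++i) {
      int p = parent[i];
      if (p < 0) continue;
      double ga = g_axial[i];
      diag[i] += ga;
      diag[p] += ga;
      double dve = (ve_unit[i] - ve_unit[p]) * w_next;  // mV
      // -L Ve contribution: node i gets -ga*(ve_i - ve_p), parent opposite
      rhs[i] -= ga * dve;
      rhs[p] += ga * dve;
    }
    // Hines elimination (children have larger indices)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = off[i] / diag[i];
      diag[p] -= f * off[i];
      rhs[p] -= f * rhs[i];
    }
    V[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      V[i] = (rhs[i] - off[i] * V[parent[i]]) / diag[i];

    for (int i = 0; i < n; ++i)
      if (!std::isfinite(V[i]))
        stop("cable integration diverged at t = %g ms (compartment %d)",
             (s + 1) * dt, i + 1);

    // calcium pool
    if (have_ca) {
      for (int c = 0; c < nchan; ++c) {
        const Channel& C = chans[c];
        if (!C.carries_ca) continue;
        for (int i = 0; i < n; ++i) {
          double d = dens(c, i);
          if (d == 0.0) continue;
          double open = 1.0;
          for (int g = C.gate_begin; g < C.gate_end; ++g)
            open *= std::pow(gate_state(g, i), gates[g].exponent);
          double E = ca_nf * std::log(ca_cao / std::max(ca[i], ca_floor));
          icad[i] += d * open * (V[i] - E);  // uA/cm^2
        }
      }
      for (int i = 0; i < n; ++i) {
        ca[i] += dt * (-ca_k * icad[i] - (ca[i] - ca_rest) / ca_tau);
        if (ca[i] < ca_floor) ca[i] = ca_floor;
        icad[i] = 0.0;
      }
    }

    for (int r = 0; r < nrec; ++r) trace(r, s + 1) = V[record[r]];
  }

  return List::create(_["trace"] = trace,
                      _["v_final"] = NumericVector(V.begin(), V.end()),
                      _["gates_final"] = gate_state,
                      _["ca_final"] = have_ca
                        ? NumericVector(ca.begin(), ca.end())
                        : NumericVector(0));
}
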