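// Single-compartment conductance-based neuron model used by the synthetic
// recording generator. Explicit spike currents (Hodgkin-Huxley style sodium
// and delayed-rectifier) produce full action-potential waveforms so that
// threshold, peak, AHP and width are measurable on simulated traces; the
// optional subthreshold channels (fast/slow inactivating A-type potassium,
// low-threshold transient calcium, hyperpolarisation-activated cation, and a
// slow spike-activated adaptation conductance) shape the discharge
// phenotypes. Fixed-step classical 4th-order Runge-Kutta integration.
//
// Units: mV, ms, pF, nS, pA. dV/dt = (I_ext - sum I_ion)/C in mV/ms.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double ENa = 50.0, EK = -90.0, ECa = 120.0, Eh = -30.0;

struct Params {
  double C, gL, EL, gNa, gK, VT, gNaP;
  double gKAf, tau_af, tau_hf;
  double gKAs, tau_as, tau_hs;
  double gCaT, tau_mT, tau_hT;
  double gH, tau_r;
  double gW, tau_w_act, tau_w_rec, w_vhalf, w_k;
};

static Params unpack(const List& p) {
  Params q;
  q.C = p["C"]; q.gL = p["gL"]; q.EL = p["EL"];
  q.gNa = p["gNa"]; q.gK = p["gK"]; q.VT = p["VT"]; q.gNaP = p["gNaP"];
  q.gKAf = p["gKAf"]; q.tau_af = p["tau_af"]; q.tau_hf = p["tau_hf"];
  q.gKAs = p["gKAs"]; q.tau_as = p["tau_as"]; q.tau_hs = p["tau_hs"];
  q.gCaT = p["gCaT"]; q.tau_mT = p["tau_mT"]; q.tau_hT = p["tau_hT"];
  q.gH = p["gH"]; q.tau_r = p["tau_r"];
  q.gW = p["gW"]; q.tau_w_act = p["tau_w_act"]; q.tau_w_rec = p["tau_w_rec"];
  q.w_vhalf = p["w_vhalf"]; q.w_k = p["w_k"];
  return q;
}

static inline double sigm(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

// guarded x / (1 - exp(-x/k)) style rates (Hodgkin-Huxley, Traub shift VT)
static inline double vtrap(double x, double k) {
  if (std::fabs(x / k) < 1e-6) return k * (1.0 - x / (2.0 * k));
  return x / (std::exp(x / k) - 1.0);
}

static inline double am(double v, double VT) { return 0.32 * vtrap(-(v - VT - 13.0), 4.0); }
static inline double bm(double v, double VT) { return 0.28 * vtrap(v - VT - 40.0, 5.0); }
static inline double ah(double v, double VT) { return 0.128 * std::exp(-(v - VT - 17.0) / 18.0); }
static inline double bh(double v, double VT) { return 4.0 / (1.0 + std::exp(-(v - VT - 40.0) / 5.0)); }
static inline double an(double v, double VT) { return 0.032 * vtrap(-(v - VT - 15.0), 5.0); }
static inline double bn(double v, double VT) { return 0.5 * std::exp(-(v - VT - 10.0) / 40.0); }

// steady-state activation / inactivation of the subthreshold channels
static inline double af_inf(double v) { return sigm(v, -55.0, 8.0); }
static inline double hf_inf(double v) { return sigm(v, -65.0, -6.0); }
static inline double as_inf(double v) { return sigm(v, -50.0, 8.0); }
static inline double hs_inf(double v) { return sigm(v, -65.0, -6.0); }
static inline double mT_inf(double v) { return sigm(v, -52.0, 5.0); }
static inline double hT_inf(double v) { return sigm(v, -72.0, -4.0); }
static inline double r_inf(double v)  { return sigm(v, -85.0, -6.0); }

enum { iV, im, ih, in_, iaf, ihf, ias, ihs, imT, ihT, ir, iw, NSTATE };

static inline double ionic_current(const Params& p, const double* s) {
  double v = s[iV];
  double I = p.gL * (v - p.EL);
  I += p.gNa * s[im] * s[im] * s[im] * s[ih] * (v - ENa);
  I += p.gNaP * sigm(v, -52.0, 3.0) * (v - ENa);   // persistent Na, instantaneous
  I += p.gK * s[in_] * s[in_] * s[in_] * s[in_] * (v - EK);
  I += p.gKAf * s[iaf] * s[ihf] * (v - EK);
  I += p.gKAs * s[ias] * s[ihs] * (v - EK);
  I += p.gCaT * s[imT] * s[imT] * s[ihT] * (v - ECa);
  I += p.gH * s[ir] * (v - Eh);
  I += p.gW * s[iw] * (v - EK);
  return I;
}

static inline void deriv(const Params& p, const double* s, double* ds,
                         double Iext) {
  double v = s[iV];
  ds[iV] = (Iext - ionic_current(p, s)) / p.C;
  ds[im] = am(v, p.VT) * (1.0 - s[im]) - bm(v, p.VT) * s[im];
  ds[ih] = ah(v, p.VT) * (1.0 - s[ih]) - bh(v, p.VT) * s[ih];
  ds[in_] = an(v, p.VT) * (1.0 - s[in_]) - bn(v, p.VT) * s[in_];
  ds[iaf] = (af_inf(v) - s[iaf]) / p.tau_af;
  ds[ihf] = (hf_inf(v) - s[ihf]) / p.tau_hf;
  ds[ias] = (as_inf(v) - s[ias]) / p.tau_as;
  ds[ihs] = (hs_inf(v) - s[ihs]) / p.tau_hs;
  ds[imT] = (mT_inf(v) - s[imT]) / p.tau_mT;
  ds[ihT] = (hT_inf(v) - s[ihT]) / p.tau_hT;
  ds[ir] = (r_inf(v) - s[ir]) / p.tau_r;
  double tw = (v > p.w_vhalf) ? p.tau_w_act : p.tau_w_rec;
  ds[iw] = (sigm(v, p.w_vhalf, p.w_k) - s[iw]) / tw;
}

static void init_state(const Params& p, double v0, double* s) {
  s[iV] = v0;
  s[im] = am(v0, p.VT) / (am(v0, p.VT) + bm(v0, p.VT));
  s[ih] = ah(v0, p.VT) / (ah(v0, p.VT) + bh(v0, p.VT));
  s[in_] = an(v0, p.VT) / (an(v0, p.VT) + bn(v0, p.VT));
  s[iaf] = af_inf(v0); s[ihf] = hf_inf(v0);
  s[ias] = as_inf(v0); s[ihs] = hs_inf(v0);
  s[imT] = mT_inf(v0); s[ihT] = hT_inf(v0);
  s[ir] = r_inf(v0);
  s[iw] = sigm(v0, p.w_vhalf, p.w_k);
}

// Total ionic current with gates at steady state: the bias needed to hold v0.
// [[Rcpp::export(name = ".steady_current_cpp")]]
double steady_current_cpp(List params, double v0) {
  Params p = unpack(params);
  double s[NSTATE];
  init_state(p, v0, s);
  return ionic_current(p, s);
}

// Steady-state values and time constants of the subthreshold gates at a
// command potential (used by the analytic voltage-clamp generator).
// [[Rcpp::export(name = ".gates_at_cpp")]]
NumericVector gates_at_cpp(List params, double v) {
  Params p = unpack(params);
  NumericVector out = NumericVector::create(
    _["af_inf"] = af_inf(v), _["tau_af"] = p.tau_af,
    _["hf_inf"] = hf_inf(v), _["tau_hf"] = p.tau_hf,
    _["as_inf"] = as_inf(v), _["tau_as"] = p.tau_as,
    _["hs_inf"] = hs_inf(v), _["tau_hs"] = p.tau_hs,
    _["mT_inf"] = mT_inf(v), _["tau_mT"] = p.tau_mT,
    _["hT_inf"] = hT_inf(v), _["tau_hT"] = p.tau_hT,
    _["r_inf"] = r_inf(v),   _["tau_r"] = p.tau_r);
  return out;
}

// Integrate the model under an injected-current waveform sampled at the
// internal time step. Returns the voltage downsampled by keep_every and the
// model's own spike times (upward crossings of -20 mV).
// [[Rcpp::export(name = ".sim_cc_cpp")]]
List sim_cc_cpp(List params, NumericVector i_ext, double dt, int keep_every,
                double v0) {
  Params p = unpack(params);
  int n = i_ext.size();
  int n_out = (n - 1) / keep_every + 1;
  NumericVector vout(n_out);
  std::vector<double> spikes;
  double s[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE],
      tmp[NSTATE];
  init_state(p, v0, s);
  vout[0] = s[iV];
  bool above = s[iV] > -20.0;
  int iout = 1;
  for (int t = 1; t < n; ++t) {
    double I = i_ext[t - 1];
    deriv(p, s, k1, I);
    for (int j = 0; j < NSTATE; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    deriv(p, tmp, k2, I);
    for (int j = 0; j < NSTATE; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    deriv(p, tmp, k3, I);
    for (int j = 0; j < NSTATE; ++j) tmp[j] = s[j] + dt * k3[j];
    deriv(p, tmp, k4, I);
    for (int j = 0; j < NSTATE; ++j)
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (!R_finite(s[iV]) || std::fabs(s[iV]) > 500.0) {
      stop("integration blew up at t = %f ms (V = %f); "
           "check the phenotype spec", t * dt, s[iV]);
    }
    // clamp gates to [0, 1] against roundoff
    for (int j = 1; j < NSTATE; ++j) {
      if (s[j] < 0.0) s[j] = 0.0;
      else if (s[j] > 1.0) s[j] = 1.0;
    }
    if (!above && s[iV] > -20.0) {
      spikes.push_back(t * dt);
      above = true;
    } else if (above && s[iV] < -25.0) {
      above = false;
    }
    if (t % keep_every == 0) vout[iout++] = s[iV];
  }
  return List::create(_["V"] = vout, _["spike_times_ms"] = wrap(spikes));
}
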