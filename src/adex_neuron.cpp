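// Monte-Carlo single-neuron oracles used to fit and validate the mean-field
// transfer function: an AdEx neuron (spiking) and a passive conductance
// membrane (no spike mechanism) under Poisson synaptic bombardment.
// Units: ms, mV, nS, pF, pA; rates at the interface in Hz.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List adex_neuron_mc(double duration_ms, double dt, double nu_e_hz, double nu_i_hz,
                    double K_e, double K_i, List pars, bool passive,
                    double transient_ms) {
  double C_m = pars["C_m"], g_L = pars["g_L"], E_L = pars["E_L"];
  double E_e = pars["E_e"], E_i = pars["E_i"];
  double Q_e = pars["Q_e"], Q_i = pars["Q_i"];
  double tau_e = pars["tau_e"], tau_i = pars["tau_i"];
  double V_T = pars["V_T"], Delta_T = pars["Delta_T"];
  double V_reset = pars["V_reset"], t_ref = pars["t_ref"];
  double a = pars["a"], b = pars["b"], tau_w = pars["tau_w"];
  double V_spike = pars["V_spike"];

  int n_steps = (int)std::ceil(duration_ms / dt);
  double rate_e = K_e * nu_e_hz * 1e-3 * dt;  // mean presyn events per step
  double rate_i = K_i * nu_i_hz * 1e-3 * dt;

  double V = E_L, ge = 0.0, gi = 0.0, w = 0.0;
  double ref_left = 0.0;
  long n_spikes = 0;
  double sumV = 0.0, sumV2 = 0.0;
  long n_acc = 0;

  RNGScope scope;
  for (int k = 0; k < n_steps; k++) {
    double t = k * dt;
    ge += Q_e * R::rpois(rate_e);
    gi += Q_i * R::rpois(rate_i);
    ge -= ge * dt / tau_e;
    gi -= gi * dt / tau_i;

    if (ref_left > 0.0) {
      ref_left -= dt;
      V = V_reset;
    } else {
      double I_exp = passive ? 0.0 : g_L * Delta_T * std::exp((V - V_T) / Delta_T);
      double dV = (-g_L * (V - E_L) + I_exp - ge * (V - E_e) - gi * (V - E_i) - w) / C_m;
      V += dt * dV;
      if (!passive) {
        double dw = (a * (V - E_L) - w) / tau_w;
        w += dt * dw;
        if (V >= V_spike) {
          if (t >= transient_ms) n_spikes++;
          V = V_reset;
          w += b;
          ref_left = t_ref;
        }
      }
    }
    if (t >= transient_ms) {
      sumV += V;
      sumV2 += V * V;
      n_acc++;
    }
  }
  double effective_s = (duration_ms - transient_ms) * 1e-3;
  double muV = sumV / n_acc;
  double varV = sumV2 / n_acc - muV * muV;
  return List::create(_["rate_hz"] = n_spikes / effective_s,
                      _["mu_V"] = muV,
                      _["sigma_V"] = varV > 0 ? std::sqrt(varV) : 0.0,
                      _["duration_s"] = effective_s);
}
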