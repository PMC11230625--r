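// Stochastic Heun integrator for a network of AdEx mean-field nodes coupled
// by a directed weight matrix. Each node carries (nu_e, nu_i, W); the
// semi-analytic transfer function maps synaptic input statistics to output
// rate through an effective threshold polynomial.
// Internal units: ms, mV, nS, pF, pA, kHz. Interfaces use Hz / seconds.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct MFParams {
  double g_L, C_m, E_L_e, E_L_i, E_e, E_i, Q_e, Q_i, tau_e, tau_i;
  double K_e, K_i, T, tau_w, b, a, nu_ext_khz, cap_khz, sigma_eps;
  double ceil_e_khz, ceil_i_khz;   // refractory ceilings per population
};

struct TFCoeffs {
  arma::vec P_e, P_i;     // 11 each
  double muV0, dmuV0, sV0, dsV0, tVN0, dtVN0;
};

// conductance-based membrane statistics for one population.
// nu_e, nu_i in kHz; W in pA; E_L of the receiving population.
static inline void cond_stats(double nu_e, double nu_i, double W, double E_L,
                              const MFParams &p, double &muV, double &sV,
                              double &tV, double &muG) {
  double muGe = p.K_e * nu_e * p.tau_e * p.Q_e;
  double muGi = p.K_i * nu_i * p.tau_i * p.Q_i;
  muG = p.g_L + muGe + muGi;
  double tau_m = p.C_m / muG;
  muV = (muGe * p.E_e + muGi * p.E_i + p.g_L * E_L - W) / muG;
  double Ue = (p.Q_e / muG) * (p.E_e - muV);
  double Ui = (p.Q_i / muG) * (p.E_i - muV);
  double se = p.K_e * nu_e * (Ue * p.tau_e) * (Ue * p.tau_e);
  double si = p.K_i * nu_i * (Ui * p.tau_i) * (Ui * p.tau_i);
  double de = se / (tau_m + p.tau_e);
  double di = si / (tau_m + p.tau_i);
  double var = 0.5 * (de + di);
  sV = var > 0 ? std::sqrt(var) : 0.0;
  tV = (de + di) > 0 ? (se + si) / (de + di) : tau_m;
}

// effective-threshold polynomial: full second order in the normalized
// (muV, sigmaV, tauV*muG/C_m) plus one trilinear cross term -> 11 terms.
static inline double v_thr_eff(double muV, double sV, double tVN,
                               const arma::vec &P, const TFCoeffs &c) {
  double x1 = (muV - c.muV0) / c.dmuV0;
  double x2 = (sV - c.sV0) / c.dsV0;
  double x3 = (tVN - c.tVN0) / c.dtVN0;
  return P(0) + P(1) * x1 + P(2) * x2 + P(3) * x3 +
         P(4) * x1 * x1 + P(5) * x2 * x2 + P(6) * x3 * x3 +
         P(7) * x1 * x2 + P(8) * x1 * x3 + P(9) * x2 * x3 +
         P(10) * x1 * x2 * x3;
}

// output rate (kHz) of one population given its synaptic input statistics;
// bounded by the refractory ceiling of the population
static inline double tf_rate(double nu_e, double nu_i, double W, double E_L,
                             const arma::vec &P, const MFParams &p,
                             const TFCoeffs &c, double ceil_khz,
                             double &muV_out) {
  double muV, sV, tV, muG;
  cond_stats(nu_e, nu_i, W, E_L, p, muV, sV, tV, muG);
  muV_out = muV;
  double tVN = tV * muG / p.C_m;
  double Vthr = v_thr_eff(muV, sV, tVN, P, c);
  double r;
  if (sV < p.sigma_eps) r = (muV < Vthr) ? 0.0 : 1.0 / tV;
  else {
    double z = (Vthr - muV) / (std::sqrt(2.0) * sV);
    r = 0.5 * std::erfc(z) / tV;
  }
  return r < ceil_khz ? r : ceil_khz;
}

static MFParams unpack_params(const List &pars) {
  MFParams p;
  p.g_L = pars["g_L"]; p.C_m = pars["C_m"];
  p.E_L_e = pars["E_L_e"]; p.E_L_i = pars["E_L_i"];
  p.E_e = pars["E_e"]; p.E_i = pars["E_i"];
  p.Q_e = pars["Q_e"]; p.Q_i = pars["Q_i"];
  p.tau_e = pars["tau_e"]; p.tau_i = pars["tau_i"];
  double N_tot = pars["N_tot"], p_conn = pars["p_conn"], frac = pars["frac_exc"];
  p.K_e = p_conn * frac * N_tot;
  p.K_i = p_conn * (1.0 - frac) * N_tot;
  p.T = pars["T"]; p.tau_w = pars["tau_w"];
  p.b = pars["b"]; p.a = pars["a"];
  p.nu_ext_khz = as<double>(pars["nu_ext"]) * 1e-3;
  p.cap_khz = as<double>(pars["rate_cap"]) * 1e-3;
  p.ceil_e_khz = as<double>(pars["ceiling_e"]) * 1e-3;
  p.ceil_i_khz = as<double>(pars["ceiling_i"]) * 1e-3;
  p.sigma_eps = pars["sigma_eps"];
  return p;
}

// per-region RNG streams (splitmix64-seeded xorshift64*, Box-Muller),
// so region trajectories are invariant to the presence of other regions
struct RegionRng {
  uint64_t s;
  bool has_spare = false;
  double spare = 0.0;
  void seed(uint64_t seed, uint64_t region) {
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL * (region + 1);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x106689d45497fdb5ULL;
    has_spare = false;
  }
  double unif() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    uint64_t x = s * 0x2545F4914F6CDD1DULL;
    return (x >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 1e-300);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

static TFCoeffs unpack_coeffs(const List &co) {
  TFCoeffs c;
  c.P_e = as<arma::vec>(co["P_e"]);
  c.P_i = as<arma::vec>(co["P_i"]);
  NumericVector nm = co["norm"];
  c.muV0 = nm[0]; c.dmuV0 = nm[1]; c.sV0 = nm[2];
  c.dsV0 = nm[3]; c.tVN0 = nm[4]; c.dtVN0 = nm[5];
  return c;
}

// [[Rcpp::export]]
List mf_network_cpp(const arma::mat &Wc,          // n x n effective coupling (S * row-normalized)
                    const arma::imat &delay_steps, // n x n integer delays (0 = none)
                    const arma::vec &stim_wave,    // nt-long added drive (Hz) on targets
                    const arma::vec &stim_target,  // n-long 0/1 indicator
                    double dt, int n_steps, int record_every,
                    double noise_std_hz, List pars, List coeffs,
                    double nu_e0_hz, double nu_i0_hz, double W0,
                    double seed, double stream_offset) {
  MFParams p = unpack_params(pars);
  TFCoeffs c = unpack_coeffs(coeffs);
  int n = Wc.n_rows;
  std::vector<RegionRng> rng(n);
  for (int r = 0; r < n; r++)
    rng[r].seed((uint64_t)seed, (uint64_t)(stream_offset + r));
  bool has_delays = arma::any(arma::vectorise(delay_steps) > 0);
  int max_del = has_delays ? (int)delay_steps.max() : 0;

  arma::vec nu_e(n), nu_i(n), W(n), muV(n);
  nu_e.fill(nu_e0_hz * 1e-3);
  nu_i.fill(nu_i0_hz * 1e-3);
  W.fill(W0);
  muV.fill(p.E_L_e);

  // ring buffer of nu_e history for delayed coupling
  arma::mat hist;
  int hlen = max_del + 1;
  if (has_delays) { hist.set_size(n, hlen); hist.each_col() = nu_e; }

  int n_rec = n_steps / record_every;
  arma::mat rec_e(n, n_rec), rec_i(n, n_rec), rec_W(n, n_rec), rec_V(n, n_rec);
  arma::vec rec_t(n_rec);

  double noise_inc = noise_std_hz * 1e-3 * std::sqrt(dt / p.T);
  arma::vec k1e(n), k1i(n), k1w(n), k2e(n), k2i(n), k2w(n);
  arma::vec coup(n), coup2(n), mu_tmp(n);

  int rec_idx = 0;
  for (int k = 0; k < n_steps; k++) {
    double stim_now = stim_wave(k);
    double stim_next = (k + 1 < n_steps) ? stim_wave(k + 1) : stim_wave(k);

    // coupling from (possibly delayed) excitatory rates
    if (!has_delays) {
      coup = Wc * nu_e;
    } else {
      int pos = k % hlen;
      hist.col(pos) = nu_e;
      for (int r = 0; r < n; r++) {
        double s = 0.0;
        for (int j = 0; j < n; j++) {
          int d = delay_steps(r, j);
          int idx = (pos - d % hlen + hlen) % hlen;
          s += Wc(r, j) * hist(j, idx);
        }
        coup(r) = s;
      }
    }

    // stage 1
    for (int r = 0; r < n; r++) {
      double drive = nu_e(r) + coup(r) + p.nu_ext_khz +
                     stim_target(r) * stim_now * 1e-3;
      double mv;
      double Fe = tf_rate(drive, nu_i(r), W(r), p.E_L_e, c.P_e, p, c, p.ceil_e_khz, mv);
      double mvi;
      double Fi = tf_rate(drive, nu_i(r), 0.0, p.E_L_i, c.P_i, p, c, p.ceil_i_khz, mvi);
      k1e(r) = (Fe - nu_e(r)) / p.T;
      k1i(r) = (Fi - nu_i(r)) / p.T;
      k1w(r) = -W(r) / p.tau_w + p.b * nu_e(r) + p.a * (mv - p.E_L_e) / p.tau_w;
      mu_tmp(r) = mv;
    }
    arma::vec e1 = arma::clamp(nu_e + dt * k1e, 0.0, p.cap_khz);
    arma::vec i1 = arma::clamp(nu_i + dt * k1i, 0.0, p.cap_khz);
    arma::vec w1 = W + dt * k1w;

    // stage 2 (delayed coupling approximated with stage-1 history; exact when no delays)
    if (!has_delays) coup2 = Wc * e1; else coup2 = coup;
    for (int r = 0; r < n; r++) {
      double drive = e1(r) + coup2(r) + p.nu_ext_khz +
                     stim_target(r) * stim_next * 1e-3;
      double mv;
      double Fe = tf_rate(drive, i1(r), w1(r), p.E_L_e, c.P_e, p, c, p.ceil_e_khz, mv);
      double mvi;
      double Fi = tf_rate(drive, i1(r), 0.0, p.E_L_i, c.P_i, p, c, p.ceil_i_khz, mvi);
      k2e(r) = (Fe - e1(r)) / p.T;
      k2i(r) = (Fi - i1(r)) / p.T;
      k2w(r) = -w1(r) / p.tau_w + p.b * e1(r) + p.a * (mv - p.E_L_e) / p.tau_w;
    }

    for (int r = 0; r < n; r++) {
      double xi = noise_std_hz > 0 ? rng[r].norm() : 0.0;
      nu_e(r) += 0.5 * dt * (k1e(r) + k2e(r)) + noise_inc * xi;
      nu_i(r) += 0.5 * dt * (k1i(r) + k2i(r));
      W(r) += 0.5 * dt * (k1w(r) + k2w(r));
    }
    nu_e = arma::clamp(nu_e, 0.0, p.cap_khz);
    nu_i = arma::clamp(nu_i, 0.0, p.cap_khz);
    muV = mu_tmp;

    if (!nu_e.is_finite() || !W.is_finite()) {
      arma::uvec bad = arma::find_nonfinite(nu_e);
      int reg = bad.n_elem > 0 ? (int)bad(0) : 0;
      stop("numerical blow-up at step %d (t = %.1f ms), region %d",
           k, k * dt, reg + 1);
    }

    if ((k + 1) % record_every == 0 && rec_idx < n_rec) {
      rec_e.col(rec_idx) = nu_e * 1e3;
      rec_i.col(rec_idx) = nu_i * 1e3;
      rec_W.col(rec_idx) = W;
      rec_V.col(rec_idx) = muV;
      rec_t(rec_idx) = (k + 1) * dt * 1e-3; // seconds
      rec_idx++;
    }
  }
  return List::create(_["time"] = rec_t, _["nu_e"] = rec_e, _["nu_i"] = rec_i,
                      _["W"] = rec_W, _["mu_V"] = rec_V);
}

// Single evaluation of the transfer chain, exported for cross-checking the
// R reference implementation against the integrator's internal one.
// [[Rcpp::export]]
NumericVector mf_transfer_cpp(double nu_e_hz, double nu_i_hz, double W,
                              std::string pop, List pars, List coeffs) {
  MFParams p = unpack_params(pars);
  TFCoeffs c = unpack_coeffs(coeffs);
  double E_L = (pop == "e") ? p.E_L_e : p.E_L_i;
  const arma::vec &P = (pop == "e") ? c.P_e : c.P_i;
  double mv;
  double ceil = (pop == "e") ? p.ceil_e_khz : p.ceil_i_khz;
  double r = tf_rate(nu_e_hz * 1e-3, nu_i_hz * 1e-3, W, E_L, P, p, c, ceil, mv);
  return NumericVector::create(_["rate_hz"] = r * 1e3, _["mu_V"] = mv);
}
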