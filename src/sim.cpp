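// Simulation kernels: single conductance-based neurons under Poissonian
// synaptic bombardment, and sparse E/I networks of the same models.
//
// Units throughout: mV, ms, nS, pF, pA (nS * mV = pA; pA / pF = mV/ms).
// Rates cross the R/C++ boundary in Hz and are converted to 1/ms here.
//
// All randomness uses R's RNG (RNGScope), so set.seed() on the R side makes
// every kernel bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// x / (1 - exp(-x/s)) with its removable singularity at x = 0 (limit s).
static inline double ratio_exp(double x, double s) {
  double r = x / s;
  if (std::fabs(r) < 1e-7) return s * (1.0 + 0.5 * r);
  return x / (-std::expm1(-r));
}

struct HHRates {
  double an, bn, am, bm, ah, bh, pinf, taup;
};

static inline HHRates hh_rates(double v, double VT, double taumax) {
  HHRates r;
  r.an = 0.032 * ratio_exp(v - VT - 15.0, 5.0);
  r.bn = 0.5 * std::exp(-(v - VT - 10.0) / 40.0);
  r.am = 0.32 * ratio_exp(v - VT - 13.0, 4.0);
  r.bm = 0.28 * ratio_exp(-(v - VT - 40.0), 5.0);
  r.ah = 0.128 * std::exp(-(v - VT - 17.0) / 18.0);
  r.bh = 4.0 / (1.0 + std::exp(-(v - VT - 40.0) / 5.0));
  r.pinf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  r.taup = taumax / (3.3 * std::exp((v + 35.0) / 20.0) +
                     std::exp(-(v + 35.0) / 20.0));
  return r;
}

// Gating rates for a vector of voltages; one row per voltage, columns
// (alpha_n, beta_n, alpha_m, beta_m, alpha_h, beta_h, p_inf, tau_p).
// [[Rcpp::export]]
NumericMatrix hh_rates_cpp(NumericVector v, double VT, double taumax) {
  int n = v.size();
  NumericMatrix out(n, 8);
  for (int i = 0; i < n; ++i) {
    HHRates r = hh_rates(v[i], VT, taumax);
    out(i, 0) = r.an; out(i, 1) = r.bn; out(i, 2) = r.am; out(i, 3) = r.bm;
    out(i, 4) = r.ah; out(i, 5) = r.bh; out(i, 6) = r.pinf; out(i, 7) = r.taup;
  }
  return out;
}

static inline double ml_Mss(double v, double V1, double V2) {
  return 0.5 * (1.0 + std::tanh((v - V1) / V2));
}
static inline double ml_Nss(double v, double V3, double V4) {
  return 0.5 * (1.0 + std::tanh((v - V3) / V4));
}
static inline double ml_tauN(double v, double V3, double V4, double phi) {
  return 1.0 / (2.0 * phi * std::cosh((v - V3) / (2.0 * V4)));
}

// Parameter vector layouts (kept in lock-step with the R constructors):
// adex: cm gL EL Delta vt vrest Trefr a b tauw vcut
// hh:   cm gL gNa gK gM EL ENa EK VT taumax spike_thr
// ml:   cm gL gCa gK EL ECa EK V1 V2 V3 V4 phi I0 spike_thr
enum ModelId { ADEX = 1, HH = 2, ML = 3 };

// One neuron, two independent aggregate Poisson input streams
// (K_e synapses at nu_e Hz, K_i at nu_i Hz), exponential-decay conductances.
// Event counts per bin are Binomial(K, nu * dt), the exact aggregate law.
// [[Rcpp::export]]
List sim_neuron_cpp(int model, NumericVector p, NumericVector syn,
                    double nu_e, double nu_i, int Ke, int Ki,
                    double duration, double dt,
                    double record_dt = 0.0, bool record_g = false) {
  const double Qe = syn[0], Qi = syn[1], tau = syn[2], Ee = syn[3], Ei = syn[4];
  const double decay = std::exp(-dt / tau);
  const double pe = nu_e * dt / 1000.0, pi_ = nu_i * dt / 1000.0;
  const int nsteps = (int)std::lround(duration / dt);
  const int rec_every = record_dt > 0 ? std::max(1, (int)std::lround(record_dt / dt)) : 0;

  double ge = 0.0, gi = 0.0;
  std::vector<double> spikes;
  std::vector<double> tr_t, tr_v, tr_ge, tr_gi;
  if (rec_every > 0) {
    int nrec = nsteps / rec_every + 1;
    tr_t.reserve(nrec); tr_v.reserve(nrec);
    if (record_g) { tr_ge.reserve(nrec); tr_gi.reserve(nrec); }
  }

  // state
  double v = 0, w = 0, n = 0, m = 0, h = 0, pg = 0, Nk = 0, refr = 0;
  bool above = false;
  double cm, gL, EL;
  if (model == ADEX) {
    cm = p[0]; gL = p[1]; EL = p[2];
    v = EL; w = 0.0;
  } else if (model == HH) {
    cm = p[0]; gL = p[1]; EL = p[5];
    v = EL;
    HHRates r = hh_rates(v, p[8], p[9]);
    n = r.an / (r.an + r.bn); m = r.am / (r.am + r.bm);
    h = r.ah / (r.ah + r.bh); pg = r.pinf;
  } else {
    cm = p[0]; gL = p[1]; EL = p[4];
    v = EL; Nk = ml_Nss(v, p[9], p[10]);
  }

  for (int k = 0; k < nsteps; ++k) {
    ge *= decay; gi *= decay;
    if (Ke > 0 && pe > 0) ge += Qe * R::rbinom((double)Ke, std::min(pe, 1.0));
    if (Ki > 0 && pi_ > 0) gi += Qi * R::rbinom((double)Ki, std::min(pi_, 1.0));
    const double t = k * dt;
    const double Isyn = ge * (Ee - v) + gi * (Ei - v);

    if (model == ADEX) {
      const double Delta = p[3], vt = p[4], vrest = p[5], Trefr = p[6];
      const double a = p[7], b = p[8], tauw = p[9], vcut = p[10];
      if (refr > 0) {
        refr -= dt;
        v = vrest;
        w += dt * (a * (v - EL) - w) / tauw;
      } else {
        const double dv = (gL * (EL - v) + gL * Delta * std::exp((v - vt) / Delta)
                           - w + Isyn) / cm;
        const double dw = (a * (v - EL) - w) / tauw;
        v += dt * dv; w += dt * dw;
        if (v > vcut) { v = vrest; w += b; refr = Trefr; spikes.push_back(t + dt); }
      }
    } else if (model == HH) {
      const double gNa = p[2], gK = p[3], gM = p[4];
      const double ENa = p[6], EK = p[7], VT = p[8], taumax = p[9], thr = p[10];
      HHRates r = hh_rates(v, VT, taumax);
      const double dv = (gL * (EL - v) + gNa * m * m * m * h * (ENa - v)
                         + gK * n * n * n * n * (EK - v)
                         + gM * pg * (EK - v) + Isyn) / cm;
      n += dt * (r.an * (1.0 - n) - r.bn * n);
      m += dt * (r.am * (1.0 - m) - r.bm * m);
      h += dt * (r.ah * (1.0 - h) - r.bh * h);
      pg += dt * (r.pinf - pg) / r.taup;
      v += dt * dv;
      if (!above && v >= thr) { spikes.push_back(t + dt); above = true; }
      else if (above && v < thr) above = false;
    } else {
      const double gCa = p[2], gK = p[3], ECa = p[5], EK = p[6];
      const double V1 = p[7], V2 = p[8], V3 = p[9], V4 = p[10];
      const double phi = p[11], I0 = p[12], thr = p[13];
      const double dv = (gL * (EL - v) + gCa * ml_Mss(v, V1, V2) * (ECa - v)
                         + gK * Nk * (EK - v) + Isyn + I0) / cm;
      Nk += dt * (ml_Nss(v, V3, V4) - Nk) / ml_tauN(v, V3, V4, phi);
      v += dt * dv;
      if (!above && v >= thr) { spikes.push_back(t + dt); above = true; }
      else if (above && v < thr) above = false;
    }

    if (!std::isfinite(v))
      stop("non-finite membrane potential (v) at t = %.3f ms", t);

    if (rec_every > 0 && (k % rec_every) == 0) {
      tr_t.push_back(t + dt); tr_v.push_back(v);
      if (record_g) { tr_ge.push_back(ge); tr_gi.push_back(gi); }
    }
  }

  List out = List::create(
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["n_steps"] = nsteps);
  if (rec_every > 0) {
    out["trace_t"] = NumericVector(tr_t.begin(), tr_t.end());
    out["trace_v"] = NumericVector(tr_v.begin(), tr_v.end());
    if (record_g) {
      out["trace_ge"] = NumericVector(tr_ge.begin(), tr_ge.end());
      out["trace_gi"] = NumericVector(tr_gi.begin(), tr_gi.end());
    }
  }
  return out;
}

// Erdos-Renyi directed adjacency in CSR-by-source form; ptr is 0-based,
// targets are 0-based neuron indices; no self-connections.
// [[Rcpp::export]]
List build_connectivity_cpp(int N, double p) {
  std::vector<int> ptr(N + 1, 0);
  std::vector<int> targets;
  targets.reserve((size_t)(p * (double)N * (double)N * 1.05) + 64);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      if (unif_rand() < p) targets.push_back(j);
    }
    ptr[i + 1] = (int)targets.size();
  }
  return List::create(_["ptr"] = IntegerVector(ptr.begin(), ptr.end()),
                      _["targets"] = IntegerVector(targets.begin(), targets.end()));
}

// Sparse E/I network simulation. Recurrent spikes at step k increment target
// conductances at the end of step k (visible from step k+1, delayless on the
// grid). Each neuron also receives an independent external excitatory stream
// of Ke_ext synapses at nu_drive (+ per-step stimulus rate) Hz through Q_e.
// [[Rcpp::export]]
List sim_network_cpp(int model, NumericMatrix pars, IntegerVector pop,
                     NumericVector syn, IntegerVector ptr, IntegerVector targets,
                     int Ke_ext, double nu_drive, NumericVector stim,
                     double duration, double dt, double v_init_jitter = 5.0,
                     double ge0 = 0.0, double gi0 = 0.0,
                     double v0_center = NA_REAL, double p0_init = NA_REAL) {
  const int N = pop.size();
  const double Qe = syn[0], Qi = syn[1], tau = syn[2], Ee = syn[3], Ei = syn[4];
  const double decay = std::exp(-dt / tau);
  const int nsteps = (int)std::lround(duration / dt);
  const bool has_stim = stim.size() > 0;

  // pars: one column per population (0 = excitatory, 1 = inhibitory)
  std::vector<double> v(N), s1(N, 0.0), s2(N, 0.0), s3(N, 0.0), s4(N, 0.0);
  std::vector<double> ge(N, 0.0), gi(N, 0.0), refr(N, 0.0);
  for (int i = 0; i < N; ++i) {
    // desynchronized start: conductances mildly jittered around the means
    ge[i] = ge0 * (0.9 + 0.2 * unif_rand());
    gi[i] = gi0 * (0.9 + 0.2 * unif_rand());
  }
  std::vector<bool> above(N, false);
  std::vector<int> sp_id; std::vector<double> sp_t;
  std::vector<int> step_spikers; step_spikers.reserve(256);

  for (int i = 0; i < N; ++i) {
    const int c = pop[i];
    double EL = (model == ADEX) ? pars(2, c) : (model == HH ? pars(5, c) : pars(4, c));
    double vc = ISNAN(v0_center) ? EL : v0_center;
    v[i] = vc + v_init_jitter * (2.0 * unif_rand() - 1.0);
    if (model == HH) {
      HHRates r = hh_rates(v[i], pars(8, c), pars(9, c));
      s1[i] = r.an / (r.an + r.bn); s2[i] = r.am / (r.am + r.bm);
      s3[i] = r.ah / (r.ah + r.bh);
      // optionally start from an adapted state (elevated slow K+ gate)
      s4[i] = ISNAN(p0_init) ? r.pinf : std::max(r.pinf, p0_init);
    } else if (model == ML) {
      s1[i] = ml_Nss(v[i], pars(9, c), pars(10, c));
    }
  }

  for (int k = 0; k < nsteps; ++k) {
    const double t = k * dt;
    double rate_ext = nu_drive + (has_stim ? stim[k] : 0.0);
    if (rate_ext < 0) rate_ext = 0.0;
    const double p_ext = std::min(rate_ext * dt / 1000.0, 1.0);
    step_spikers.clear();

    for (int i = 0; i < N; ++i) {
      ge[i] *= decay; gi[i] *= decay;
      if (Ke_ext > 0 && p_ext > 0) ge[i] += Qe * R::rbinom((double)Ke_ext, p_ext);
      const int c = pop[i];
      const double Isyn = ge[i] * (Ee - v[i]) + gi[i] * (Ei - v[i]);
      bool spiked = false;

      if (model == ADEX) {
        const double cm = pars(0, c), gL = pars(1, c), EL = pars(2, c);
        const double Delta = pars(3, c), vt = pars(4, c), vrest = pars(5, c);
        const double Trefr = pars(6, c), a = pars(7, c), b = pars(8, c),
                     tauw = pars(9, c), vcut = pars(10, c);
        if (refr[i] > 0) {
          refr[i] -= dt; v[i] = vrest;
          s1[i] += dt * (a * (v[i] - EL) - s1[i]) / tauw;
        } else {
          const double dv = (gL * (EL - v[i])
                             + gL * Delta * std::exp((v[i] - vt) / Delta)
                             - s1[i] + Isyn) / cm;
          const double dw = (a * (v[i] - EL) - s1[i]) / tauw;
          v[i] += dt * dv; s1[i] += dt * dw;
          if (v[i] > vcut) {
            v[i] = vrest; s1[i] += b; refr[i] = Trefr; spiked = true;
          }
        }
      } else if (model == HH) {
        const double cm = pars(0, c), gL = pars(1, c), gNa = pars(2, c),
                     gK = pars(3, c), gM = pars(4, c), EL = pars(5, c),
                     ENa = pars(6, c), EK = pars(7, c), VT = pars(8, c),
                     taumax = pars(9, c), thr = pars(10, c);
        HHRates r = hh_rates(v[i], VT, taumax);
        const double dv = (gL * (EL - v[i])
                           + gNa * s2[i] * s2[i] * s2[i] * s3[i] * (ENa - v[i])
                           + gK * s1[i] * s1[i] * s1[i] * s1[i] * (EK - v[i])
                           + gM * s4[i] * (EK - v[i]) + Isyn) / cm;
        s1[i] += dt * (r.an * (1.0 - s1[i]) - r.bn * s1[i]);
        s2[i] += dt * (r.am * (1.0 - s2[i]) - r.bm * s2[i]);
        s3[i] += dt * (r.ah * (1.0 - s3[i]) - r.bh * s3[i]);
        s4[i] += dt * (r.pinf - s4[i]) / r.taup;
        v[i] += dt * dv;
        if (!above[i] && v[i] >= thr) { spiked = true; above[i] = true; }
        else if (above[i] && v[i] < thr) above[i] = false;
      } else {
        const double cm = pars(0, c), gL = pars(1, c), gCa = pars(2, c),
                     gK = pars(3, c), EL = pars(4, c), ECa = pars(5, c),
                     EK = pars(6, c), V1 = pars(7, c), V2 = pars(8, c),
                     V3 = pars(9, c), V4 = pars(10, c), phi = pars(11, c),
                     I0 = pars(12, c), thr = pars(13, c);
        const double dv = (gL * (EL - v[i])
                           + gCa * ml_Mss(v[i], V1, V2) * (ECa - v[i])
                           + gK * s1[i] * (EK - v[i]) + Isyn + I0) / cm;
        s1[i] += dt * (ml_Nss(v[i], V3, V4) - s1[i]) / ml_tauN(v[i], V3, V4, phi);
        v[i] += dt * dv;
        if (!above[i] && v[i] >= thr) { spiked = true; above[i] = true; }
        else if (above[i] && v[i] < thr) above[i] = false;
      }

      if (!std::isfinite(v[i]))
        stop("non-finite membrane potential for neuron %d at t = %.3f ms",
             i + 1, t);
      if (spiked) {
        sp_id.push_back(i + 1); sp_t.push_back(t + dt);
        step_spikers.push_back(i);
      }
    }

    for (size_t si = 0; si < step_spikers.size(); ++si) {
      const int s = step_spikers[si];
      const bool exc = pop[s] == 0;
      for (int e = ptr[s]; e < ptr[s + 1]; ++e) {
        const int tg = targets[e];
        if (exc) ge[tg] += Qe; else gi[tg] += Qi;
      }
    }
    if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["neuron"] = IntegerVector(sp_id.begin(), sp_id.end()),
                      _["t"] = NumericVector(sp_t.begin(), sp_t.end()),
                      _["n_steps"] = nsteps);
}
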