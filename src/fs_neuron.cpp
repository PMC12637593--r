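#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment conductance-based fast-spiking neuron.
//
// Currents (pA; V in mV, g in nS, C in pF, t in ms):
//   leak            g_l (V - e_l)
//   transient Na    g_na m^3 h s (V - e_na): fast (h) and slow (s) inactivation
//   fast K (Kv3)    g_kv3 n^2 (V - e_k)
//   delayed rect.   [g_hom p z_hom + g_het p_het z_het] (V - e_k)
// where the delayed-rectifier (Kv2-like) conductance is split into a
// homomeric and a heteromeric population; the heteromer steady-state
// inactivation half-voltage is shifted by d_inact (mV, negative) and its
// activation half-voltage by d_act (mV, negative).
//
// Gates use first-order kinetics integrated by exponential Euler; the
// voltage equation is also advanced by exponential Euler on its locally
// linear (conductance) form, which is unconditionally stable.  Noise is an
// Ornstein-Uhlenbeck current with stationary SD noise_sd_pA and correlation
// time tau_noise, driven by pre-generated standard normal deviates so that
// all randomness flows through R's RNG.

static inline double sigmoid(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

// [[Rcpp::export(name = ".fs_neuron_sim")]]
List fs_neuron_sim(NumericVector par, double dt, int n_samples, int n_sub,
                   NumericVector i_stim, NumericVector noise_z,
                   bool record_currents) {
  const double cm     = par["cm_pF"];
  const double g_l    = par["g_leak_nS"];
  const double e_l    = par["e_leak_mV"];
  const double g_na   = par["g_na_nS"];
  const double e_na   = par["e_na_mV"];
  const double g_kv3  = par["g_kv3_nS"];
  const double e_k    = par["e_k_mV"];
  const double g_kv2  = par["g_kv2_nS"];
  const double f_het  = par["f_het"];
  const double d_in   = par["d_inact_mV"];
  const double v0     = par["v_init_mV"];
  const double nsd    = par["noise_sd_pA"];
  const double tau_no = par["tau_noise_ms"];

  // gating parameters (half-voltages mV, slopes mV, taus ms)
  const double vm_m = par["m_vhalf"], km_m = par["m_k"], tm_m = par["m_tau"];
  const double vh_h = par["h_vhalf"], kh_h = par["h_k"];
  const double vs_s = par["s_vhalf"], ks_s = par["s_k"], ts_s = par["s_tau"];
  const double s_min = par["s_min"]; // incomplete slow inactivation
  const double th0  = par["h_tau0"],  tha = par["h_tau_amp"],
               thv  = par["h_tau_vmid"], thk = par["h_tau_width"];
  const double vn_n = par["n_vhalf"], kn_n = par["n_k"];
  const double tn0  = par["n_tau0"],  tna = par["n_tau_amp"],
               tnv  = par["n_tau_vmid"], tnk = par["n_tau_width"];
  const double vp_p = par["p_vhalf"], kp_p = par["p_k"], tp_p = par["p_tau"];
  const double d_act = par["d_act_mV"]; // heteromer activation half-voltage shift
  const double vz_z = par["z_vhalf"], kz_z = par["z_k"], tz_z = par["z_tau"];
  const double z_min = par["z_min"]; // incomplete steady-state inactivation floor

  const double g_hom = (1.0 - f_het) * g_kv2;
  const double g_het = f_het * g_kv2;
  const double h_sub = dt / n_sub;

  double V = v0;
  // gates start at steady state for v0
  double m = sigmoid(v0, vm_m, km_m);
  double h = sigmoid(-(v0 - vh_h), 0.0, kh_h); // inactivation: decreasing in V
  double sg = s_min + (1.0 - s_min) * sigmoid(-(v0 - vs_s), 0.0, ks_s); // slow Na inactivation
  double n = sigmoid(v0, vn_n, kn_n);
  double p = sigmoid(v0, vp_p, kp_p);
  double p_het = sigmoid(v0, vp_p + d_act, kp_p);
  double z_hom = z_min + (1.0 - z_min) * sigmoid(-(v0 - vz_z), 0.0, kz_z);
  double z_het = z_min + (1.0 - z_min) * sigmoid(-(v0 - (vz_z + d_in)), 0.0, kz_z);
  double i_ou = 0.0;

  const double ou_decay = std::exp(-h_sub / tau_no);
  const double ou_sd = nsd * std::sqrt(1.0 - ou_decay * ou_decay);

  NumericVector v_out(n_samples);
  NumericVector i_ion(record_currents ? n_samples : 0);
  NumericVector i_noise(record_currents ? n_samples : 0);

  R_xlen_t zi = 0;
  const bool has_noise = noise_z.size() > 0 && nsd > 0.0;

  for (int s = 0; s < n_samples; ++s) {
    const double i_app = i_stim[s];
    for (int k = 0; k < n_sub; ++k) {
      // gate updates (exponential Euler at current V)
      const double m_inf = sigmoid(V, vm_m, km_m);
      const double h_inf = 1.0 - sigmoid(V, vh_h, kh_h);
      const double dvh = (V - thv) / thk;
      const double tau_h = th0 + tha * std::exp(-dvh * dvh);
      const double n_inf = sigmoid(V, vn_n, kn_n);
      const double dvn = (V - tnv) / tnk;
      const double tau_n = tn0 + tna * std::exp(-dvn * dvn);
      const double p_inf = sigmoid(V, vp_p, kp_p);
      const double pe_inf = sigmoid(V, vp_p + d_act, kp_p);
      const double zh_inf = z_min + (1.0 - z_min) * (1.0 - sigmoid(V, vz_z, kz_z));
      const double ze_inf = z_min + (1.0 - z_min) * (1.0 - sigmoid(V, vz_z + d_in, kz_z));

      if (tm_m > 0.0) {
        m += (m_inf - m) * (1.0 - std::exp(-h_sub / tm_m));
      } else {
        m = m_inf; // instantaneous activation
      }
      h += (h_inf - h) * (1.0 - std::exp(-h_sub / tau_h));
      const double s_inf = s_min + (1.0 - s_min) * (1.0 - sigmoid(V, vs_s, ks_s));
      sg += (s_inf - sg) * (1.0 - std::exp(-h_sub / ts_s));
      n += (n_inf - n) * (1.0 - std::exp(-h_sub / tau_n));
      p += (p_inf - p) * (1.0 - std::exp(-h_sub / tp_p));
      p_het += (pe_inf - p_het) * (1.0 - std::exp(-h_sub / tp_p));
      z_hom += (zh_inf - z_hom) * (1.0 - std::exp(-h_sub / tz_z));
      z_het += (ze_inf - z_het) * (1.0 - std::exp(-h_sub / tz_z));

      if (has_noise) {
        i_ou = i_ou * ou_decay + ou_sd * noise_z[zi++];
      }

      // voltage update: dV/dt = (A - G V)/cm, exponential Euler
      const double g_na_eff = g_na * m * m * m * h * sg;
      const double g_k3_eff = g_kv3 * n * n;
      const double g_k2_eff = g_hom * p * z_hom + g_het * p_het * z_het;
      const double G = g_l + g_na_eff + g_k3_eff + g_k2_eff;
      const double A = g_l * e_l + g_na_eff * e_na +
                       (g_k3_eff + g_k2_eff) * e_k + i_app + i_ou;
      const double v_inf = A / G;
      V = v_inf + (V - v_inf) * std::exp(-G * h_sub / cm);
      if (!std::isfinite(V)) {
        stop("fs neuron integration diverged (non-finite V) at t = %f ms "
             "with sub-step %f ms; reduce the integration step",
             s * dt + k * h_sub, h_sub);
      }
    }
    v_out[s] = V;
    if (record_currents) {
      // total ionic current at the sample point (pA, outward positive)
      const double ionic =
          g_l * (V - e_l) +
          g_na * m * m * m * h * sg * (V - e_na) +
          (g_kv3 * n * n + g_hom * p * z_hom + g_het * p_het * z_het) * (V - e_k);
      i_ion[s] = ionic;
      i_noise[s] = i_ou;
    }
  }

  List out = List::create(_["v_mV"] = v_out);
  if (record_currents) {
    out["i_ion_pA"] = i_ion;
    out["i_noise_pA"] = i_noise;
  }
  return out;
}
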