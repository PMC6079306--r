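#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Victor-Purpura spike-train distance, O(nm) dynamic programming.
// Costs: insert/delete = 1, shift by dt = q*|dt|.
// [[Rcpp::export]]
double cpp_vp_distance(NumericVector a, NumericVector b, double q) {
  int n = a.size(), m = b.size();
  if (n == 0) return (double)m;
  if (m == 0) return (double)n;
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      double shift = prev[j - 1] + q * std::fabs(a[i - 1] - b[j - 1]);
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      cur[j] = std::min(shift, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Izhikevich neuron driven by a piecewise-constant input current (one value
// per input sample of width dt_input), integrated with Euler steps dt_int.
// v, u in the model's native mV/ms units; returns spike times in seconds.
// [[Rcpp::export]]
NumericVector cpp_izhikevich(NumericVector I, double dt_input, double dt_int,
                             double A, double B, double C,
                             double a, double b, double c, double d,
                             double v_thr, double v0, double u0) {
  int nsub = (int)std::round(dt_input / dt_int);
  if (nsub < 1) nsub = 1;
  double h = dt_input / nsub * 1000.0;  // ms per internal step
  double v = v0, u = u0;
  std::vector<double> spikes;
  for (int k = 0; k < I.size(); ++k) {
    double Ik = I[k];
    for (int s = 0; s < nsub; ++s) {
      v += h * (A * v * v + B * v + C - u + Ik);
      u += h * a * (b * v - u);
      if (v >= v_thr) {
        spikes.push_back(k * dt_input + (s + 1) * dt_input / nsub);
        v = c;
        u += d;
      }
    }
  }
  return wrap(spikes);
}

// One stimulus presentation of the cuneate projection-neuron model.
//
// State: Vm, xCaA, xCaI, xKCa, xKVm (gates), Ca (concentration), plus one
// decaying conductance accumulator per excitatory synapse, one for the lump
// inhibitory synapse, and a rise/decay accumulator pair per synapse for the
// subsynaptic local calcium kernel.
//
// atot_mode: 0 = A_tot is k*[Ca] from the intermediate dynamics,
//            1 = A_tot is the plain sum of the per-synapse local calcium
//                activities (supralinearity-ablation mode).
// [[Rcpp::export]]
List cpp_cn_simulate(List prm, List syn, List loc,
                     IntegerVector spike_ch, NumericVector spike_t,
                     NumericVector I_ext, double duration, double dt,
                     NumericVector init, bool record, bool plasticity,
                     double ca_thr, int atot_mode) {
  // neuron parameters
  const double Cm = prm["C_m"], gL = prm["g_L"], EL = prm["E_L"];
  const double DT = prm["Delta_T"], Vt = prm["V_t"];
  const double gK = prm["g_K"], gCa = prm["g_Ca"];
  const double EK = prm["E_K"], ECa = prm["E_Ca"];
  const double BCa = prm["B_Ca"], Carest = prm["Ca_rest"];
  const double tCa = prm["tau_Ca_conc"], tCaA = prm["tau_Ca_a"],
               tCaI = prm["tau_Ca_i"], tKCa = prm["tau_KCa"],
               tKVm = prm["tau_KVm"];
  const double pCaA1 = prm["p_Ca_a_1"], pCaA2 = prm["p_Ca_a_2"];
  const double pCaI1 = prm["p_Ca_i_1"], pCaI2 = prm["p_Ca_i_2"];
  const double pKVm1 = prm["p_KVm_1"], pKVm2 = prm["p_KVm_2"];
  const double pKCa1 = prm["p_KCa_1"], pKCa2 = prm["p_KCa_2"];
  const double kAtot = prm["k_Atot"];
  const double ca_per_spike = prm["ca_per_spike"];
  const double slope_thr = prm["spike_detect_slope"];
  const double refractory = prm["refractory"];
  const double Vceil = Vt + 10.0 * DT;
  const int refr_steps = (int)std::round(refractory / dt);

  // synapse bank
  NumericVector w_exc = syn["w_exc"];
  const int ns = w_exc.size();
  const double gmax = syn["g_max"], tsyn = syn["tau_syn"];
  const double Eexc = syn["E_rev_exc"], Einh = syn["E_rev_inh"];
  const double winh = syn["w_inh_total"];
  const double inh_delay = syn["inh_delay"];  // disynaptic latency

  // local calcium kernel
  const double tau_d = loc["tau_d"], tau_r = loc["tau_r"],
               tau_1 = loc["tau_1"], tau_l = loc["tau_l"];
  const double offset = loc["offset"];  // absolute offset, precomputed
  const double alpha = tau_1 / (tau_d - tau_r);

  const int nsteps = (int)std::round(duration / dt);
  const bool ext_series = I_ext.size() > 1;
  const double ext0 = I_ext.size() > 0 ? I_ext[0] : 0.0;

  double Vm = init[0], xa = init[1], xi = init[2], xkca = init[3],
         xkvm = init[4], Ca = init[5];

  std::vector<double> s_exc(ns, 0.0), locD(ns, 0.0), locR(ns, 0.0);
  double s_inh = 0.0;
  const double dsyn = std::exp(-dt / tsyn);
  const double dD = std::exp(-dt / tau_d), dR = std::exp(-dt / tau_r);

  std::vector<double> spikes;
  std::vector<double> int_aa(ns, 0.0), int_al(ns, 0.0);
  double atot_sum = 0.0;
  int crossings = 0;
  double atot_prev = (atot_mode == 1) ? 0.0 : kAtot * Ca;
  bool armed = true;
  double V_init = Vt;  // fallback initiation potential for ceiling events
  int refr_count = 0;
  int isp = 0;        // pointer into spike arrays (excitatory stream)
  int iin = 0;        // pointer for the delayed inhibitory stream
  int ilc = 0;        // pointer for the local-calcium stream (latency tau_l)
  bool blowup = false;

  NumericVector recV, recCa, recAtot;
  if (record) {
    recV = NumericVector(nsteps + 1);
    recCa = NumericVector(nsteps + 1);
    recAtot = NumericVector(nsteps + 1);
    recV[0] = Vm; recCa[0] = Ca;
  }

  for (int n = 0; n < nsteps; ++n) {
    double t = n * dt;
    // deliver afferent spikes falling in [t, t+dt)
    while (isp < spike_t.size() && spike_t[isp] < t + dt) {
      if (spike_t[isp] >= t) {
        int ch = spike_ch[isp] - 1;
        if (ch >= 0 && ch < ns) s_exc[ch] += 1.0;
      }
      ++isp;
    }
    while (iin < spike_t.size() && spike_t[iin] + inh_delay < t + dt) {
      if (spike_t[iin] + inh_delay >= t) {
        int ch = spike_ch[iin] - 1;
        if (ch >= 0 && ch < ns) s_inh += 1.0;
      }
      ++iin;
    }
    while (ilc < spike_t.size() && spike_t[ilc] + tau_l < t + dt) {
      if (spike_t[ilc] + tau_l >= t) {
        int ch = spike_ch[ilc] - 1;
        if (ch >= 0 && ch < ns) { locD[ch] += 1.0; locR[ch] += 1.0; }
      }
      ++ilc;
    }

    // currents from the current state
    double sum_ws = 0.0;
    for (int i = 0; i < ns; ++i) sum_ws += w_exc[i] * s_exc[i];
    double gexc = gmax * sum_ws, ginh = gmax * winh * s_inh;
    double gca = gCa * xa * xa * xa * xi;
    double gk = gK * std::pow(xkca, 4) * std::pow(xkvm, 4);
    double earg = (Vm - Vt) / DT;
    if (earg > 20.0) earg = 20.0;  // overflow guard; ceiling fires first
    double Ispike = gL * DT * std::exp(earg);
    double Iext = ext_series ? I_ext[n] : ext0;
    // integrating-factor (exponential Euler) membrane update: exact for the
    // conductance part over one step, unconditionally stable for any g_max
    double gtot = gL + gexc + ginh + gca + gk;
    double Vinf = (gL * EL + gexc * Eexc + ginh * Einh + gca * ECa +
                   gk * EK + Ispike + Iext) / gtot;
    double Vnew = Vinf + (Vm - Vinf) * std::exp(-gtot * dt / Cm);
    double dVdt = (Vnew - Vm) / dt;

    // spike detection: slope threshold on the upstroke, with a ceiling
    // fallback; membrane reset to the potential at which the spike initiated
    // and held there for the fast-AHP refractory window
    bool fired = false;
    if (refr_count > 0) {
      Vnew = V_init;
      --refr_count;
    } else if (armed && dVdt >= slope_thr) {
      fired = true;
      // initiation potential: where the upstroke crossed the speed
      // criterion, capped at the formal EIF threshold so the fast AHP
      // always ends below the spike-generation region
      V_init = std::min(Vm, Vt);
      Vnew = V_init;
    } else if (Vnew >= Vceil) {
      fired = true;  // sustained drive keeps slope detection disarmed
      Vnew = V_init;
    }
    if (fired) {
      spikes.push_back(t + dt);
      armed = false;
      refr_count = refr_steps;
      Ca += ca_per_spike;  // spike-evoked (HVA-type) calcium influx
    } else if (dVdt < slope_thr) armed = true;

    // intermediate dynamics; gate equilibria evaluated at the midpoint
    // voltage of the step for second-order accuracy of the gate forcing
    double Vmid = 0.5 * (Vm + Vnew);
    double xa_bar = 1.0 / (1.0 + std::exp((pCaA1 - Vmid) / pCaA2));
    double xi_bar = 1.0 - 1.0 / (1.0 + std::exp((pCaI1 - Vmid) / pCaI2));
    double xkvm_bar = 1.0 / (1.0 + std::exp((pKVm1 - Vmid) / pKVm2));
    // calcium-ACTIVATED gate: opens as [Ca] rises (CAP physiology)
    double xkca_bar = 1.0 / (1.0 + std::exp((pKCa1 - Ca) / pKCa2));
    // calcium: exponential relaxation toward its instantaneous equilibrium
    double influx = BCa * gCa * xa * xa * xa * xi * (ECa - Vmid);
    double Caeq = Carest + influx * tCa;
    double Canew = Caeq + (Ca - Caeq) * std::exp(-dt / tCa);
    // exact exponential relaxation toward the (frozen) equilibria
    xa = xa_bar + (xa - xa_bar) * std::exp(-dt / tCaA);
    xi = xi_bar + (xi - xi_bar) * std::exp(-dt / tCaI);
    xkca = xkca_bar + (xkca - xkca_bar) * std::exp(-dt / tKCa);
    xkvm = xkvm_bar + (xkvm - xkvm_bar) * std::exp(-dt / tKVm);
    Ca = Canew;
    if (Ca < 0) Ca = 0;
    Vm = Vnew;

    // conductance and local-calcium kernels decay
    for (int i = 0; i < ns; ++i) {
      s_exc[i] *= dsyn;
      locD[i] *= dD;
      locR[i] *= dR;
    }
    s_inh *= dsyn;

    // activities at t+dt
    double atot;
    if (atot_mode == 1) {
      atot = 0.0;
      for (int i = 0; i < ns; ++i) {
        double al = alpha * (locD[i] - locR[i]) - offset;
        if (al > 0) atot += al;
      }
    } else {
      atot = kAtot * Ca;
    }
    atot_sum += atot;
    if (atot_prev < ca_thr && atot >= ca_thr) ++crossings;
    atot_prev = atot;

    if (plasticity) {
      for (int i = 0; i < ns; ++i) {
        double al = alpha * (locD[i] - locR[i]) - offset;
        if (al > 0) {
          int_aa[i] += atot * al * dt;
          int_al[i] += al * dt;
        }
      }
    }

    if (record) {
      recV[n + 1] = Vm;
      recCa[n + 1] = Ca;
      recAtot[n + 1] = atot;
    }

    if (!std::isfinite(Vm) || std::fabs(Vm) > 0.5) { blowup = true; break; }
  }

  List out = List::create(
    _["spike_times"] = wrap(spikes),
    _["atot_mean"] = atot_sum * dt / duration,
    _["int_atot_aloc"] = wrap(int_aa),
    _["int_aloc"] = wrap(int_al),
    _["ca_crossings"] = crossings,
    _["state"] = NumericVector::create(Vm, xa, xi, xkca, xkvm, Ca),
    _["blowup"] = blowup);
  if (record) {
    out["V_m"] = recV;
    out["Ca_conc"] = recCa;
    out["A_tot"] = recAtot;
  }
  return out;
}
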