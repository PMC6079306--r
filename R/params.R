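#' Cuneate projection neuron (CN) model parameters
#'
#' Constructs the parameter set of the CN membrane model: the EIF fast
#' dynamics (capacitance, leak, spike slope factor and threshold), the
#' LVA/CAP intermediate dynamics (maximum conductances, reversals, gating
#' sigmoid constants and time constants) and the intracellular calcium
#' concentration dynamics. All values are strict SI (V, S, F, s, A; calcium
#' concentration in molar). Defaults are the fitted values of the published
#' cuneate model, except `B_Ca` whose table value is dimensionally inert (it
#' would leave the calcium concentration pinned at rest for any physically
#' possible LVA current); the default keeps the fitted mantissa with the
#' exponent recalibrated so that burst-evoked calcium transients traverse the
#' dynamic range of the CAP gating sigmoid (roughly 100-300 nM). See the
#' methods vignette.
#'
#' @param ... named overrides of any default parameter.
#' @return an object of class `cn_neuron_params` (a named list).
#' @examples
#' p <- cn_neuron_params()
#' p$E_L                     # leak reversal, volts
#' cn_neuron_params(g_Ca = 0, g_K = 0)  # plain EIF
#' @export
cn_neuron_params <- function(...) {
  p <- list(
    C_m = 4.270e-11,          # membrane capacitance (F)
    g_L = 8.100e-09,          # leak conductance (S)
    E_L = -62.309e-3,         # leak reversal (V)
    Delta_T = 1.3063e-3,      # EIF spike slope factor (V)
    V_t = -57.129e-3,         # EIF spike threshold (V)
    g_K = 2.022e-08,          # max CAP conductance (S)
    g_Ca = 2.082e-08,         # max LVA conductance (S)
    E_K = -104.514e-3,        # potassium reversal (V)
    E_Ca = 121.436e-3,        # calcium reversal (V)
    B_Ca = 3.374e5,           # current-to-concentration factor (M/C); see docs
    Ca_rest = 1.010e-07,      # resting calcium concentration (M)
    tau_Ca_conc = 0.0063,     # calcium concentration leak time constant (s)
    tau_Ca_a = 2.722e-04,     # LVA activation time constant (s)
    tau_Ca_i = 0.0207,        # LVA inactivation time constant (s)
    tau_KCa = 0.0013,         # CAP calcium-gate time constant (s)
    tau_KVm = 0.0011,         # CAP voltage-gate time constant (s)
    p_Ca_a_1 = -60.8369e-3,   # sigmoid midpoint, LVA activation (V)
    p_Ca_a_2 = 6.3419e-3,     # sigmoid slope, LVA activation (V)
    p_Ca_i_1 = -68.0100e-3,   # sigmoid midpoint, LVA inactivation (V)
    p_Ca_i_2 = 1.3008e-3,     # sigmoid slope, LVA inactivation (V)
    p_KVm_1 = -64.0785e-3,    # sigmoid midpoint, CAP voltage gate (V)
    p_KVm_2 = 0.7833e-3,      # sigmoid slope, CAP voltage gate (V)
    p_KCa_1 = 2.2166e-07,     # sigmoid midpoint, CAP calcium gate (M)
    p_KCa_2 = 4.7923e-08,     # sigmoid slope, CAP calcium gate (M)
    k_Atot = 1,               # total calcium activity per unit concentration
    spike_detect_slope = 20,  # depolarization-speed spike criterion (V/s)
    refractory = 1e-3,        # fast-AHP hold at the initiation potential (s)
    ca_per_spike = 2e-8       # spike-evoked (HVA) calcium increment (M)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown neuron parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- lapply(ov, parse_quantity)
  }
  must_pos <- c("C_m", "g_L", "Delta_T", "tau_Ca_conc", "tau_Ca_a",
                "tau_Ca_i", "tau_KCa", "tau_KVm")
  for (nm in must_pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("neuron parameter '", nm, "' must be positive")
  for (nm in c("g_K", "g_Ca"))
    if (p[[nm]] < 0) stop("conductance '", nm, "' must be >= 0")
  structure(p, class = "cn_neuron_params")
}

#' Bank of PA synapses on one CN
#'
#' Holds the excitatory weight vector (one weight per primary afferent), the
#' lump inhibitory weight, and the shared conductance kernel constants. Every
#' PA spike drives both its own excitatory synapse and the lump inhibitory
#' synapse (the inhibitory interneurons are not simulated explicitly).
#'
#' @param n_exc number of excitatory PA synapses.
#' @param w_exc weight vector in `[0.001, 1]`; default uniform 0.125 so the
#'   total starts at the homeostatic set point of 10 for 80 synapses.
#' @param w_inh_total lump inhibitory weight (>= 0); default 0.5, within the
#'   basin of attraction of the inhibitory homeostat (see the methods
#'   vignette).
#' @param g_max maximum synaptic conductance constant (S).
#' @param tau_syn conductance decay time constant (s).
#' @param E_rev_exc,E_rev_inh synaptic reversal potentials (V).
#' @param inh_delay disynaptic latency of the interneuron-relayed
#'   inhibition relative to the direct PA excitation (s); the measured
#'   compound-IPSP onset lag is about 1 ms.
#' @return an object of class `cn_synapse_bank`.
#' @export
cn_synapse_bank <- function(n_exc = 80, w_exc = NULL, w_inh_total = 0.5,
                            g_max = 23e-8, tau_syn = 6.4e-3,
                            E_rev_exc = 0, E_rev_inh = -80e-3,
                            inh_delay = 1e-3) {
  if (is.null(w_exc)) w_exc <- rep(0.125, n_exc)
  n_exc <- length(w_exc)
  g_max <- parse_quantity(g_max); tau_syn <- parse_quantity(tau_syn)
  E_rev_exc <- parse_quantity(E_rev_exc); E_rev_inh <- parse_quantity(E_rev_inh)
  if (any(w_exc < 0.001 - 1e-12 | w_exc > 1 + 1e-12))
    stop("excitatory weights must lie in [0.001, 1]")
  if (w_inh_total < 0) stop("w_inh_total must be >= 0")
  if (tau_syn <= 0) stop("tau_syn must be > 0")
  structure(list(n_exc = n_exc, w_exc = w_exc, w_inh_total = w_inh_total,
                 g_max = g_max, tau_syn = tau_syn,
                 E_rev_exc = E_rev_exc, E_rev_inh = E_rev_inh,
                 inh_delay = parse_quantity(inh_delay)),
            class = "cn_synapse_bank")
}

#' Subsynaptic local calcium kernel parameters
#'
#' The calcium transient evoked in a synaptic space by one presynaptic spike
#' follows a difference-of-exponentials kernel
#' `alpha * (exp(-t/tau_d) - exp(-t/tau_r))` with `alpha = tau_1/(tau_d -
#' tau_r)`, delayed by `tau_l`. Supralinearity is approximated by subtracting
#' an offset equal to `offset_frac` of the single-pulse peak from the summed
#' signal and rectifying at zero, so only repetitive (high-frequency)
#' activation produces a sizeable local calcium activity.
#'
#' @param tau_d decay time constant (s).
#' @param tau_r rise time constant (s).
#' @param tau_1 scaling constant (s).
#' @param tau_l latency (s).
#' @param offset_frac offset as a fraction of the single-pulse peak, in `[0, 1)`.
#' @param scale_pct global percentage scaling applied to `(tau_d, tau_r, tau_1)`;
#'   100 is the base configuration.
#' @return an object of class `cn_local_ca_params`.
#' @export
cn_local_ca_params <- function(tau_d = 12.5e-3, tau_r = 4e-3, tau_1 = 21e-3,
                               tau_l = 0, offset_frac = 0.75, scale_pct = 100) {
  s <- scale_pct / 100
  tau_d <- parse_quantity(tau_d) * s
  tau_r <- parse_quantity(tau_r) * s
  tau_1 <- parse_quantity(tau_1) * s
  tau_l <- parse_quantity(tau_l)
  if (!(tau_d > tau_r && tau_r > 0))
    stop("local calcium kernel requires tau_d > tau_r > 0")
  if (offset_frac < 0 || offset_frac >= 1)
    stop("offset_frac must lie in [0, 1)")
  structure(list(tau_d = tau_d, tau_r = tau_r, tau_1 = tau_1, tau_l = tau_l,
                 offset_frac = offset_frac, scale_pct = scale_pct),
            class = "cn_local_ca_params")
}

#' Plasticity configuration
#'
#' Set points, slopes and window lengths of the calcium-gated Hebbian rule
#' and its two homeostatic controls.
#'
#' @param setpoint_sum_wexc target total excitatory weight (Syn_EQ zero point).
#' @param slope_above,slope_below Syn_EQ slopes above/below the set point.
#' @param comp_steepness steepness of the weight-compensation sigmoid on the
#'   `[0, 1]` weight axis (see [weight_compensation()]).
#' @param comp_midpoint weight at which both compensation branches equal 0.5.
#' @param setpoint_ca_rate calcium spike-rate set point (Hz).
#' @param inh_delta_min,inh_delta_max inhibitory weight change at 0 Hz and at
#'   `inh_rate_max` Hz.
#' @param inh_rate_max upper end of the calcium-rate range for the inhibitory
#'   rule (Hz); rates are clamped to `[0, inh_rate_max]`.
#' @param avg_window moving-average window, in presentations, for the total
#'   calcium activity and the calcium spike rate.
#' @param ca_rate_threshold threshold on the total calcium activity above
#'   which an upward crossing counts as one calcium spike.
#' @param eta global learning-rate constant mapping the net learning-drive
#'   integral onto weight units.
#' @param w_min,w_max excitatory weight bounds.
#' @return an object of class `cn_plasticity_config`.
#' @export
cn_plasticity_config <- function(setpoint_sum_wexc = 10,
                                 slope_above = 0.12, slope_below = 0.04,
                                 comp_steepness = 0.1, comp_midpoint = 0.5,
                                 setpoint_ca_rate = 20,
                                 inh_delta_min = -0.01, inh_delta_max = 0.01,
                                 inh_rate_max = 200,
                                 avg_window = 3,
                                 ca_rate_threshold = 2e-7,
                                 eta = 1.2e8,
                                 w_min = 0.001, w_max = 1) {
  stopifnot(slope_above > 0, slope_below > 0, avg_window >= 1,
            inh_delta_min < 0, inh_delta_max > 0,
            setpoint_ca_rate > 0, setpoint_ca_rate < inh_rate_max,
            w_min < w_max)
  structure(list(setpoint_sum_wexc = setpoint_sum_wexc,
                 slope_above = slope_above, slope_below = slope_below,
                 comp_steepness = comp_steepness, comp_midpoint = comp_midpoint,
                 setpoint_ca_rate = setpoint_ca_rate,
                 inh_delta_min = inh_delta_min, inh_delta_max = inh_delta_max,
                 inh_rate_max = inh_rate_max, avg_window = avg_window,
                 ca_rate_threshold = ca_rate_threshold, eta = eta,
                 w_min = w_min, w_max = w_max),
            class = "cn_plasticity_config")
}

#' CN state vector
#'
#' The five dynamic state variables of the CN plus the calcium concentration:
#' membrane potential, LVA activation/inactivation gates, CAP calcium and
#' voltage gates, and the intracellular calcium concentration.
#'
#' @param V_m membrane potential (V).
#' @param x_Ca_a,x_Ca_i,x_KCa,x_KVm channel gates in `[0, 1]`.
#' @param Ca_conc calcium concentration (M, >= 0).
#' @return an object of class `cn_state`.
#' @export
cn_state <- function(V_m, x_Ca_a, x_Ca_i, x_KCa, x_KVm, Ca_conc) {
  x <- c(V_m = V_m, x_Ca_a = x_Ca_a, x_Ca_i = x_Ca_i,
         x_KCa = x_KCa, x_KVm = x_KVm, Ca_conc = Ca_conc)
  if (any(!is.finite(x))) stop("non-finite state value")
  if (any(x[2:5] < 0 | x[2:5] > 1)) stop("gates must lie in [0, 1]")
  if (x[["Ca_conc"]] < 0) stop("Ca_conc must be >= 0")
  structure(as.list(x), class = "cn_state")
}

#' Resting CN state
#'
#' State with the membrane at the leak reversal, gates at their equilibria
#' for that potential, and calcium at rest. This is the conventional initial
#' condition; the true resting fixed point (with the standing CAP current) is
#' found within a few tens of ms of relaxation.
#'
#' @param params a [cn_neuron_params()] object.
#' @return a [cn_state()] object.
#' @export
cn_state_rest <- function(params = cn_neuron_params()) {
  eq <- gating_equilibria(params$E_L, params$Ca_rest, params)
  cn_state(params$E_L, eq$x_Ca_a, eq$x_Ca_i, eq$x_KCa, eq$x_KVm, params$Ca_rest)
}
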