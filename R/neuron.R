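#' Leak plus EIF spike current
#'
#' Returns `I_L + I_spike = -g_L (V_m - E_L) + g_L Delta_T exp((V_m -
#' V_t)/Delta_T)`, the sum of the passive leak and the exponential
#' spike-initiation current of the EIF model.
#'
#' @param V_m membrane potential (V), vectorized.
#' @param params a [cn_neuron_params()] object.
#' @return current (A).
#' @export
leak_and_spike_current <- function(V_m, params = cn_neuron_params()) {
  if (any(!is.finite(V_m))) stop("non-finite membrane potential")
  -params$g_L * (V_m - params$E_L) +
    params$g_L * params$Delta_T * exp((V_m - params$V_t) / params$Delta_T)
}

#' Gating equilibrium values
#'
#' Voltage-dependent equilibria of the LVA activation/inactivation gates and
#' the CAP voltage gate, and the calcium-dependent equilibrium of the CAP
#' calcium gate. Each is a two-parameter sigmoid
#' `(1 + exp((p1 - x)/p2))^-1`; the LVA inactivation gate uses one minus the
#' sigmoid (it closes with depolarization). The CAP calcium gate is an
#' activation gate: nearly closed at resting calcium, opening as burst
#' calcium rises, which is what lets the potassium conductance terminate
#' bursts (see the methods vignette for why this follows the channel's
#' stated function).
#'
#' @param V_m membrane potential (V).
#' @param Ca_conc calcium concentration (M).
#' @param params a [cn_neuron_params()] object.
#' @return list with `x_Ca_a`, `x_Ca_i`, `x_KVm`, `x_KCa`, each in `[0, 1]`.
#' @export
gating_equilibria <- function(V_m, Ca_conc, params = cn_neuron_params()) {
  if (any(!is.finite(c(V_m, Ca_conc)))) stop("non-finite input")
  sig <- function(x, p1, p2) 1 / (1 + exp((p1 - x) / p2))
  list(
    x_Ca_a = sig(V_m, params$p_Ca_a_1, params$p_Ca_a_2),
    x_Ca_i = 1 - sig(V_m, params$p_Ca_i_1, params$p_Ca_i_2),
    x_KVm = sig(V_m, params$p_KVm_1, params$p_KVm_2),
    x_KCa = sig(Ca_conc, params$p_KCa_1, params$p_KCa_2)
  )
}

#' LVA and CAP channel currents
#'
#' `I_Ca = -g_Ca x_Ca_a^3 x_Ca_i (V_m - E_Ca)` and
#' `I_K = -g_K x_KCa^4 x_KVm^4 (V_m - E_K)`.
#'
#' @param state a [cn_state()] object.
#' @param params a [cn_neuron_params()] object.
#' @return list with `I_Ca` and `I_K` (A).
#' @export
ion_currents <- function(state, params = cn_neuron_params()) {
  I_Ca <- -params$g_Ca * state$x_Ca_a^3 * state$x_Ca_i * (state$V_m - params$E_Ca)
  I_K <- -params$g_K * state$x_KCa^4 * state$x_KVm^4 * (state$V_m - params$E_K)
  list(I_Ca = I_Ca, I_K = I_K)
}

#' One integration step of the CN state
#'
#' Advances all five dynamic variables plus the calcium concentration by one
#' step. The membrane uses an integrating-factor (exponential Euler) update
#' over the leak/LVA/CAP conductances, which is unconditionally stable for
#' arbitrarily large conductances, with the EIF spike current and the input
#' currents (`I_syn`, `I_ext`) as explicit sources; gates relax first-order
#' exponentially (exactly, with equilibria frozen over the step) toward
#' their equilibria; the calcium concentration
#' gains the LVA influx (`B_Ca` times the inward calcium current magnitude,
#' so depolarization-activated LVA raises the concentration) and leaks back
#' toward rest with `tau_Ca_conc`. All derivatives are evaluated at the
#' incoming state (synchronous update). No spike detection is performed here;
#' see [cn_integrate()].
#'
#' @param state a [cn_state()] object.
#' @param I_syn,I_ext synaptic and external currents (A).
#' @param dt step (s); must satisfy `dt <= 0.5 * min(time constants)`.
#' @param params a [cn_neuron_params()] object.
#' @return the advanced [cn_state()].
#' @export
cn_step <- function(state, I_syn = 0, I_ext = 0, dt = 1e-4,
                    params = cn_neuron_params()) {
  taus <- c(params$tau_Ca_conc, params$tau_Ca_a, params$tau_Ca_i,
            params$tau_KCa, params$tau_KVm)
  if (dt <= 0) stop("dt must be > 0")
  if (dt > 0.5 * min(taus))
    stop("dt = ", dt, " s violates the stability guard dt <= 0.5 * min(tau) = ",
         0.5 * min(taus), " s")
  g_ca <- params$g_Ca * state$x_Ca_a^3 * state$x_Ca_i
  g_k <- params$g_K * state$x_KCa^4 * state$x_KVm^4
  I_spike <- params$g_L * params$Delta_T *
    exp(min((state$V_m - params$V_t) / params$Delta_T, 20))
  g_tot <- params$g_L + g_ca + g_k
  V_inf <- (params$g_L * params$E_L + g_ca * params$E_Ca + g_k * params$E_K +
              I_spike + I_syn + I_ext) / g_tot
  V_new <- V_inf + (state$V_m - V_inf) * exp(-g_tot * dt / params$C_m)
  eq <- gating_equilibria(state$V_m, state$Ca_conc, params)
  influx <- params$B_Ca * params$g_Ca * state$x_Ca_a^3 * state$x_Ca_i *
    (params$E_Ca - state$V_m)
  Ca_eq <- params$Ca_rest + influx * params$tau_Ca_conc
  Ca_new <- Ca_eq + (state$Ca_conc - Ca_eq) * exp(-dt / params$tau_Ca_conc)
  relax <- function(x, xb, tau) xb + (x - xb) * exp(-dt / tau)
  cn_state(
    V_m = V_new,
    x_Ca_a = relax(state$x_Ca_a, eq$x_Ca_a, params$tau_Ca_a),
    x_Ca_i = relax(state$x_Ca_i, eq$x_Ca_i, params$tau_Ca_i),
    x_KCa = relax(state$x_KCa, eq$x_KCa, params$tau_KCa),
    x_KVm = relax(state$x_KVm, eq$x_KVm, params$tau_KVm),
    Ca_conc = max(Ca_new, 0)
  )
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Integrate the CN over a stimulus window
#'
#' Runs the full model (fast EIF + intermediate LVA/CAP + calcium
#' concentration + synaptic conductances) with explicit Euler at step `dt`.
#' A spike is registered when the depolarization speed `dV_m/dt` crosses
#' `spike_detect_slope` on the upstroke (with a numeric ceiling at
#' `V_t + 10 Delta_T` as fallback); the membrane is then immediately reset to
#' the potential at which the spike initiated, mimicking the fast AHP of
#' cuneate projection neurons. Detection re-arms once `dV_m/dt` falls back
#' below the slope threshold.
#'
#' @param inputs optional afferent spikes: a list with integer `channel`
#'   (1-based, one excitatory synapse per channel) and numeric `time` (s),
#'   or `NULL` for no synaptic input.
#' @param duration window length (s).
#' @param dt integration step (s).
#' @param params a [cn_neuron_params()] object.
#' @param bank a [cn_synapse_bank()]; required when `inputs` is given.
#' @param local a [cn_local_ca_params()] object.
#' @param init initial [cn_state()]; default [cn_state_rest()].
#' @param I_ext external current: scalar or per-step vector (A).
#' @param record keep the membrane, calcium and total-activity series.
#' @param atot_mode `"calcium"` (total calcium activity `k_Atot * [Ca]`) or
#'   `"sum_aloc"` (ablation: plain sum of per-synapse local activities).
#' @param ca_rate_threshold threshold for calcium-spike counting, in units of
#'   the total activity.
#' @param plasticity also accumulate the per-synapse learning-drive
#'   integrals used by the weight update.
#' @return a `voltage_trace` object: `dt`, `duration`, `spike_times`, the
#'   recorded `V_m`, `Ca_conc` and `A_tot` series (if `record`), the mean
#'   total activity `atot_mean`, the calcium-spike count `ca_crossings`, the
#'   final `state`, and (if `plasticity`) the integrals `int_atot_aloc` and
#'   `int_aloc`.
#' @export
cn_integrate <- function(inputs = NULL, duration, dt = 1e-4,
                         params = cn_neuron_params(), bank = NULL,
                         local = cn_local_ca_params(),
                         init = NULL, I_ext = 0, record = TRUE,
                         atot_mode = c("calcium", "sum_aloc"),
                         ca_rate_threshold = 2e-7, plasticity = FALSE) {
  atot_mode <- match.arg(atot_mode)
  if (duration <= 0) stop("duration must be > 0")
  taus <- c(params$tau_Ca_conc, params$tau_Ca_a, params$tau_Ca_i,
            params$tau_KCa, params$tau_KVm)
  if (dt > 0.5 * min(taus)) stop("dt violates the stability guard")
  if (is.null(init)) init <- cn_state_rest(params)
  if (is.null(bank)) bank <- cn_synapse_bank(n_exc = 0, w_exc = numeric(0))
  if (is.null(inputs)) inputs <- list(channel = integer(0), time = numeric(0))
  ord <- order(inputs$time)
  ch <- as.integer(inputs$channel)[ord]
  tt <- as.numeric(inputs$time)[ord]
  offset <- local$offset_frac * local_ca_peak(local)
  loc <- list(tau_d = local$tau_d, tau_r = local$tau_r, tau_1 = local$tau_1,
              tau_l = local$tau_l, offset = offset)
  res <- cpp_cn_simulate(unclass(params), unclass(bank), loc,
                         ch, tt, as.numeric(I_ext), duration, dt,
                         as.numeric(unlist(init)), record, plasticity,
                         ca_rate_threshold,
                         if (atot_mode == "sum_aloc") 1L else 0L)
  if (isTRUE(res$blowup))
    stop("numeric blow-up: |V_m| exceeded 0.5 V outside a spike; ",
         "check dt, g_max and input scaling")
  st <- res$state
  out <- list(dt = dt, duration = duration,
              spike_times = as.numeric(res$spike_times),
              atot_mean = res$atot_mean,
              ca_crossings = res$ca_crossings,
              state = cn_state(st[1], st[2], st[3], st[4], st[5], st[6]))
  if (record) {
    out$time <- seq(0, duration, by = dt)
    out$V_m <- res$V_m
    out$Ca_conc <- res$Ca_conc
    out$A_tot <- res$A_tot
  }
  if (plasticity) {
    out$int_atot_aloc <- res$int_atot_aloc
    out$int_aloc <- res$int_aloc
  }
  structure(out, class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat("<voltage_trace> ", x$duration, "s at dt =", x$dt, "s;",
      length(x$spike_times), "spikes\n")
  invisible(x)
}

#' @export
as.data.frame.voltage_trace <- function(x, ...) {
  if (is.null(x$V_m)) stop("trace was not recorded")
  data.frame(time_s = x$time, Vm_V = x$V_m, Ca_conc = x$Ca_conc)
}
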