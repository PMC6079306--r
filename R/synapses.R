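#' Summated synaptic current
#'
#' Evaluates the instantaneous synaptic current on the CN given, for every
#' synapse, the elapsed times since its afferent spikes:
#' `I_syn = g_max sum_i w_i exp(-dt_i/tau) (E_exc - V_m) +
#'  g_max w_inh sum_j exp(-dt_j/tau) (E_inh - V_m)`.
#' Each PA spike drives both its excitatory synapse and the lump inhibitory
#' synapse.
#'
#' @param active_exc list (length `n_exc`) of vectors of elapsed times (s)
#'   since each excitatory synapse's spikes; may be empty vectors.
#' @param active_inh vector of elapsed times (s) feeding the lump inhibitory
#'   synapse (normally the union of all PA spikes).
#' @param V_m membrane potential (V).
#' @param bank a [cn_synapse_bank()].
#' @return current (A).
#' @export
synaptic_current <- function(active_exc, active_inh, V_m,
                             bank = cn_synapse_bank()) {
  if (length(active_exc) != bank$n_exc)
    stop("active_exc must have one entry per excitatory synapse")
  all_t <- c(unlist(active_exc), active_inh)
  if (length(all_t) && any(all_t < 0)) stop("elapsed times must be >= 0")
  gexc <- vapply(active_exc, function(ts) sum(exp(-ts / bank$tau_syn)), numeric(1))
  ginh <- sum(exp(-active_inh / bank$tau_syn))
  bank$g_max * sum(bank$w_exc * gexc) * (bank$E_rev_exc - V_m) +
    bank$g_max * bank$w_inh_total * ginh * (bank$E_rev_inh - V_m)
}

#' Single-spike local calcium kernel
#'
#' `alpha * (exp(-(t - tau_l)/tau_d) - exp(-(t - tau_l)/tau_r))` with
#' `alpha = tau_1/(tau_d - tau_r)`, zero before the latency `tau_l`.
#' Non-negative since `tau_d > tau_r`.
#'
#' @param t time since the presynaptic spike (s), vectorized.
#' @param p a [cn_local_ca_params()].
#' @return kernel value (dimensionless activity).
#' @export
local_ca_kernel <- function(t, p = cn_local_ca_params()) {
  if (p$tau_d <= p$tau_r) stop("configuration error: tau_d must exceed tau_r")
  alpha <- p$tau_1 / (p$tau_d - p$tau_r)
  tt <- t - p$tau_l
  out <- alpha * (exp(-tt / p$tau_d) - exp(-tt / p$tau_r))
  out[tt < 0] <- 0
  out
}

#' Peak time and value of the local calcium kernel
#'
#' The kernel peaks at `t* = tau_l + tau_d tau_r/(tau_d - tau_r) *
#' log(tau_d/tau_r)`; [local_ca_peak()] returns the kernel value there
#' (about 0.983 at the default constants).
#'
#' @param p a [cn_local_ca_params()].
#' @return peak time (s) / peak value.
#' @export
local_ca_peak_time <- function(p = cn_local_ca_params()) {
  p$tau_l + p$tau_d * p$tau_r / (p$tau_d - p$tau_r) * log(p$tau_d / p$tau_r)
}

#' @rdname local_ca_peak_time
#' @export
local_ca_peak <- function(p = cn_local_ca_params()) {
  local_ca_kernel(local_ca_peak_time(p), p)
}

#' Subsynaptic local calcium activity over a time grid
#'
#' Superimposes the single-spike kernel for every presynaptic spike,
#' subtracts the supralinearity offset (`offset_frac` of the single-pulse
#' peak) and rectifies at zero:
#' `A_loc(t) = max(sum_k kernel(t - t_k) - offset, 0)`. A single spike
#' therefore clears the offset only briefly around the kernel peak, while a
#' high-frequency burst produces a supralinearly growing activity.
#'
#' @param spikes sorted spike times (s).
#' @param t_grid evaluation times (s).
#' @param p a [cn_local_ca_params()].
#' @return activity series on `t_grid`.
#' @export
local_ca_activity <- function(spikes, t_grid, p = cn_local_ca_params()) {
  if (is.unsorted(spikes)) stop("spikes must be sorted")
  acc <- numeric(length(t_grid))
  for (ts in spikes) acc <- acc + local_ca_kernel(t_grid - ts, p)
  pmax(acc - p$offset_frac * local_ca_peak(p), 0)
}
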