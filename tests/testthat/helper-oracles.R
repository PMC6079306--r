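# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations.

# Victor-Purpura distance by exhaustive enumeration of monotone matchings:
# every spike is either matched (cost q*|dt|) or inserted/deleted (cost 1).
vp_brute <- function(a, b, q) {
  n <- length(a); m <- length(b)
  best <- n + m
  match_cost <- function(ia, ib) {
    # ia, ib: index vectors of equal length, strictly increasing (monotone)
    q * sum(abs(a[ia] - b[ib])) + (n - length(ia)) + (m - length(ib))
  }
  k_max <- min(n, m)
  for (k in 0:k_max) {
    ia_sets <- if (k == 0) list(integer(0)) else
      asplit(combn(n, k), 2)
    ib_sets <- if (k == 0) list(integer(0)) else
      asplit(combn(m, k), 2)
    for (ia in ia_sets) for (ib in ib_sets) {
      best <- min(best, match_cost(as.integer(ia), as.integer(ib)))
    }
  }
  best
}

# Minimal EIF simulator (no LVA/CAP), same spike convention as the CN model;
# written independently as a plain R loop.
eif_reference <- function(amp, params, dt = 1e-4, duration = 1) {
  V <- params$E_L
  V_init <- params$V_t
  armed <- TRUE
  refr <- 0
  nsp <- 0
  refr_steps <- round(params$refractory / dt)
  for (i in seq_len(round(duration / dt))) {
    I_spk <- params$g_L * params$Delta_T *
      exp(min((V - params$V_t) / params$Delta_T, 20))
    V_inf <- (params$g_L * params$E_L + I_spk + amp) / params$g_L
    V_new <- V_inf + (V - V_inf) * exp(-params$g_L * dt / params$C_m)
    dV <- (V_new - V) / dt
    if (refr > 0) {
      V_new <- V_init
      refr <- refr - 1
    } else if (armed && dV >= params$spike_detect_slope) {
      nsp <- nsp + 1
      V_init <- min(V, params$V_t)
      V_new <- V_init
      armed <- FALSE
      refr <- refr_steps
    } else if (V_new >= params$V_t + 10 * params$Delta_T) {
      nsp <- nsp + 1
      V_new <- V_init
      armed <- FALSE
      refr <- refr_steps
    } else if (dV < params$spike_detect_slope) armed <- TRUE
    V <- V_new
  }
  nsp
}

# Self-consistent resting potential of the full model: gates at their
# voltage equilibria, calcium at its influx-balanced equilibrium.
cn_rest_oracle <- function(p) {
  net_current <- function(V) {
    xa <- 1 / (1 + exp((p$p_Ca_a_1 - V) / p$p_Ca_a_2))
    xi <- 1 - 1 / (1 + exp((p$p_Ca_i_1 - V) / p$p_Ca_i_2))
    xkvm <- 1 / (1 + exp((p$p_KVm_1 - V) / p$p_KVm_2))
    influx <- p$B_Ca * p$g_Ca * xa^3 * xi * (p$E_Ca - V)
    Ca <- p$Ca_rest + influx * p$tau_Ca_conc
    xkca <- 1 / (1 + exp((p$p_KCa_1 - Ca) / p$p_KCa_2))
    -p$g_L * (V - p$E_L) +
      p$g_L * p$Delta_T * exp((V - p$V_t) / p$Delta_T) -
      p$g_Ca * xa^3 * xi * (V - p$E_Ca) -
      p$g_K * xkca^4 * xkvm^4 * (V - p$E_K)
  }
  uniroot(net_current, c(-0.075, -0.058), tol = 1e-12)$root
}

# Six-step current protocol spike counts for a given parameter set.
step_counts <- function(params, amps = c(100, 200, 300, 400, 600, 800) * 1e-12,
                        dt = 1e-4, pre = 0.05, dur = 0.1, post = 0.15) {
  vapply(amps, function(amp) {
    n <- round((pre + dur + post) / dt)
    I <- numeric(n)
    I[seq(round(pre / dt) + 1, round((pre + dur) / dt))] <- amp
    length(cn_integrate(NULL, pre + dur + post, dt = dt, I_ext = I,
                        record = FALSE)$spike_times)
  }, numeric(1))
}

# Small Poisson spike train on [0, dur]
rpois_train <- function(rate, dur) sort(runif(rpois(1, rate * dur), 0, dur))
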