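#' Homeostatic synaptic-equilibrium gain (Syn_EQ)
#'
#' Dual-slope linear gain on the learning threshold that keeps the total
#' excitatory weight near its set point (10 by default): equal to 1 at the
#' set point, rising with slope 0.12 above it and falling with slope 0.04
#' below it (floored at 0). Above the set point the threshold grows, biasing
#' updates toward depression, and vice versa.
#'
#' @param sum_wexc total excitatory synaptic weight (>= 0), vectorized.
#' @param cfg a [cn_plasticity_config()].
#' @return gain (dimensionless, >= 0).
#' @export
syn_eq <- function(sum_wexc, cfg = cn_plasticity_config()) {
  if (any(sum_wexc < 0)) stop("sum_wexc must be >= 0")
  d <- sum_wexc - cfg$setpoint_sum_wexc
  pmax(1 + ifelse(d > 0, cfg$slope_above, cfg$slope_below) * d, 0)
}

#' Learning threshold
#'
#' Product of the moving-average total calcium activity and the Syn_EQ gain.
#' Total activity above the threshold puts the neuron in the potentiation
#' ("positive") zone, below it in the depression ("negative") zone.
#'
#' @param atot_avg moving-average total calcium activity (>= 0).
#' @param sum_wexc current total excitatory weight.
#' @param cfg a [cn_plasticity_config()].
#' @return threshold, in total-activity units.
#' @export
learning_threshold <- function(atot_avg, sum_wexc, cfg = cn_plasticity_config()) {
  if (any(atot_avg < 0)) stop("atot_avg must be >= 0")
  atot_avg * syn_eq(sum_wexc, cfg)
}

#' Synaptic weight compensation
#'
#' Sigmoid multiplier modelling that receptor-channel insertion becomes less
#' likely the more channels are already inserted, and removal less likely
#' the fewer remain: for potentiation `K = 1 - S((w - m)/s)`, for depression
#' `K = S((w - m)/s)` with `S` the logistic function, midpoint `m` and
#' steepness `s`. Both branches equal 0.5 at the midpoint and satisfy
#' `K_dep(w) = 1 - K_pot(w)`.
#'
#' @param w synaptic weight in `[0.001, 1]`, vectorized.
#' @param drive_sign `+1` (or `"+"`) for potentiation, `-1` (or `"-"`) for
#'   depression.
#' @param cfg a [cn_plasticity_config()].
#' @return multiplier in `(0, 1)`.
#' @export
weight_compensation <- function(w, drive_sign, cfg = cn_plasticity_config()) {
  if (is.character(drive_sign))
    drive_sign <- ifelse(drive_sign == "-", -1, 1)
  s <- 1 / (1 + exp(-(w - cfg$comp_midpoint) / cfg$comp_steepness))
  ifelse(drive_sign >= 0, 1 - s, s)
}

#' Excitatory weight update for one synapse
#'
#' Integrates the net learning drive over the presentation,
#' `wc = integral (A_tot(t) - threshold) * A_loc(t) dt`, multiplies by the
#' learning rate `eta` and the weight-compensation factor for the drive's
#' sign, and clips the updated weight to `[w_min, w_max]`.
#'
#' @param atot_series total calcium activity series.
#' @param aloc_series per-synapse local calcium activity on the same grid.
#' @param threshold learning threshold (see [learning_threshold()]).
#' @param w current weight.
#' @param dt grid step (s).
#' @param cfg a [cn_plasticity_config()].
#' @return list with `wc` (raw drive integral), `dw` (applied change) and
#'   `w` (updated, clipped weight).
#' @export
excitatory_update <- function(atot_series, aloc_series, threshold, w, dt,
                              cfg = cn_plasticity_config()) {
  if (length(atot_series) != length(aloc_series))
    stop("activity series must share one time grid")
  wc <- sum((atot_series - threshold) * aloc_series) * dt
  dw <- cfg$eta * wc * weight_compensation(w, sign(wc), cfg)
  list(wc = wc, dw = dw, w = min(max(w + dw, cfg$w_min), cfg$w_max))
}

#' Calcium spike rate
#'
#' Counts upward crossings of the total calcium activity above
#' `cfg$ca_rate_threshold` and divides by the duration. A counted "calcium
#' spike" therefore corresponds to one burst-level calcium transient.
#'
#' @param x a `voltage_trace` (its recorded `A_tot` series is used) or a
#'   numeric activity series.
#' @param duration window length (s); taken from the trace if missing.
#' @param cfg a [cn_plasticity_config()].
#' @return rate (Hz).
#' @export
calcium_spike_rate <- function(x, duration = NULL, cfg = cn_plasticity_config()) {
  if (inherits(x, "voltage_trace")) {
    if (is.null(duration)) duration <- x$duration
    if (is.null(x$A_tot)) return(x$ca_crossings / duration)
    x <- x$A_tot
  }
  if (is.null(duration) || duration <= 0) stop("duration must be > 0")
  above <- x >= cfg$ca_rate_threshold
  sum(above[-1] & !above[-length(above)]) / duration
}

#' Inhibitory weight change
#'
#' Dual-slope piecewise-linear homeostatic rule for the lump inhibitory
#' weight: zero at the calcium-rate set point, reaching `inh_delta_min`
#' (default -0.01) at 0 Hz and `inh_delta_max` (default +0.01) at
#' `inh_rate_max` (default 200 Hz); rates are clamped to that range.
#'
#' @param ca_rate_avg moving-average calcium spike rate (Hz, >= 0), vectorized.
#' @param cfg a [cn_plasticity_config()].
#' @return weight change per presentation.
#' @export
inhibitory_update <- function(ca_rate_avg, cfg = cn_plasticity_config()) {
  if (any(ca_rate_avg < 0)) stop("ca_rate_avg must be >= 0")
  r <- pmin(pmax(ca_rate_avg, 0), cfg$inh_rate_max)
  sp <- cfg$setpoint_ca_rate
  ifelse(r >= sp,
         cfg$inh_delta_max * (r - sp) / (cfg$inh_rate_max - sp),
         cfg$inh_delta_min * (sp - r) / sp)
}
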