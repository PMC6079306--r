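#' Fitting configuration
#'
#' Controls the spike-timing objective and the Nelder-Mead harness used to
#' fit intermediate-dynamics parameters to voltage traces recorded under the
#' six-step current protocol (100 ms steps of 100, 200, 300, 400, 600 and
#' 800 pA).
#'
#' @param free names of the free [cn_neuron_params()] entries.
#' @param lower,upper named bounds for the free parameters (enforced by
#'   reflection).
#' @param omega_s weight punishing spike-count mismatches (dimensionless
#'   multiplier on the timing error).
#' @param step_amps protocol current amplitudes (A).
#' @param step_dur current step duration (s).
#' @param pre,post baseline before and tail after each step (s).
#' @param dt integration step (s).
#' @param maxit Nelder-Mead iteration cap per stage.
#' @param reltol simplex relative tolerance.
#' @param et_floor floor on the timing error in the count-mismatch branch of
#'   the objective (squared seconds), preventing a degenerate zero.
#' @return an object of class `cn_fit_config`.
#' @export
cn_fit_config <- function(free = "g_Ca", lower = NULL, upper = NULL,
                          omega_s = 1000,
                          step_amps = c(100, 200, 300, 400, 600, 800) * 1e-12,
                          step_dur = 0.1, pre = 0.05, post = 0.15,
                          dt = 1e-4, maxit = 200, reltol = 1e-6,
                          et_floor = 1e-6) {
  if (omega_s < 0) stop("omega_s must be >= 0")
  if (is.null(lower)) lower <- setNames(rep(0, length(free)), free)
  if (is.null(upper)) upper <- setNames(rep(Inf, length(free)), free)
  structure(list(free = free, lower = lower, upper = upper,
                 omega_s = omega_s, step_amps = step_amps,
                 step_dur = step_dur, pre = pre, post = post, dt = dt,
                 maxit = maxit, reltol = reltol, et_floor = et_floor),
            class = "cn_fit_config")
}

#' Total spike-timing error between measured and simulated spike sets
#'
#' For each current step, sums over the larger of the two spike sets the
#' squared distance from each spike to its nearest neighbour in the other
#' set, and adds the per-step sums. Units: squared time, in the units of the
#' input spike times. A pair in which the smaller set is empty contributes
#' zero (the count penalty of [fit_objective()] handles it).
#'
#' @param T_meas,T_sim lists of sorted spike-time vectors, one per step.
#' @return non-negative timing error.
#' @export
spike_time_error <- function(T_meas, T_sim) {
  if (length(T_meas) != length(T_sim)) stop("step lists must align")
  tot <- 0
  for (k in seq_along(T_meas)) {
    a <- T_meas[[k]]; b <- T_sim[[k]]
    if (length(a) >= length(b)) { big <- a; small <- b } else { big <- b; small <- a }
    if (length(small) == 0 || length(big) == 0) next
    tot <- tot + sum(vapply(big, function(t) min((t - small)^2), numeric(1)))
  }
  tot
}

#' Spike-timing objective with count-mismatch penalty
#'
#' Equal spike counts on every step: the objective is the timing error
#' alone. Any count mismatch: the timing error (floored at `et_floor`) is
#' multiplied by `omega_s` times the summed squared count differences over
#' the mismatched steps.
#'
#' @param T_meas,T_sim lists of spike-time vectors per step.
#' @param cfg a [cn_fit_config()].
#' @return objective value.
#' @export
fit_objective <- function(T_meas, T_sim, cfg = cn_fit_config()) {
  et <- spike_time_error(T_meas, T_sim)
  dc <- vapply(seq_along(T_meas),
               function(k) length(T_sim[[k]]) - length(T_meas[[k]]), numeric(1))
  if (all(dc == 0)) return(et)
  max(et, cfg$et_floor) * cfg$omega_s * sum(dc[dc != 0]^2)
}

#' Trace discrepancy with spikes masked
#'
#' Mean squared voltage difference between a simulated and a measured trace,
#' excluding samples within `mask` seconds of any spike in either trace
#' (spike shapes are not informative for the subthreshold dynamics being
#' fitted). Traces on different grids are resampled with a warning.
#'
#' @param sim,meas `voltage_trace` objects (recorded).
#' @param mask half-width of the spike mask (s).
#' @return mean squared difference (V^2).
#' @export
trace_discrepancy <- function(sim, meas, mask = 2e-3) {
  vs <- sim$V_m; vm <- meas$V_m
  if (is.null(vs) || is.null(vm)) stop("traces must be recorded")
  if (length(vs) != length(vm) || abs(sim$dt - meas$dt) > 1e-12) {
    warning("trace grids differ; resampling simulated trace")
    vs <- stats::approx(sim$time, vs, xout = meas$time, rule = 2)$y
  }
  t <- meas$time
  keep <- rep(TRUE, length(t))
  for (ts in c(sim$spike_times, meas$spike_times))
    keep <- keep & (abs(t - ts) > mask)
  if (!any(keep)) return(0)
  mean((vs[keep] - vm[keep])^2)
}

# simulate the six-step current protocol, returning recorded traces
.simulate_protocol <- function(params, cfg) {
  dur <- cfg$pre + cfg$step_dur + cfg$post
  nst <- round(dur / cfg$dt)
  lapply(cfg$step_amps, function(amp) {
    I <- numeric(nst)
    I[seq(round(cfg$pre / cfg$dt) + 1, round((cfg$pre + cfg$step_dur) / cfg$dt))] <- amp
    cn_integrate(NULL, dur, dt = cfg$dt, params = params, I_ext = I,
                 record = TRUE)
  })
}

#' Simulate the six-step current protocol
#'
#' Runs the CN model through the standard characterization protocol: six
#' 100 ms current steps at 100-800 pA, each with baseline before and a tail
#' after, returning the recorded voltage traces.
#'
#' @param params a [cn_neuron_params()].
#' @param cfg a [cn_fit_config()].
#' @return list of `voltage_trace`s, one per step.
#' @export
simulate_step_protocol <- function(params = cn_neuron_params(),
                                   cfg = cn_fit_config()) {
  .simulate_protocol(params, cfg)
}

# reflect a value into [lo, hi] (triangular fold)
.reflect <- function(x, lo, hi) {
  if (!is.finite(hi)) return(pmax(x, lo))
  r <- (x - lo) / (hi - lo)
  r <- abs(r %% 2)
  r <- ifelse(r > 1, 2 - r, r)
  lo + r * (hi - lo)
}

#' Fit intermediate-dynamics parameters to measured traces
#'
#' Two-stage Nelder-Mead scheme starting from user-supplied initial
#' parameters: stage one minimizes the spike-masked trace discrepancy
#' summed over the six current steps; stage two minimizes the spike-timing
#' objective ([fit_objective()]). Bounds on the free parameters are
#' enforced by reflection. Deterministic given the initial parameters.
#'
#' @param init a [cn_neuron_params()] starting point.
#' @param measured list of measured `voltage_trace`s, one per protocol step
#'   (e.g. from [simulate_step_protocol()] with the generating parameters).
#' @param cfg a [cn_fit_config()].
#' @param stages which objective stages to run, in order: `"trace"` and/or
#'   `"timing"`.
#' @return list with `params` (fitted [cn_neuron_params()]), `value` (final
#'   objective), `trajectory` (objective value per evaluation),
#'   `converged`.
#' @export
fit_cn_parameters <- function(init, measured, cfg = cn_fit_config(),
                              stages = c("trace", "timing")) {
  if (length(measured) != length(cfg$step_amps))
    stop("measured traces must cover the ", length(cfg$step_amps),
         "-step protocol")
  free <- cfg$free
  theta0 <- unlist(init[free])
  meas_spikes <- lapply(measured, `[[`, "spike_times")
  traj <- numeric(0)
  make_obj <- function(stage) {
    function(theta) {
      p <- init
      for (i in seq_along(free))
        p[[free[i]]] <- unname(.reflect(theta[i], cfg$lower[[free[i]]],
                                        cfg$upper[[free[i]]]))
      sims <- tryCatch(.simulate_protocol(p, cfg), error = function(e) NULL)
      v <- if (is.null(sims)) 1e12
      else if (stage == "trace")
        sum(vapply(seq_along(sims), function(k)
          trace_discrepancy(sims[[k]], measured[[k]]), numeric(1)))
      else fit_objective(meas_spikes, lapply(sims, `[[`, "spike_times"), cfg)
      traj <<- c(traj, v)
      v
    }
  }
  theta <- theta0
  converged <- TRUE
  for (stage in stages) {
    obj <- make_obj(if (stage == "trace") "trace" else "timing")
    res <- if (length(theta) == 1) {
      stats::optim(theta, obj, method = "Nelder-Mead",
                   control = list(maxit = cfg$maxit, reltol = cfg$reltol,
                                  warn.1d.NelderMead = FALSE))
    } else {
      stats::optim(theta, obj, method = "Nelder-Mead",
                   control = list(maxit = cfg$maxit, reltol = cfg$reltol))
    }
    theta <- res$par
    if (res$convergence != 0) converged <- FALSE
  }
  fitted <- init
  for (i in seq_along(free))
    fitted[[free[i]]] <- unname(.reflect(theta[i], cfg$lower[[free[i]]],
                                         cfg$upper[[free[i]]]))
  list(params = fitted, value = traj[length(traj)], trajectory = traj,
       converged = converged)
}
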