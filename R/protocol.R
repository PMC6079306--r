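#' Learning-run configuration
#'
#' Bundles the knobs of a full learning run. Intrinsic-parameter choices
#' (`g_max`, `setpoint_ca_rate`, `local_scale_pct`, `sw_spread`) correspond
#' to the intrinsic CN parameter grid of the model; the defaults are the
#' base configuration.
#'
#' @param n_presentations number of stimulus presentations (1500 in the full
#'   protocol; scaled-down runs are routinely used).
#' @param order_policy `"pseudo-random"` (seeded shuffle of a balanced
#'   multiset) or `"sequential"`.
#' @param seed_weight_id which pseudo-randomized seed-weight vector (1-5).
#' @param sw_spread seed-weight spread change in percent (0 to -80).
#' @param g_max maximum synaptic conductance constant (S).
#' @param setpoint_ca_rate calcium spike-rate set point (Hz).
#' @param local_scale_pct local calcium time-constant scaling (percent).
#' @param master_seed master RNG seed; every stochastic element of the run
#'   (presentation order, spike jitter) flows from it.
#' @param dt integration step (s).
#' @param jitter_sd spike-time jitter (s).
#' @param eta learning-rate constant (see [cn_plasticity_config()]).
#' @param w_inh_init initial lump inhibitory weight.
#' @param supralinearity `FALSE` switches to the ablated model: no local
#'   calcium offset, total activity = plain sum of local activities,
#'   intermediate dynamics bypassed as the learning signal.
#' @param abl_ca_rate_threshold,abl_eta_scale calcium-spike threshold and
#'   learning-rate rescaling used in the ablated mode, whose activity signal
#'   lives on a different scale than the calcium concentration.
#' @param checkpoint_every store a weight/RNG snapshot every this many
#'   presentations.
#' @param neuron_overrides named list of [cn_neuron_params()] overrides for
#'   this run (e.g. `list(g_Ca = 0)`).
#' @return an object of class `cn_run_config`.
#' @export
cn_run_config <- function(n_presentations = 1500,
                          order_policy = c("pseudo-random", "sequential"),
                          seed_weight_id = 1, sw_spread = 0,
                          g_max = 23e-8, setpoint_ca_rate = 20,
                          local_scale_pct = 100, master_seed = 1,
                          dt = 1e-4, jitter_sd = 5e-3, eta = NULL,
                          w_inh_init = 0.5, supralinearity = TRUE,
                          abl_ca_rate_threshold = 20, abl_eta_scale = 3e-10,
                          checkpoint_every = 100, neuron_overrides = list()) {
  order_policy <- match.arg(order_policy)
  if (n_presentations < 0) stop("n_presentations must be >= 0")
  structure(list(n_presentations = n_presentations, order_policy = order_policy,
                 seed_weight_id = seed_weight_id, sw_spread = sw_spread,
                 g_max = parse_quantity(g_max),
                 setpoint_ca_rate = setpoint_ca_rate,
                 local_scale_pct = local_scale_pct, master_seed = master_seed,
                 dt = dt, jitter_sd = parse_quantity(jitter_sd), eta = eta,
                 w_inh_init = w_inh_init, supralinearity = supralinearity,
                 abl_ca_rate_threshold = abl_ca_rate_threshold,
                 abl_eta_scale = abl_eta_scale,
                 checkpoint_every = checkpoint_every,
                 neuron_overrides = neuron_overrides),
            class = "cn_run_config")
}

#' Pseudo-randomized seed weights
#'
#' Draws the initial excitatory weight vector from a normal distribution
#' (mean 0.125, so 80 synapses start near the total-weight set point of 10)
#' clipped to `[0.001, 0.5]`. `seed_id` selects one of the reproducible
#' "Seed weights 1-5" vectors: the same id always yields the same vector.
#' `spread_pct` shrinks the spread (e.g. -80 gives one fifth of the base
#' standard deviation of 0.08).
#'
#' @param n number of synapses.
#' @param seed_id seed-weight configuration id.
#' @param spread_pct percentage change of the spread (0 to -80).
#' @param rng_seed optional explicit seed overriding the id-derived one.
#' @return weight vector in `[0.001, 0.5]`.
#' @export
make_seed_weights <- function(n = 80, seed_id = 1, spread_pct = 0,
                              rng_seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  seed <- if (is.null(rng_seed)) 5000L + as.integer(seed_id) else rng_seed
  rs <- .new_rng_state(seed)
  on.exit(.restore_rng_state(rs))
  sdv <- 0.08 * (1 + spread_pct / 100)
  pmin(pmax(rnorm(n, mean = 0.125, sd = sdv), 0.001), 0.5)
}

# internal learning engine shared by run_learning / run_monotypic
.learning_engine <- function(cfg, stim_set, order) {
  stimuli <- stim_set$stimuli
  n_exc <- length(stimuli[[1]]$trains)
  duration <- stimuli[[1]]$duration
  params <- do.call(cn_neuron_params, as.list(cfg$neuron_overrides))
  local <- cn_local_ca_params(scale_pct = cfg$local_scale_pct,
                              offset_frac = if (cfg$supralinearity) 0.75 else 0)
  pcfg <- cn_plasticity_config(setpoint_ca_rate = cfg$setpoint_ca_rate,
                               eta = if (is.null(cfg$eta)) 1.2e8 else cfg$eta)
  if (!cfg$supralinearity) {
    pcfg$ca_rate_threshold <- cfg$abl_ca_rate_threshold
    pcfg$eta <- pcfg$eta * cfg$abl_eta_scale
  }
  atot_mode <- if (cfg$supralinearity) "calcium" else "sum_aloc"
  w <- make_seed_weights(n_exc, cfg$seed_weight_id, cfg$sw_spread)
  w_inh <- cfg$w_inh_init
  n <- length(order)

  # per-channel spike trains, cached as plain lists
  trains <- lapply(stimuli, `[[`, "trains")

  rs <- .new_rng_state(cfg$master_seed)
  on.exit(.restore_rng_state(rs))

  weights <- matrix(NA_real_, n + 1, n_exc)
  weights[1, ] <- w
  w_inh_series <- numeric(n + 1); w_inh_series[1] <- w_inh
  sum_w <- numeric(n); ca_rate <- numeric(n); thr_series <- numeric(n)
  spars <- numeric(n + 1); spars[1] <- sparseness(w)
  atot_hist <- numeric(0); rate_hist <- numeric(0)
  checkpoints <- list()
  aborted <- NULL

  for (p in seq_len(n)) {
    sid <- order[p]
    tr <- trains[[sid]]
    jt <- lapply(tr, jitter_spikes, sigma = cfg$jitter_sd, window = duration)
    inputs <- list(channel = rep(seq_len(n_exc), lengths(jt)),
                   time = unlist(jt, use.names = FALSE))
    bank <- cn_synapse_bank(w_exc = w, w_inh_total = w_inh,
                            g_max = cfg$g_max)
    sim <- tryCatch(
      cn_integrate(inputs, duration, dt = cfg$dt, params = params,
                   bank = bank, local = local, record = FALSE,
                   atot_mode = atot_mode,
                   ca_rate_threshold = pcfg$ca_rate_threshold,
                   plasticity = TRUE),
      error = function(e) e)
    if (inherits(sim, "error")) {
      aborted <- list(presentation = p, message = conditionMessage(sim))
      warning("learning run aborted at presentation ", p, ": ",
              conditionMessage(sim))
      break
    }
    atot_hist <- tail(c(atot_hist, sim$atot_mean), pcfg$avg_window)
    rate_hist <- tail(c(rate_hist, sim$ca_crossings / duration), pcfg$avg_window)
    thr <- learning_threshold(mean(atot_hist), sum(w), pcfg)
    wc <- sim$int_atot_aloc - thr * sim$int_aloc
    dw <- pcfg$eta * wc * weight_compensation(w, sign(wc), pcfg)
    w <- pmin(pmax(w + dw, pcfg$w_min), pcfg$w_max)
    w_inh <- max(w_inh + inhibitory_update(mean(rate_hist), pcfg), 0)

    weights[p + 1, ] <- w
    w_inh_series[p + 1] <- w_inh
    sum_w[p] <- sum(w)
    ca_rate[p] <- sim$ca_crossings / duration
    thr_series[p] <- thr
    spars[p + 1] <- sparseness(w)
    if (cfg$checkpoint_every > 0 && p %% cfg$checkpoint_every == 0)
      checkpoints[[length(checkpoints) + 1]] <-
        list(presentation = p, w_exc = w, w_inh = w_inh,
             rng = get(".Random.seed", globalenv()))
  }
  done <- if (is.null(aborted)) n else aborted$presentation - 1
  rec <- structure(list(
    config = cfg, n_presentations = done,
    stimulus = order[seq_len(done)],
    weights = weights[seq_len(done + 1), , drop = FALSE],
    w_inh = w_inh_series[seq_len(done + 1)],
    sum_wexc = sum_w[seq_len(done)],
    ca_rate = ca_rate[seq_len(done)],
    threshold = thr_series[seq_len(done)],
    sparseness = spars[seq_len(done + 1)],
    seed_weights = weights[1, ],
    end_weights = weights[done + 1, ],
    checkpoints = checkpoints, aborted = aborted),
    class = "learning_record")
  rec
}

#' Run the diversified learning protocol
#'
#' Presents the stimulus set `n_presentations` times (balanced pseudo-random
#' order by default), jittering every PA spike train independently per
#' presentation, simulating the CN over each stimulus window, and applying
#' the excitatory weight update to every synapse and the inhibitory update
#' once per presentation. The neuron state is reset to rest between
#' presentations; weights and moving averages carry over.
#'
#' @param cfg a [cn_run_config()].
#' @param stim_set a [make_stimulus_set()] object.
#' @return a `learning_record`: per-presentation weight matrix (first row =
#'   seed weights), inhibitory weight, total excitatory weight, calcium
#'   spike rate, learning threshold, sparseness trajectory, plus the seed
#'   and end weight vectors. If the simulation becomes numerically unstable
#'   the partial record is returned with an `aborted` diagnostic.
#' @export
run_learning <- function(cfg, stim_set) {
  k <- length(stim_set$stimuli)
  n <- cfg$n_presentations
  if (n == 0) {
    return(.learning_engine(cfg, stim_set, integer(0)))
  }
  base <- rep(seq_len(k), length.out = n)
  order <- if (cfg$order_policy == "pseudo-random") {
    rs <- .new_rng_state(cfg$master_seed * 7L + 13L)
    on.exit(.restore_rng_state(rs))
    sample(base)
  } else base
  .learning_engine(cfg, stim_set, order)
}

#' Run a monotypic learning schedule
#'
#' Presents stimuli following an explicit schedule (e.g. 150 repetitions of
#' stimulus 1 followed by 150 of stimulus 5), used to probe the dependence
#' of the learnt weight landscape on the type and order of sensory
#' experience.
#'
#' @param cfg a [cn_run_config()]; `n_presentations` is taken from the
#'   schedule.
#' @param stim_set a [make_stimulus_set()] object.
#' @param schedule list of `c(stimulus_id, n_reps)` pairs.
#' @return a `learning_record` with `switch_points` marking schedule
#'   boundaries.
#' @export
run_monotypic <- function(cfg, stim_set, schedule) {
  if (length(schedule) == 0) stop("schedule must be non-empty")
  order <- unlist(lapply(schedule, function(s) rep(s[1], s[2])))
  cfg$n_presentations <- length(order)
  rec <- .learning_engine(cfg, stim_set, order)
  rec$switch_points <- cumsum(vapply(schedule, `[`, numeric(1), 2))
  rec
}

#' @export
print.learning_record <- function(x, ...) {
  cat("<learning_record> ", x$n_presentations, "presentations,",
      ncol(x$weights), "synapses; final sum(w_exc) =",
      round(sum(x$end_weights), 3), "; sparseness",
      round(x$sparseness[1], 3), "->",
      round(x$sparseness[length(x$sparseness)], 3), "\n")
  if (!is.null(x$aborted)) cat("  [aborted: ", x$aborted$message, "]\n")
  invisible(x)
}

#' Winner and loser synapses of a learning record
#'
#' Winners are the `k` synapses with the highest end weights; losers are the
#' `k` synapses with the highest seed weights among those not ending up as
#' winners (high seed weight, low end weight).
#'
#' @param record a `learning_record`.
#' @param k group size (default 10).
#' @return list with integer vectors `winners` and `losers`.
#' @export
weight_groups <- function(record, k = 10) {
  n <- length(record$end_weights)
  k <- min(k, floor(n / 2))
  winners <- order(record$end_weights, decreasing = TRUE)[seq_len(k)]
  rest <- setdiff(order(record$seed_weights, decreasing = TRUE), winners)
  list(winners = winners, losers = rest[seq_len(k)])
}

#' Sweep an intrinsic CN parameter over the learning process
#'
#' Runs the full learning protocol for every value in `values` of one
#' intrinsic parameter (`g_max`, `setpoint_ca_rate`, `local_scale_pct` or
#' `sw_spread`), `repeats` times each with fresh spike jitter, and
#' summarizes the end-weight landscapes.
#'
#' @param cfg base [cn_run_config()].
#' @param stim_set a [make_stimulus_set()] object.
#' @param parameter name of the swept configuration field.
#' @param values vector of parameter values.
#' @param repeats repetitions per value (fresh jitter via distinct master
#'   seeds derived from `cfg$master_seed`).
#' @param keep_records keep the individual `learning_record`s.
#' @return list with `summary` (one row per value: mean end-to-seed
#'   distance, across-repeat end-weight standard deviation), `end_weights`
#'   (array value x repeat x synapse) and optionally `records`.
#' @export
sweep_intrinsic <- function(cfg, stim_set, parameter = "g_max",
                            values, repeats = 5, keep_records = FALSE) {
  if (!parameter %in% names(cfg)) stop("unknown configuration field: ", parameter)
  n_exc <- length(stim_set$stimuli[[1]]$trains)
  ew <- array(NA_real_, c(length(values), repeats, n_exc))
  records <- list()
  rows <- list()
  for (vi in seq_along(values)) {
    for (r in seq_len(repeats)) {
      ci <- cfg
      ci[[parameter]] <- values[vi]
      ci$master_seed <- cfg$master_seed + 1000L * r
      rec <- run_learning(ci, stim_set)
      ew[vi, r, ] <- rec$end_weights
      if (keep_records) records[[paste(vi, r, sep = "_")]] <- rec
    }
    m <- matrix(ew[vi, , ], nrow = repeats)
    seedw <- make_seed_weights(n_exc, cfg$seed_weight_id, cfg$sw_spread)
    rows[[vi]] <- data.frame(
      parameter = parameter, value = values[vi],
      mean_dist_to_seed = mean(apply(m, 1, function(x) sqrt(sum((x - seedw)^2)))),
      across_repeat_sd = if (repeats > 1) mean(apply(m, 2, sd)) else NA_real_)
  }
  out <- list(summary = do.call(rbind, rows), end_weights = ew,
              values = values, parameter = parameter)
  if (keep_records) out$records <- records
  out
}
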