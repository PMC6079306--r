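#' Load a configuration bundle
#'
#' Reads a YAML configuration with sections `neuron`, `synapses`,
#' `local_ca`, `plasticity`, `run` and `fit` (all optional; an empty file
#' yields the full default bundle). Values may carry unit suffixes
#' (`"23e-8 S"`, `"6.4 ms"`, `"-400 pA"`); everything is converted to SI.
#' Unknown keys are rejected with the offending names listed.
#'
#' @param path YAML file path.
#' @return an object of class `cn_config_bundle` with elements `neuron`,
#'   `synapses`, `local_ca`, `plasticity`, `run`, `fit`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("neuron", "synapses", "local_ca", "plasticity", "run", "fit")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  sect <- function(nm) if (is.null(raw[[nm]])) list() else raw[[nm]]
  mk <- function(ctor, args) {
    # numeric-with-unit strings become SI numbers; other strings (e.g. an
    # order policy) pass through untouched
    args <- lapply(args, function(a) {
      if (is.character(a))
        tryCatch(parse_quantity(a), error = function(e) a)
      else a
    })
    do.call(ctor, args)
  }
  bundle <- list(
    neuron = mk(cn_neuron_params, sect("neuron")),
    synapses = mk(cn_synapse_bank, sect("synapses")),
    local_ca = mk(cn_local_ca_params, sect("local_ca")),
    plasticity = mk(cn_plasticity_config, sect("plasticity")),
    run = mk(cn_run_config, sect("run")),
    fit = mk(cn_fit_config, sect("fit"))
  )
  structure(bundle, class = "cn_config_bundle", path = path)
}

#' Save a configuration bundle
#'
#' Writes the bundle back to YAML (SI values, no unit suffixes); a
#' round-trip through [load_config()] reproduces the bundle.
#'
#' @param bundle a `cn_config_bundle`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(bundle, path) {
  out <- lapply(bundle, function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization; changes iff the configuration
#' changes.
#'
#' @param cfg any serializable configuration object.
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.num_fmt <- function(x) formatC(x, digits = 17, format = "g")

#' Save a learning record
#'
#' Writes `weights.csv` (per-presentation weight matrix, first row = seed
#' weights), `trajectory.csv` (stimulus id, total excitatory weight,
#' calcium spike rate, learning threshold, sparseness, inhibitory weight)
#' and `manifest.json` (configuration, its hash, seeds, package version,
#' abort flag). Values are written with 17 significant digits so
#' [load_record()] reproduces the record exactly.
#'
#' @param record a `learning_record`.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
save_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- record$weights
  wdf <- as.data.frame(apply(w, 2, .num_fmt))
  names(wdf) <- paste0("w", seq_len(ncol(w)))
  write.csv(cbind(presentation = 0:(nrow(w) - 1), wdf),
            file.path(dir, "weights.csv"), row.names = FALSE, quote = FALSE)
  n <- record$n_presentations
  traj <- data.frame(
    presentation = seq_len(n),
    stimulus = record$stimulus,
    sum_wexc = .num_fmt(record$sum_wexc),
    ca_rate = .num_fmt(record$ca_rate),
    threshold = .num_fmt(record$threshold),
    sparseness = .num_fmt(record$sparseness[-1]),
    w_inh = .num_fmt(record$w_inh[-1]))
  write.csv(traj, file.path(dir, "trajectory.csv"), row.names = FALSE,
            quote = FALSE)
  manifest <- list(
    config = unclass(record$config),
    config_hash = config_hash(record$config),
    n_presentations = n,
    n_synapses = ncol(w),
    package_version = as.character(utils::packageVersion("cuneate")),
    aborted = !is.null(record$aborted),
    abort_info = record$aborted)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Load a learning record saved by [save_record()]
#'
#' @param dir directory written by [save_record()].
#' @return a `learning_record` (weights, trajectory, config and seeds
#'   restored; checkpoints are not persisted).
#' @export
load_record <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  w <- as.matrix(read.csv(file.path(dir, "weights.csv"))[, -1, drop = FALSE])
  dimnames(w) <- NULL
  traj <- read.csv(file.path(dir, "trajectory.csv"))
  cfg <- structure(man$config, class = "cn_run_config")
  structure(list(
    config = cfg, n_presentations = man$n_presentations,
    stimulus = traj$stimulus,
    weights = w,
    w_inh = c(cfg$w_inh_init, traj$w_inh),
    sum_wexc = traj$sum_wexc,
    ca_rate = traj$ca_rate,
    threshold = traj$threshold,
    sparseness = c(sparseness(w[1, ]), traj$sparseness),
    seed_weights = w[1, ],
    end_weights = w[nrow(w), ],
    checkpoints = list(),
    aborted = if (isTRUE(man$aborted)) man$abort_info else NULL),
    class = "learning_record")
}

#' Export a voltage trace
#'
#' Tabular text (`time_s, Vm_V, Ca_conc`) plus the spike-time list as JSON.
#'
#' @param trace a recorded `voltage_trace`.
#' @param path CSV path; the spike list goes to `<path>.spikes.json`.
#' @return `path`, invisibly.
#' @export
save_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  df[] <- lapply(df, .num_fmt)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(trace$spike_times, paste0(path, ".spikes.json"),
                       digits = NA)
  invisible(path)
}

#' Export a stimulus set as tabular spike files
#'
#' One CSV per stimulus (`channel_id, spike_time_s`) plus a JSON manifest
#' with labels, durations, provenance and the channel map.
#'
#' @param stim_set a `stimulus_set`.
#' @param dir output directory.
#' @return manifest path, invisibly.
#' @export
save_stimulus_set <- function(stim_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(stim_set$stimuli)) {
    st <- stim_set$stimuli[[i]]
    df <- data.frame(
      channel_id = rep(seq_along(st$trains), lengths(st$trains)),
      spike_time_s = .num_fmt(unlist(st$trains, use.names = FALSE)))
    f <- file.path(dir, paste0("stimulus_", i, "_", st$label, ".csv"))
    write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(
    kind = stim_set$kind,
    labels = vapply(stim_set$stimuli, `[[`, character(1), "label"),
    durations = vapply(stim_set$stimuli, `[[`, numeric(1), "duration"),
    files = files,
    provenance = stim_set$provenance,
    channel_map = stim_set$stimuli[[1]]$channel_map)
  mf <- file.path(dir, "stimulus_set.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(mf)
}

#' Load spike trains from a tabular file
#'
#' Reads `channel_id, spike_time_s` CSV (as written by
#' [save_stimulus_set()]) into a list of spike trains.
#'
#' @param path CSV path.
#' @param n_channels total channel count (defaults to the maximum id).
#' @return list of sorted spike-time vectors.
#' @export
load_spike_trains <- function(path, n_channels = NULL) {
  df <- read.csv(path)
  if (is.null(n_channels)) n_channels <- max(df$channel_id)
  lapply(seq_len(n_channels), function(ch)
    sort(df$spike_time_s[df$channel_id == ch]))
}

#' Small deterministic fixture set for fast tests
#'
#' A 2-stimulus, 8-channel, 200 ms stimulus set (two sensors, one
#' repetition, both signals and presets) plus a tiny run configuration.
#'
#' @param seed integer seed.
#' @return list with `stim_set` and `run_config`.
#' @export
make_fixtures <- function(seed = 1) {
  duration <- 0.2; fs <- 1000
  specs <- list(
    list(label = "fix-texture", class = "texture-slide", ridge_freq = 30),
    list(label = "fix-indent", class = "indentation",
         rise_time = 0.03, shape_width = 0.6))
  stimuli <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    pars <- sp[setdiff(names(sp), c("label", "class"))]
    pars$duration <- duration; pars$fs <- fs
    wf <- synth_analog_stimuli(sp$class, pars, seed = seed * 31 + i)
    mx <- multiplex_to_80(wf, repeats = 1, fs = fs, seed = seed * 53 + i)
    keep <- mx$channel_map$sensor <= 2
    trains <- mx$trains[keep]
    map <- mx$channel_map[keep, ]
    map$channel <- seq_along(trains)
    list(label = sp$label, class = sp$class, duration = duration,
         trains = trains, channel_map = map)
  })
  stim_set <- structure(list(stimuli = stimuli, kind = "fixture",
                             provenance = list(seed = seed, duration = duration,
                                               fs = fs, repeats = 1)),
                        class = "stimulus_set")
  list(stim_set = stim_set,
       run_config = cn_run_config(n_presentations = 20, master_seed = seed,
                                  checkpoint_every = 10))
}
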