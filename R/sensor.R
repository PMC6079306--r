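#' Izhikevich encoder parameters
#'
#' Quadratic Izhikevich neuron used to convert the normalized analog output
#' of a fingertip sensor channel into a PA spike train. `A`, `B`, `C` and
#' the 30 mV depolarization threshold are the standard constants of the
#' model; `a`-`d` are the canonical regular-spiking values, giving the
#' spike-frequency adaptation characteristic of mechanoreceptor afferents.
#' Two named presets are provided; "setting-2" halves the input gain, so the
#' same analog signal yields a distinct, sparser spike pattern.
#'
#' @param preset `"setting-1"` or `"setting-2"`.
#' @param ... overrides (`A, B, C, a, b, c, d, spike_threshold, dt,
#'   input_gain, v0`).
#' @return an object of class `izhikevich_params`.
#' @export
izhikevich_params <- function(preset = c("setting-1", "setting-2"), ...) {
  preset <- match.arg(preset)
  p <- list(A = 0.04, B = 5, C = 140, a = 0.02, b = 0.2, c = -65, d = 8,
            spike_threshold = 30,  # mV, fixed in the model definition
            dt = 2.5e-4,           # internal Euler step (s)
            input_gain = if (preset == "setting-1") 14 else 7,
            v0 = -70, preset = preset)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown Izhikevich parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  structure(p, class = "izhikevich_params")
}

#' Encode an analog signal into a spike train
#'
#' Integrates `v' = A v^2 + B v + C - u + I`, `u' = a (b v - u)` with
#' Euler's method, holding the input piecewise-constant over each analog
#' sample. When `v` reaches the 30 mV threshold a spike is emitted and
#' `v <- c`, `u <- u + d`.
#'
#' @param analog current-like input series (already scaled by the input
#'   gain), sampled at `fs`.
#' @param p an [izhikevich_params()] object.
#' @param fs analog sampling rate (Hz).
#' @return sorted spike times (s).
#' @export
izhikevich_encode <- function(analog, p = izhikevich_params(), fs = 1000) {
  if (any(!is.finite(analog))) stop("non-finite analog input")
  cpp_izhikevich(as.numeric(analog), 1 / fs, p$dt,
                 p$A, p$B, p$C, p$a, p$b, p$c, p$d,
                 p$spike_threshold, p$v0, p$b * p$v0)
}

#' Synthetic fingertip sensor waveforms
#'
#' Generates the four analog sensor waveforms of one physical stimulus.
#' Two stimulus classes are emulated:
#' \describe{
#'   \item{`texture-slide`}{indentation ramp and hold, followed by a slide
#'     phase with superimposed periodic ridges at the texture's temporal
#'     frequency; the four sensors share the contact profile but carry the
#'     ridge oscillation with sensor-specific amplitudes and phases.}
#'   \item{`indentation`}{a trapezoidal force profile with shape-specific
#'     rise time; the four sensors are loaded with shape-specific gains.}
#' }
#' The cross-sensor structure is a deterministic function of the stimulus
#' parameters, so different stimuli impose distinct sensor correlation
#' patterns. A small amount of seeded Gaussian noise is added.
#'
#' @param class `"texture-slide"` or `"indentation"`.
#' @param params list of stimulus parameters: `duration` (s), `fs` (Hz),
#'   `amp`, `noise_sd`, plus `ridge_freq` (Hz) for textures or `rise_time`
#'   (s) and `shape_width` (relative, 0-1) for indentations.
#' @param seed integer seed making the waveforms reproducible.
#' @return a 4 x n matrix (rows = sensors), with attributes `fs` and `label`.
#' @export
synth_analog_stimuli <- function(class = c("texture-slide", "indentation"),
                                 params = list(), seed = 1) {
  class <- match.arg(class)
  d <- modifyList(list(duration = 1, fs = 1000, amp = 1, noise_sd = 0.02,
                       ridge_freq = 30, rise_time = 0.05, shape_width = 0.5,
                       dyn_freq = 8, dyn_amp = 0.35),
                  params)
  n <- round(d$duration * d$fs)
  t <- seq_len(n) / d$fs
  w <- matrix(0, 4, n)
  if (d$amp == 0) {
    attr(w, "fs") <- d$fs
    attr(w, "label") <- class
    return(w)
  }
  if (class == "texture-slide") {
    ramp <- pmin(t / (0.15 * d$duration), 1) * 0.6 * d$amp  # contact ramp + hold
    slide <- as.numeric(t >= 0.25 * d$duration)             # slide phase onset
    f <- d$ridge_freq
    for (i in 1:4) {
      gain <- 0.55 + 0.45 * abs(sin(i * 1.7 + f / 11))
      ridge_amp <- 0.3 + 0.15 * abs(cos(i * 0.9 + f / 7))
      phase <- 2 * pi * ((i - 1) / 4 + (f %% 5) / 5)
      # sensor-specific slow contact envelope: as the fingertip slides, each
      # sensor's load waxes and wanes on its own schedule, so channels from
      # one sensor share a macro burst pattern distinct from other sensors'
      f_env <- 1.5 + 0.7 * i
      env <- 0.5 + 0.5 * sin(2 * pi * f_env * t + i * 2.1 + f / 3)^2
      w[i, ] <- gain * ramp +
        slide * env * ridge_amp * d$amp * sin(2 * pi * f * t + phase)
    }
  } else {
    rise <- d$rise_time
    prof <- pmin(pmax((t - 0.1 * d$duration) / rise, 0), 1) *
      pmin(pmax((0.8 * d$duration - t) / (0.05 * d$duration), 0), 1)
    # trapezoid envelope (onset at 10% of the window, release at 80%)
    # modulated by the dynamic indentation oscillation
    for (i in 1:4) {
      # shape_width sets how evenly the shape loads the 2x2 sensor array;
      # the dynamic oscillation reaches each sensor with its own phase and
      # depth, as a shape pressed and rocked against the array would produce
      gain <- d$shape_width + (1 - d$shape_width) * exp(-((i - 2.5)^2) / 2)
      dyn <- 1 + d$dyn_amp * (0.6 + 0.4 * sin(i * 1.3)) *
        sin(2 * pi * d$dyn_freq * t + (i - 1) * pi / 3)
      w[i, ] <- gain * d$amp * prof * dyn
    }
  }
  rs <- .new_rng_state(seed)
  w <- w + matrix(rnorm(4 * n, sd = d$noise_sd * d$amp), 4, n)
  .restore_rng_state(rs)
  attr(w, "fs") <- d$fs
  attr(w, "label") <- class
  w
}

# run code under a temporary RNG seed, restoring the caller's RNG state
.new_rng_state <- function(seed) {
  rs <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  rs
}
.restore_rng_state <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
  invisible(NULL)
}

#' Multiplex four sensor waveforms into 80 PA spike channels
#'
#' Reproduces the fingertip channel expansion: each of the four sensors is
#' "presented" `repeats` times with fresh seeded noise (each repetition is
#' treated as a distinct sensor), each resulting signal is kept raw (SA-like,
#' sustained-level sensitive) and time-differentiated (FA-like, sensitive to
#' dynamic changes), and each of those is encoded with both Izhikevich
#' presets: `4 x 5 x 2 x 2 = 80` spike trains. Channels from sensor k occupy
#' positions `(k-1)*20 + 1 .. k*20`.
#'
#' @param waveforms 4 x n sensor matrix from [synth_analog_stimuli()].
#' @param repeats repetitions per sensor (default 5).
#' @param presets list of the two [izhikevich_params()] settings.
#' @param fs sampling rate (Hz).
#' @param noise_sd per-repetition sensor noise (signal units).
#' @param seed integer seed for the repetition noise.
#' @return list with `trains` (list of 80 spike-time vectors) and
#'   `channel_map` (data.frame: channel, sensor, preset, signal, repetition).
#' @export
multiplex_to_80 <- function(waveforms, repeats = 5,
                            presets = list(izhikevich_params("setting-1"),
                                           izhikevich_params("setting-2")),
                            fs = NULL, noise_sd = 0.02, seed = 1) {
  if (nrow(waveforms) != 4) stop("exactly 4 sensor waveforms are required")
  if (is.null(fs)) fs <- attr(waveforms, "fs")
  if (is.null(fs)) stop("sampling rate fs is required")
  n <- ncol(waveforms)
  rs <- .new_rng_state(seed)
  on.exit(.restore_rng_state(rs))
  trains <- vector("list", 0)
  map <- list()
  ch <- 0
  for (k in 1:4) {
    # fresh noise per repetition; raw and derivative per repetition
    reps_raw <- lapply(seq_len(repeats), function(r)
      waveforms[k, ] + rnorm(n, sd = noise_sd))
    for (pi in 1:2) {
      p <- presets[[pi]]
      for (sig in c("raw", "derivative")) {
        for (r in seq_len(repeats)) {
          x <- reps_raw[[r]]
          if (sig == "derivative") {
            x <- c(0, diff(x)) * fs
            x <- as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2))
            x[is.na(x)] <- 0
            x <- abs(x)
          }
          x <- .unit_scale(x)
          ch <- ch + 1
          trains[[ch]] <- izhikevich_encode(p$input_gain * x, p, fs)
          map[[ch]] <- data.frame(channel = ch, sensor = k,
                                  preset = p$preset, signal = sig,
                                  repetition = r)
        }
      }
    }
  }
  list(trains = trains, channel_map = do.call(rbind, map))
}

.unit_scale <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) return(numeric(length(x)))
  (x - rng[1]) / diff(rng)
}

#' Build a stimulus set
#'
#' Assembles the five-training / five-non-training stimulus collections used
#' by the learning protocol: three texture-slide stimuli with distinct ridge
#' frequencies and two dynamic indentations with distinct shapes. Each
#' stimulus is expanded to 80 PA spike trains via [multiplex_to_80()].
#'
#' @param kind `"training"` or `"non-training"` (different texture
#'   frequencies and indentation shapes).
#' @param duration stimulus duration (s).
#' @param fs analog sampling rate (Hz).
#' @param seed master seed; every stimulus derives its own deterministic
#'   sub-seed from it.
#' @param n_sensors,repeats channel-expansion controls (defaults give 80
#'   channels).
#' @return an object of class `stimulus_set`: list of stimuli (each with
#'   `label`, `class`, `duration`, `trains`, `channel_map`) plus provenance.
#' @export
make_stimulus_set <- function(kind = c("training", "non-training"),
                              duration = 1, fs = 1000, seed = 1,
                              repeats = 5) {
  kind <- match.arg(kind)
  specs <- if (kind == "training") list(
    list(label = "texture-A", class = "texture-slide", ridge_freq = 15),
    list(label = "texture-B", class = "texture-slide", ridge_freq = 22),
    list(label = "texture-C", class = "texture-slide", ridge_freq = 32),
    list(label = "indent-broad", class = "indentation", rise_time = 0.05,
         shape_width = 0.8, dyn_freq = 7),
    list(label = "indent-sharp", class = "indentation", rise_time = 0.15,
         shape_width = 0.3, dyn_freq = 11)
  ) else list(
    list(label = "texture-D", class = "texture-slide", ridge_freq = 18),
    list(label = "texture-E", class = "texture-slide", ridge_freq = 26),
    list(label = "texture-F", class = "texture-slide", ridge_freq = 38),
    list(label = "indent-medium", class = "indentation", rise_time = 0.09,
         shape_width = 0.6, dyn_freq = 8),
    list(label = "indent-point", class = "indentation", rise_time = 0.22,
         shape_width = 0.15, dyn_freq = 13)
  )
  stimuli <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    pars <- sp[setdiff(names(sp), c("label", "class"))]
    pars$duration <- duration
    pars$fs <- fs
    wf <- synth_analog_stimuli(sp$class, pars, seed = seed * 101 + i)
    mx <- multiplex_to_80(wf, repeats = repeats, fs = fs,
                          seed = seed * 977 + i)
    list(label = sp$label, class = sp$class, duration = duration,
         trains = mx$trains, channel_map = mx$channel_map)
  })
  structure(list(stimuli = stimuli, kind = kind,
                 provenance = list(seed = seed, duration = duration, fs = fs,
                                   repeats = repeats)),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set> ", length(x$stimuli), x$kind, "stimuli;",
      length(x$stimuli[[1]]$trains), "PA channels each\n")
  invisible(x)
}

#' Jitter spike times
#'
#' Adds independent zero-mean Gaussian noise (sd `sigma`) to every spike
#' time, clips to the stimulus window and re-sorts.
#'
#' @param train sorted spike times (s).
#' @param sigma jitter standard deviation (s); 5 ms in the learning protocol.
#' @param window stimulus window length (s) for clipping, or `NULL`.
#' @param seed optional seed; by default the caller's RNG stream is used.
#' @return jittered, sorted spike times.
#' @export
jitter_spikes <- function(train, sigma = 5e-3, window = NULL, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0 || length(train) == 0) return(train)
  if (!is.null(seed)) {
    rs <- .new_rng_state(seed)
    on.exit(.restore_rng_state(rs))
  }
  out <- train + rnorm(length(train), sd = sigma)
  if (!is.null(window)) out <- pmin(pmax(out, 0), window)
  sort(out)
}
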