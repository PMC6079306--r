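test_that("Izhikevich encoder spikes deterministically with adaptation", {
  p1 <- izhikevich_params("setting-1")
  expect_length(izhikevich_encode(numeric(500), p1, fs = 1000), 0)
  sp <- izhikevich_encode(rep(10, 500), p1, fs = 1000)
  expect_gt(length(sp), 3)
  # regular-spiking adaptation: inter-spike intervals grow early on
  isi <- diff(sp)
  expect_gt(isi[3], isi[1])
  # determinism
  expect_identical(sp, izhikevich_encode(rep(10, 500), p1, fs = 1000))
  # the two presets differ through the input gain
  p2 <- izhikevich_params("setting-2")
  expect_equal(p2$input_gain, p1$input_gain / 2)
})

test_that("synthetic stimuli are deterministic with class-specific spectra", {
  z <- synth_analog_stimuli("texture-slide", list(amp = 0), seed = 1)
  expect_true(all(z == 0))
  w1 <- synth_analog_stimuli("texture-slide", list(ridge_freq = 18), seed = 7)
  w2 <- synth_analog_stimuli("texture-slide", list(ridge_freq = 18), seed = 7)
  expect_identical(w1, w2)
  expect_error(synth_analog_stimuli("poke"), "arg")

  # dominant spectral peak in the slide phase tracks the ridge frequency
  peak_freq <- function(f) {
    w <- synth_analog_stimuli("texture-slide",
                              list(ridge_freq = f, noise_sd = 0), seed = 3)
    x <- w[1, 400:1000]
    sp <- Mod(fft(x - mean(x)))[2:200]
    freqs <- (1:199) / length(x) * 1000
    freqs[which.max(sp)]
  }
  expect_equal(peak_freq(18), 18, tolerance = 0.15)
  expect_equal(peak_freq(30), 30, tolerance = 0.15)
})

test_that("multiplexing yields 80 mapped channels with SA/FA division", {
  wf <- synth_analog_stimuli("texture-slide", list(ridge_freq = 20), seed = 2)
  mx <- multiplex_to_80(wf, seed = 4)
  expect_length(mx$trains, 80)
  expect_equal(nrow(mx$channel_map), 80)
  expect_equal(unname(table(mx$channel_map$sensor)), rep(20L, 4),
               ignore_attr = TRUE)
  # channels of sensor k occupy the (k-1)*20 + 1 .. k*20 block
  expect_true(all(mx$channel_map$sensor == rep(1:4, each = 20)))
  expect_error(multiplex_to_80(wf[1:3, , drop = FALSE], seed = 1), "4 sensor")

  # static indentation: SA (raw) channels fire during the plateau while FA
  # (derivative) channels are nearly silent
  wfi <- synth_analog_stimuli("indentation",
                              list(rise_time = 0.05, shape_width = 0.8,
                                   dyn_amp = 0, noise_sd = 0.01), seed = 3)
  mi <- multiplex_to_80(wfi, repeats = 2, seed = 5)
  plateau <- function(tr) sum(tr > 0.35 & tr < 0.7)
  m <- mi$channel_map
  sa <- mean(vapply(mi$trains[m$signal == "raw" & m$preset == "setting-1"],
                    plateau, numeric(1)))
  fa <- mean(vapply(mi$trains[m$signal == "derivative" & m$preset == "setting-1"],
                    plateau, numeric(1)))
  expect_gt(sa, 5 * (fa + 0.1))

  # channel map round-trips through serialization
  f <- tempfile(fileext = ".csv")
  write.csv(mx$channel_map, f, row.names = FALSE)
  expect_equal(read.csv(f), mx$channel_map, ignore_attr = TRUE)
})

test_that("stimulus sets hold five labelled 80-channel stimuli in-window", {
  ss <- make_stimulus_set("training", seed = 1)
  expect_length(ss$stimuli, 5)
  for (st in ss$stimuli) {
    expect_length(st$trains, 80)
    spk <- unlist(st$trains)
    expect_true(all(spk >= 0 & spk <= st$duration))
  }
  expect_equal(sum(vapply(ss$stimuli, function(s) s$class == "indentation",
                          logical(1))), 2)
  # PA firing stays well below 200 Hz (no synaptic rate adaptation needed)
  rates <- unlist(lapply(ss$stimuli, function(s) lengths(s$trains))) /
    ss$stimuli[[1]]$duration
  expect_lt(max(rates), 200)
  # non-training set differs
  nt <- make_stimulus_set("non-training", seed = 1)
  expect_false(identical(lengths(nt$stimuli[[1]]$trains),
                         lengths(ss$stimuli[[1]]$trains)))
})

test_that("channels of one sensor are mutually more similar than across sensors", {
  ss <- make_stimulus_set("training", seed = 1)
  st <- ss$stimuli[[1]]
  map <- st$channel_map
  grp <- function(k) map$channel[map$sensor == k & map$signal == "raw" &
                                   map$preset == "setting-1"]
  mean_vpd <- function(idx1, idx2 = NULL) {
    if (is.null(idx2)) {
      pr <- combn(idx1, 2)
      mean(apply(pr, 2, function(q)
        victor_purpura(st$trains[[q[1]]], st$trains[[q[2]]], 10)))
    } else {
      mean(outer(idx1, idx2, Vectorize(function(i, j)
        victor_purpura(st$trains[[i]], st$trains[[j]], 10))))
    }
  }
  within <- mean(c(mean_vpd(grp(1)), mean_vpd(grp(2))))
  across <- mean_vpd(grp(1), grp(2))
  expect_lt(within, across)
})

test_that("jitter is Gaussian, clipped, sorted and seed-reproducible", {
  train <- seq(0.01, 0.99, by = 0.01)
  expect_identical(jitter_spikes(train, 0), train)
  set.seed(11)
  big <- as.numeric(1:1e4)  # widely spaced: jitter cannot reorder
  j <- jitter_spikes(big, sigma = 5e-3)
  # folded-normal mean displacement: sigma * sqrt(2/pi)
  expect_equal(mean(abs(j - big)), 5e-3 * sqrt(2 / pi), tolerance = 0.05)
  jc <- jitter_spikes(c(0.0001, 0.9999), sigma = 0.05, window = 1, seed = 3)
  expect_true(all(jc >= 0 & jc <= 1))
  expect_identical(jitter_spikes(train, 5e-3, seed = 9),
                   jitter_spikes(train, 5e-3, seed = 9))
  expect_error(jitter_spikes(train, -1), "sigma")
})
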