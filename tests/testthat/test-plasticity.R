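cfg <- cn_plasticity_config()

test_that("Syn_EQ is the dual-slope gain anchored at the set point", {
  expect_equal(syn_eq(10, cfg), 1)
  expect_equal(syn_eq(15, cfg), 1.6)   # 1 + 0.12 * 5
  expect_equal(syn_eq(5, cfg), 0.8)    # 1 + 0.04 * (-5)
  expect_equal(syn_eq(0, cfg), 0.6)
  expect_error(syn_eq(-1, cfg), ">= 0")
})

test_that("learning threshold is the average activity times Syn_EQ", {
  expect_equal(learning_threshold(0, 12, cfg), 0)
  expect_equal(learning_threshold(1.7, 10, cfg), 1.7)
  expect_equal(learning_threshold(2, 15, cfg), 3.2)
})

test_that("weight compensation is a complementary sigmoid pair", {
  expect_equal(weight_compensation(cfg$comp_midpoint, +1, cfg), 0.5)
  expect_equal(weight_compensation(cfg$comp_midpoint, "-", cfg), 0.5)
  # potentiation harder at high weight, depression harder at low weight
  expect_gt(weight_compensation(0.1, +1, cfg), weight_compensation(0.9, +1, cfg))
  expect_lt(weight_compensation(0.1, -1, cfg), weight_compensation(0.9, -1, cfg))
  w <- seq(0.001, 1, length.out = 25)
  expect_equal(weight_compensation(w, -1, cfg), 1 - weight_compensation(w, +1, cfg))
  expect_true(all(weight_compensation(w, 1, cfg) > 0 &
                    weight_compensation(w, 1, cfg) < 1))
})

test_that("excitatory update gates on local activity and drive sign", {
  t_grid <- seq(0, 1, by = 1e-3)
  atot <- 1 + sin(2 * pi * t_grid)

  # silent synapse: no change
  up0 <- excitatory_update(atot, numeric(length(atot)), 1, 0.3, 1e-3, cfg)
  expect_equal(up0$dw, 0)
  expect_equal(up0$w, 0.3)

  # local activity only where A_tot is above threshold: potentiation
  aloc_hi <- as.numeric(atot > 1.5)
  up_hi <- excitatory_update(atot, aloc_hi, 1, 0.3, 1e-3, cfg)
  expect_gt(up_hi$dw, 0)

  # local activity only where A_tot is below threshold: depression
  aloc_lo <- as.numeric(atot < 0.5)
  up_lo <- excitatory_update(atot, aloc_lo, 1, 0.3, 1e-3, cfg)
  expect_lt(up_lo$dw, 0)

  # weights are clipped into [w_min, w_max]
  big <- cn_plasticity_config(eta = 1e12)
  expect_equal(excitatory_update(atot, aloc_hi, 1, 0.9, 1e-3, big)$w, big$w_max)
  expect_equal(excitatory_update(atot, aloc_lo, 1, 0.1, 1e-3, big)$w, big$w_min)

  expect_error(excitatory_update(atot, aloc_hi[-1], 1, 0.3, 1e-3, cfg), "grid")
})

test_that("a burst-aligned synapse out-learns an equally active misaligned one", {
  # deterministic two-synapse toy: same total local activity, different timing
  t_grid <- seq(0, 1, by = 1e-3)
  atot <- 1 + sin(2 * pi * 3 * t_grid)
  aligned <- pmax(sin(2 * pi * 3 * t_grid), 0)        # peaks with A_tot
  misaligned <- pmax(-sin(2 * pi * 3 * t_grid), 0)    # peaks against A_tot
  wa <- wm <- 0.125
  small <- cn_plasticity_config(eta = 0.05)
  for (k in 1:20) {
    thr <- learning_threshold(mean(atot), wa + wm, small)
    wa <- excitatory_update(atot, aligned, thr, wa, 1e-3, small)$w
    wm <- excitatory_update(atot, misaligned, thr, wm, 1e-3, small)$w
  }
  expect_gt(wa, wm)
  expect_gt(wa, 0.125)
  expect_lt(wm, 0.125)
})

test_that("calcium spike rate counts upward threshold crossings", {
  expect_equal(calcium_spike_rate(rep(1e-8, 1000), 1, cfg), 0)
  # 10 synthetic bumps in 0.5 s -> 20 Hz
  t_grid <- seq(0, 0.5, by = 1e-4)
  bumps <- numeric(length(t_grid))
  centers <- seq(0.025, 0.475, by = 0.05)
  for (tc in centers) bumps <- bumps + 5e-7 * exp(-((t_grid - tc) / 2e-3)^2)
  expect_equal(calcium_spike_rate(bumps, 0.5, cfg), length(centers) / 0.5)
  expect_equal(calcium_spike_rate(bumps, 0.5, cfg), 20)
})

test_that("inhibitory rule is dual-slope, zero at the set point, clamped", {
  expect_equal(inhibitory_update(cfg$setpoint_ca_rate, cfg), 0)
  expect_equal(inhibitory_update(0, cfg), -0.01)
  expect_equal(inhibitory_update(200, cfg), 0.01)
  expect_equal(inhibitory_update(110, cfg), 0.005)  # halfway 20 -> 200
  expect_equal(inhibitory_update(500, cfg), 0.01)   # clamped above 200
  expect_equal(inhibitory_update(10, cfg), -0.005)
  expect_error(inhibitory_update(-5, cfg), ">= 0")
})
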