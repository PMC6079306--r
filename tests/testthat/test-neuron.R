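p <- cn_neuron_params()

test_that("leak and spike currents follow the EIF closed forms", {
  # at E_L the leak vanishes, only the exponential term remains
  expect_equal(leak_and_spike_current(p$E_L, p),
               p$g_L * p$Delta_T * exp((p$E_L - p$V_t) / p$Delta_T))
  # at V_t the exponent is zero
  expect_equal(leak_and_spike_current(p$V_t, p),
               -p$g_L * (p$V_t - p$E_L) + p$g_L * p$Delta_T)
  # one slope factor above threshold: spike term gains a factor e
  i1 <- leak_and_spike_current(p$V_t + p$Delta_T, p) +
    p$g_L * (p$V_t + p$Delta_T - p$E_L)
  expect_equal(i1, p$g_L * p$Delta_T * exp(1))
  expect_error(leak_and_spike_current(NaN, p), "finite")
})

test_that("gating equilibria are sigmoids with the expected anchors", {
  eq <- gating_equilibria(p$p_Ca_a_1, p$Ca_rest, p)
  expect_equal(eq$x_Ca_a, 0.5)
  # invert the sigmoid analytically: p1 + p2*log(3) gives 0.75
  eq2 <- gating_equilibria(p$p_Ca_a_1 + p$p_Ca_a_2 * log(3), p$Ca_rest, p)
  expect_equal(eq2$x_Ca_a, 0.75)
  lo <- gating_equilibria(-10, p$Ca_rest, p)
  expect_lt(lo$x_Ca_a, 1e-10)
  expect_gt(lo$x_Ca_i, 1 - 1e-10)
  # CAP calcium gate opens with calcium
  expect_lt(gating_equilibria(p$E_L, p$Ca_rest, p)$x_KCa,
            gating_equilibria(p$E_L, 1e-6, p)$x_KCa)
  vals <- unlist(gating_equilibria(-0.06, 2e-7, p))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("channel currents vanish for closed gates and at reversals", {
  st <- cn_state(-0.06, 0, 0.5, 0.5, 0.5, p$Ca_rest)
  expect_equal(ion_currents(st, p)$I_Ca, 0)
  st2 <- cn_state(p$E_K, 0.5, 0.5, 0.5, 0.5, p$Ca_rest)
  expect_equal(ion_currents(st2, p)$I_K, 0)
  # all gates open at -60 mV: hand evaluation
  st3 <- cn_state(-0.060, 1, 1, 1, 1, p$Ca_rest)
  ic <- ion_currents(st3, p)
  expect_equal(ic$I_Ca, -p$g_Ca * (-0.060 - p$E_Ca))
  expect_equal(ic$I_K, -p$g_K * (-0.060 - p$E_K))
})

test_that("cn_step enforces the stability guard and relaxes correctly", {
  st <- cn_state_rest(p)
  expect_error(cn_step(st, dt = 1e-3, params = p), "stability guard")

  # hold the membrane at a fixed potential much longer than tau_Ca_a:
  # the activation gate must settle at its equilibrium
  V_hold <- -0.055
  s <- cn_state(V_hold, 0, 1, 0, 0, p$Ca_rest)
  for (i in 1:100) {
    s <- cn_step(s, dt = 1e-4, params = p)
    s$V_m <- V_hold
  }
  expect_equal(s$x_Ca_a, gating_equilibria(V_hold, p$Ca_rest, p)$x_Ca_a,
               tolerance = 1e-6)

  # with g_Ca = 0 the calcium concentration decays exponentially to rest
  p0 <- cn_neuron_params(g_Ca = 0, ca_per_spike = 0)
  s <- cn_state(p0$E_L, 0, 0, 0, 0, 5 * p0$Ca_rest)
  ca <- numeric(200)
  for (i in 1:200) {
    s <- cn_step(s, dt = 1e-4, params = p0)
    s$V_m <- p0$E_L
    ca[i] <- s$Ca_conc
  }
  t_grid <- (1:200) * 1e-4
  expected <- p0$Ca_rest + 4 * p0$Ca_rest * exp(-t_grid / p0$tau_Ca_conc)
  expect_lt(max(abs(ca - expected) / expected), 1e-3)
})

test_that("zero-input membrane settles at the fixed point found by root-finding", {
  tr <- cn_integrate(NULL, 0.5, params = p)
  expect_length(tr$spike_times, 0)
  v_star <- cn_rest_oracle(p)
  expect_lt(abs(tail(tr$V_m, 1) - v_star), 1e-3)
})

test_that("release from -400 pA hyperpolarization elicits rebound spiking", {
  dt <- 1e-4
  n <- round(0.6 / dt)
  I <- numeric(n)
  I[round(0.05 / dt):round(0.25 / dt)] <- -400e-12
  tr <- cn_integrate(NULL, 0.6, dt = dt, I_ext = I)
  post <- tr$spike_times[tr$spike_times > 0.25 & tr$spike_times <= 0.35]
  expect_gte(length(post), 1)
  # no spiking during the hyperpolarizing step itself
  expect_length(tr$spike_times[tr$spike_times > 0.06 & tr$spike_times < 0.25], 0)
  # the rebound rides on a calcium transient
  expect_gt(max(tr$Ca_conc), 2 * p$Ca_rest)
})

test_that("spike count is non-decreasing over the six-step current protocol", {
  counts <- step_counts(cn_neuron_params())
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[6], 0)
})

test_that("rebound spike times converge under dt halving", {
  reb <- function(dt) {
    n <- round(0.6 / dt)
    I <- numeric(n)
    I[round(0.05 / dt):round(0.25 / dt)] <- -400e-12
    cn_integrate(NULL, 0.6, dt = dt, I_ext = I, record = FALSE)$spike_times
  }
  s1 <- reb(5e-5)
  s2 <- reb(2.5e-5)
  expect_equal(length(s1), length(s2))
  expect_lt(max(abs(s1 - s2)), 0.2e-3)
})

test_that("with g_Ca = g_K = 0 the model reduces to a plain EIF", {
  p0 <- cn_neuron_params(g_Ca = 0, g_K = 0, ca_per_spike = 0)
  for (amp in c(100e-12, 300e-12, 600e-12)) {
    n_pkg <- length(cn_integrate(NULL, 1, params = p0, I_ext = amp,
                                 record = FALSE)$spike_times)
    n_ref <- eif_reference(amp, p0)
    expect_lte(abs(n_pkg - n_ref), 1)
  }
})

test_that("gates stay in [0,1] and calcium non-negative under random drive", {
  set.seed(42)
  s <- cn_state_rest(p)
  ok <- TRUE
  for (i in 1:5000) {
    s <- cn_step(s, I_ext = runif(1, -0.5, 0.5) * 1e-9, dt = 1e-4, params = p)
    g <- c(s$x_Ca_a, s$x_Ca_i, s$x_KCa, s$x_KVm)
    if (any(g < 0 | g > 1) || s$Ca_conc < 0) { ok <- FALSE; break }
    if (abs(s$V_m) > 0.2) s$V_m <- p$E_L  # keep the open-loop step bounded
  }
  expect_true(ok)
})

test_that("extreme drive stays bounded; non-finite input aborts loudly", {
  # the integrating-factor update plus the spike ceiling keep even a 1 uA
  # injection bounded (pegged firing, no divergence)
  tr <- cn_integrate(NULL, 0.05, I_ext = 1e-6)
  expect_true(all(is.finite(tr$V_m)))
  expect_lt(max(abs(tr$V_m)), 0.5)
  expect_gt(length(tr$spike_times), 10)
  expect_error(cn_integrate(NULL, 0.05, I_ext = NaN), "blow-up")
})

test_that("voltage traces expose a tabular view", {
  tr <- cn_integrate(NULL, 0.05)
  df <- as.data.frame(tr)
  expect_named(df, c("time_s", "Vm_V", "Ca_conc"))
  expect_equal(nrow(df), length(tr$time))
  expect_true(all(diff(tr$spike_times) > 0) || length(tr$spike_times) < 2)
})
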