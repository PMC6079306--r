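test_that("Victor-Purpura distance matches its worked values", {
  expect_equal(victor_purpura(c(0.1, 0.2), c(0.1, 0.2)), 0)
  expect_equal(victor_purpura(numeric(0), 0.1), 1)
  expect_equal(victor_purpura(numeric(0), numeric(0)), 0)
  # shift (q*0.05 = 0.5) is cheaper than delete + add (2)
  expect_equal(victor_purpura(0.10, 0.15, q = 10), 0.5)
  expect_error(victor_purpura(c(0.2, 0.1), 0.1), "sorted")
  expect_error(victor_purpura(0.1, 0.1, q = -1), "q")
})

test_that("the DP agrees with brute-force matching enumeration", {
  grid <- seq(0, 0.4, by = 0.1)  # 5-point time grid
  set.seed(5)
  for (rep in 1:40) {
    a <- sort(sample(grid, sample(0:4, 1)))
    b <- sort(sample(grid, sample(0:4, 1)))
    q <- sample(c(0.5, 2, 10), 1)
    expect_equal(victor_purpura(a, b, q), vp_brute(a, b, q))
  }
})

test_that("VPd satisfies metric axioms and its q limits", {
  set.seed(6)
  trains <- replicate(6, sort(runif(sample(1:6, 1))), simplify = FALSE)
  for (i in 1:6) for (j in 1:6) {
    dij <- victor_purpura(trains[[i]], trains[[j]])
    expect_equal(dij, victor_purpura(trains[[j]], trains[[i]])) # symmetry
    if (i == j) expect_equal(dij, 0)
    for (k in 1:6)
      expect_lte(dij, victor_purpura(trains[[i]], trains[[k]]) +
                   victor_purpura(trains[[k]], trains[[j]]) + 1e-12)
  }
  a <- c(0.1, 0.35, 0.8); b <- c(0.12, 0.35)
  expect_equal(victor_purpura(a, b, q = 0), 1)                 # |n_a - n_b|
  expect_equal(victor_purpura(a, b, q = 1e6), 3 + 2 - 2 * 1)   # one coincidence
})

test_that("correlation index separates coherent from incoherent groups", {
  same <- replicate(4, c(0.1, 0.3, 0.5), simplify = FALSE)
  ci0 <- correlation_index(list(same, same))
  expect_equal(ci0$index, 0)

  set.seed(8)
  slow <- replicate(5, rpois_train(5, 1), simplify = FALSE)
  fast <- replicate(5, rpois_train(40, 1), simplify = FALSE)
  within_slow <- correlation_index(list(slow))$index
  mixed <- correlation_index(list(c(slow[1:3], fast[1:2])))$index
  expect_gt(mixed, within_slow)
  expect_error(correlation_index(list()), "empty")
})

test_that("reconstructed responses superimpose weighted EPSP kernels", {
  tr <- list(c(0.1), c(0.2, 0.4))
  expect_equal(reconstruct_response(tr, c(0, 0), duration = 0.5),
               numeric(501))
  # one spike, unit weight: a clean exponential at tau = 6.4 ms
  r <- reconstruct_response(list(0.1), 1, duration = 0.5, dt = 1e-3)
  t_grid <- seq(0, 0.5, by = 1e-3)
  expected <- ifelse(t_grid >= 0.1, exp(-(t_grid - 0.1) / 6.4e-3), 0)
  expect_lt(max(abs(r - expected)), 1e-6)
  # linearity in the weights
  r12 <- reconstruct_response(tr, c(0.3, 0.7), duration = 0.5)
  r1 <- reconstruct_response(tr, c(0.3, 0), duration = 0.5)
  r2 <- reconstruct_response(tr, c(0, 0.7), duration = 0.5)
  expect_equal(r12, r1 + r2, tolerance = 1e-12)
  expect_error(reconstruct_response(tr, 1, duration = 0.5), "equal length")
})

test_that("zero-lag correlation is normalized and handles degeneracy", {
  x <- sin(seq(0, 4 * pi, length.out = 1000))
  expect_equal(zero_lag_correlation(x, x), 1)
  y <- cos(seq(0, 4 * pi, length.out = 1000))
  expect_lt(abs(zero_lag_correlation(x[-1000], y[-1000])), 1e-6)
  expect_warning(z <- zero_lag_correlation(numeric(10), x[1:10]), "zero")
  expect_equal(z, 0)
  expect_error(zero_lag_correlation(x, x[-1]), "equal length")
})

test_that("sparseness is the l2/l1 ratio with its known anchors", {
  one_hot <- c(rep(0, 79), 1)
  expect_equal(sparseness(one_hot), 1)
  expect_equal(sparseness(rep(0.3, 80)), 1 / sqrt(80))
  w <- runif(40)
  expect_equal(sparseness(3.7 * w), sparseness(w))
  set.seed(9)
  for (i in 1:20) {
    v <- runif(sample(2:50, 1))
    s <- sparseness(v)
    expect_gte(s, 1 / sqrt(length(v)) - 1e-12)
    expect_lte(s, 1)
  }
  expect_error(sparseness(numeric(5)), "zero")
  expect_error(sparseness(c(-1, 1)), "non-negative")
})

test_that("classical MDS reproduces generating configurations", {
  # colinear points embed exactly in 1-D
  x <- c(0, 1, 3)
  d1 <- as.matrix(dist(x))
  fit1 <- classical_mds(d1, dims = 1)
  expect_equal(as.matrix(dist(fit1$points)), d1, ignore_attr = TRUE,
               tolerance = 1e-10)

  set.seed(10)
  pts <- matrix(rnorm(16), 8, 2)
  fit <- classical_mds(as.matrix(dist(pts)), dims = 2)
  expect_equal(as.matrix(dist(fit$points)), as.matrix(dist(pts)),
               ignore_attr = TRUE, tolerance = 1e-8)

  # identical landscapes coincide; deficient rank pads with a warning
  d0 <- matrix(0, 3, 3)
  expect_warning(fit0 <- classical_mds(d0, dims = 2), "zero-padding")
  expect_equal(max(abs(dist(fit0$points))), 0)
  expect_error(classical_mds(matrix(1:9, 3)), "symmetric")
})

test_that("paired tests report learning effects with degeneracy handling", {
  x <- c(1, 2, 3, 4, 5, 6)
  same <- paired_stats(x, x, "t")
  expect_equal(same$p_value, 1)
  expect_match(same$note, "zero")

  set.seed(12)
  a <- rnorm(20)
  b <- rnorm(20, mean = 2)  # shifted pairs, delta = 2 sd
  expect_lt(paired_stats(a, b, "t")$p_value, 0.01)
  expect_lt(paired_stats(a, b, "wilcoxon")$p_value, 0.01)
  expect_equal(paired_stats(a, b, "t")$statistic,
               -paired_stats(b, a, "t")$statistic)
  expect_error(paired_stats(1:3, 2:4), "5")
})
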