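test_that("transition counting matches brute-force enumeration", {
  s <- c(1, 1, 2, 2, 1, 2)
  cm <- count_transitions(s, lag = 1)
  expect_equal(cm$counts, count_oracle(s, 1, 2))
  expect_equal(sum(cm$counts), 5)  # 6 frames -> 5 sliding pairs
  # a single pair survives at lag 5 on 6 frames
  expect_equal(sum(count_transitions(s, lag = 5)$counts), 1)
  set.seed(30)
  r <- sample.int(6, 1e4, replace = TRUE)
  expect_equal(count_transitions(r, lag = 7)$counts,
               count_oracle(r, 7, 6))
  expect_error(count_transitions(c(1, 2), lag = 5), "shorter")
})

test_that("counting never pairs frames across trajectory boundaries", {
  cm <- count_transitions(list(c(1, 2), c(2, 1)), lag = 1)
  expect_equal(cm$counts, rbind(c(0, 1), c(1, 0)))
})

test_that("ergodic trimming keeps the dominant connected component", {
  cm <- count_transitions(c(rep(1, 6), rep(2, 8)), lag = 1)
  cm$counts <- diag(c(5, 7))  # two disconnected self-looping states
  m <- estimate_msm(cm)
  expect_equal(m$active_set, 2L)  # the larger-count component
  expect_equal(m$T, matrix(1, 1, 1))
})

test_that("symmetric counts give the exact symmetric fixed point", {
  m <- exact_msm(rbind(c(8, 2), c(2, 8)))
  expect_equal(m$T, rbind(c(0.8, 0.2), c(0.2, 0.8)), tolerance = 1e-12)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("the reversible MLE recovers a known 3-state chain", {
  set.seed(31)
  Ttrue <- random_reversible_T(3, seed = 31)
  pi_true <- stationary_distribution(Ttrue)
  s <- sample_markov_chain(Ttrue, 1e6, start = "stationary", seed = 31)
  m <- estimate_msm(count_transitions(s, 1))
  expect_lt(max(abs(m$T - Ttrue)), 0.01)
  expect_lt(max(abs(m$pi - pi_true)), 0.01)
})

test_that("every estimated model satisfies detailed balance and spectral bounds", {
  for (seed in c(32, 33, 34)) {
    n <- sample(2:6, 1)
    s <- sample_markov_chain(random_reversible_T(4, seed), 2e4,
                             seed = seed)
    m <- estimate_msm(count_transitions(s, 2))
    expect_equal(rowSums(m$T), rep(1, nrow(m$T)), tolerance = 1e-10)
    db <- m$pi * m$T - t(m$pi * m$T)
    expect_lt(max(abs(db)) / max(m$pi * m$T), 1e-8)
    expect_true(all(abs(m$eigenvalues) <= 1 + 1e-10))
    expect_equal(m$eigenvalues[1], 1, tolerance = 1e-10)
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  }
})

test_that("Chapman-Kolmogorov holds for Markovian data", {
  Ttrue <- random_reversible_T(3, seed = 35)
  s <- sample_markov_chain(Ttrue, 5e5, seed = 35)
  m1 <- estimate_msm(count_transitions(s, 5))
  m2 <- estimate_msm(count_transitions(s, 10))
  expect_lt(max(abs(m1$T %*% m1$T - m2$T)), 0.02)
})

test_that("implied timescales reproduce the closed form", {
  expect_equal(implied_timescales(exp(-1), lag_ns = 15), 15,
               tolerance = 1e-10)
  expect_equal(implied_timescales(0.5, lag_ns = 20), 28.85390082,
               tolerance = 1e-8)
  expect_equal(implied_timescales(1 - 1e-13, lag_ns = 1), Inf)
  expect_warning(ts <- implied_timescales(c(0.5, -0.2), lag_ns = 10),
                 "nonpositive")
  expect_true(is.na(ts[2]))
})

test_that("lag scan is flat for exactly Markovian data", {
  # slowly mixing symmetric (hence reversible, uniform-pi) chain so the
  # relaxation time spans the tested lags
  Ttrue <- rbind(c(0.96, 0.03, 0.01), c(0.03, 0.95, 0.02),
                 c(0.01, 0.02, 0.97))
  s <- sample_markov_chain(Ttrue, 3e5, seed = 36)
  ls <- lag_scan(s, c(1, 2, 4, 8), frame_spacing = 1)
  expect_equal(ls$suggested_lag, 1L)
  t_true <- implied_timescales(sort(eigen(Ttrue, only.values = TRUE)$values,
                                    decreasing = TRUE)[2], lag_ns = 1)
  expect_lt(abs(ls$table$ts1[1] - t_true) / t_true, 0.1)
  expect_error(lag_scan(s, c(1, 2)), "at least 3")
})

test_that("lag scan plateaus at the hidden relaxation time under noisy observation", {
  Th <- matrix(c(0.98, 0.02, 0.04, 0.96), 2, byrow = TRUE)
  hid <- sample_markov_chain(Th, 5e5, seed = 9)
  set.seed(10)
  n <- length(hid)
  obs <- ifelse(hid == 1, sample(1:2, n, TRUE), sample(3:4, n, TRUE))
  flip <- runif(n) < 0.02
  obs[flip] <- 5L - obs[flip]
  ls <- lag_scan(obs, c(1, 2, 5, 10, 15, 20, 25, 30), frame_spacing = 1)
  t1 <- ls$table$ts1
  expect_true(all(diff(t1) > 0))          # rises toward the plateau
  t_true <- -1 / log(1 - 0.02 - 0.04)     # hidden-chain relaxation
  expect_lt(abs(t1[length(t1)] - t_true) / t_true, 0.1)
  expect_false(is.na(ls$suggested_lag))
})

test_that("the landscape equation reproduces exact two-state free energies", {
  # reversible T with pi = (0.8, 0.2) built from exact counts
  m <- exact_msm(rbind(c(76, 4), c(4, 16)))
  expect_equal(m$pi, c(0.8, 0.2), tolerance = 1e-12)
  states <- c(1, 2)
  x <- c(0.25, 0.75)  # delta histogram per state
  fes <- free_energy_surface(m, states, x, bins = 2, kT = 0.5924)
  dF <- max(fes$F, na.rm = TRUE) - min(fes$F, na.rm = TRUE)
  expect_equal(dF, 0.5924 * log(4), tolerance = 1e-12)
  # single state, uniform histogram -> F identically 0 on occupied bins
  m1 <- exact_msm(matrix(10, 1, 1))
  f1 <- free_energy_surface(m1, rep(1, 100), seq(0, 1, length.out = 100),
                            bins = 10)
  expect_true(all(abs(f1$F[!is.na(f1$F)]) < 1e-12))
})

test_that("landscape errors when an active state has no observable frames", {
  m <- exact_msm(rbind(c(8, 2), c(2, 8)))
  expect_error(free_energy_surface(m, c(1, 1), c(0.1, 0.2), bins = 2),
               "without observable frames")
})

test_that("double-well landscape recovers the generating potential", {
  h <- 4
  x <- brownian_dynamics(double_well_1d(h), dt = 5e-3, n_steps = 2e6,
                         seed = 11)[, 1]
  kc <- k_centers(matrix(x, ncol = 1), 30)
  m <- estimate_msm(count_transitions(kc$assignments, 20))
  fes <- free_energy_surface(m, kc$assignments, x, bins = 60)
  mid <- (fes$x_edges[-1] + fes$x_edges[-61]) / 2
  Ftheory <- 0.5924 * h * (mid^2 - 1)^2
  # well region: bins within 1 kT of each minimum (avoids the steep
  # flanks where finite bin width alone biases the histogram)
  well <- h * (mid^2 - 1)^2 <= 1
  off <- mean(fes$F[well] - Ftheory[well], na.rm = TRUE)
  expect_lt(max(abs(fes$F[well] - Ftheory[well] - off), na.rm = TRUE),
            0.15)
})

test_that("adaptive seeding returns the least-populated states", {
  m <- exact_msm(rbind(c(45, 5, 0), c(5, 25, 5), c(0, 5, 10)))
  expect_equal(order(m$pi)[1], 3)
  expect_equal(adaptive_seed_states(m, 1), 3L)
  expect_equal(adaptive_seed_states(m, 3), order(m$pi))
  set.seed(37)
  s <- sample_markov_chain(random_reversible_T(8, 37), 5e4, seed = 37)
  m8 <- estimate_msm(count_transitions(s, 1))
  expect_equal(adaptive_seed_states(m8, 4),
               m8$active_set[order(m8$pi, m8$active_set)][1:4])
  expect_error(adaptive_seed_states(m8, 99), "exceeds")
})
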