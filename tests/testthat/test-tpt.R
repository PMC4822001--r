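# Independent committor oracle: absorbing-chain power iteration. Make A
# absorbing at 0 and B absorbing at 1, iterate q <- T q to convergence.
committor_oracle <- function(T, A, B, tol = 1e-12) {
  q <- rep(0.5, nrow(T))
  q[A] <- 0; q[B] <- 1
  repeat {
    qn <- drop(T %*% q)
    qn[A] <- 0; qn[B] <- 1
    if (max(abs(qn - q)) < tol) return(qn)
    q <- qn
  }
}

test_that("committors solve the symmetric chain and boundary conditions", {
  # symmetric 3-state linear chain A - I - B from exact counts
  m <- exact_msm(rbind(c(90, 10, 0), c(10, 80, 10), c(0, 10, 90)))
  q <- committors(m, 1, 3)
  expect_equal(q$q_plus, c(0, 0.5, 1), tolerance = 1e-12)
  expect_equal(q$q_minus, 1 - q$q_plus, tolerance = 1e-10)
  expect_error(committors(m, c(1, 2), 2), "disjoint")
})

test_that("committors match absorbing-chain iteration on random reversible chains", {
  for (seed in c(41, 42)) {
    Ttrue <- random_reversible_T(6, seed)
    s <- sample_markov_chain(Ttrue, 5e4, seed = seed)
    m <- estimate_msm(count_transitions(s, 1))
    q <- committors(m, A = 1, B = c(5, 6))
    expect_equal(q$q_plus, committor_oracle(m$T, 1, c(5, 6)),
                 tolerance = 1e-8)
    expect_true(all(q$q_plus >= 0 & q$q_plus <= 1))
    expect_equal(q$q_minus, 1 - q$q_plus, tolerance = 1e-8)
  }
})

test_that("committors are monotone along a 1D chain", {
  # nearest-neighbour 6-state chain (symmetric counts)
  C <- matrix(0, 6, 6)
  for (i in 1:5) { C[i, i + 1] <- 5; C[i + 1, i] <- 5; C[i, i] <- 40 }
  C[6, 6] <- 40
  m <- exact_msm(C)
  q <- committors(m, 1, 6)$q_plus
  expect_true(all(diff(q) >= -1e-12))
})

test_that("reactive flux is conserved and matches the single-edge closed form", {
  m <- exact_msm(rbind(c(76, 4), c(4, 16)))
  fx <- reactive_flux(m, 1, 2)
  expect_equal(fx$total_flux, m$pi[1] * m$T[1, 2], tolerance = 1e-12)
  # conservation at intermediate nodes of a 5-state model
  Ttrue <- random_reversible_T(5, seed = 43)
  s <- sample_markov_chain(Ttrue, 5e4, seed = 43)
  m5 <- estimate_msm(count_transitions(s, 1))
  fx5 <- reactive_flux(m5, 1, 5)
  net <- fx5$net_flux
  for (i in 2:4)
    expect_equal(sum(net[, i]), sum(net[i, ]), tolerance = 1e-12)
  # flux out of A equals flux into B
  expect_equal(sum(net[1, -1]), sum(net[-5, 5]), tolerance = 1e-12)
})

test_that("pathway decomposition handles forced topologies", {
  # single chain A -> I -> B carries all flux on one path
  C <- rbind(c(80, 10, 0), c(10, 80, 10), c(0, 10, 80))
  m <- exact_msm(C)
  res <- transition_paths(m, 1, 3, stop_fraction = 1)
  expect_length(res$pathways, 1)
  expect_equal(res$pathways[[1]]$states, c(1, 2, 3))
  expect_equal(res$pathways[[1]]$flux, res$total_flux, tolerance = 1e-12)
})

test_that("parallel channels decompose in flux order with exact split", {
  # A = 1, B = 4; two 2-hop channels via 2 (strong) and 3 (weak), built
  # from symmetric counts with a 3:1 capacity ratio
  C <- matrix(0, 4, 4)
  C[1, 2] <- C[2, 1] <- 30; C[2, 4] <- C[4, 2] <- 30
  C[1, 3] <- C[3, 1] <- 10; C[3, 4] <- C[4, 3] <- 10
  diag(C) <- c(60, 40, 40, 60)
  m <- exact_msm(C)
  res <- transition_paths(m, 1, 4, stop_fraction = 1)
  expect_length(res$pathways, 2)
  expect_equal(res$pathways[[1]]$states, c(1, 2, 4))
  expect_equal(res$pathways[[2]]$states, c(1, 3, 4))
  expect_gt(res$pathways[[1]]$flux, res$pathways[[2]]$flux)
  expect_equal(sum(vapply(res$pathways, `[[`, numeric(1), "flux")),
               res$total_flux, tolerance = 1e-10)
  # known 3:1 split -> 75% of flux through the major channel
  expect_equal(flux_fraction_through(res, 2, pathways = res$pathways),
               0.75, tolerance = 1e-10)
  expect_equal(flux_fraction_through(res, 3, pathways = res$pathways),
               0.25, tolerance = 1e-10)
})

test_that("decomposition agrees with exhaustive path enumeration on random networks", {
  Ttrue <- random_reversible_T(7, seed = 44)
  s <- sample_markov_chain(Ttrue, 1e5, seed = 44)
  m <- estimate_msm(count_transitions(s, 1))
  fx <- reactive_flux(m, 1, 7)
  paths <- top_pathways(fx, stop_fraction = 1, max_paths = 10000)
  expect_equal(sum(vapply(paths, `[[`, numeric(1), "flux")),
               fx$total_flux, tolerance = 1e-10)
  # the first (widest) path's bottleneck matches brute force
  cap <- fx$net_flux
  cap[, 1] <- 0; cap[7, ] <- 0
  all_paths <- enumerate_simple_paths(cap, 1, 7)
  best <- max(vapply(all_paths, `[[`, numeric(1), "bottleneck"))
  expect_equal(paths[[1]]$flux, best, tolerance = 1e-12)
  # decomposition is deterministic
  paths2 <- top_pathways(fx, stop_fraction = 1, max_paths = 10000)
  expect_identical(paths, paths2)
})

test_that("flux fractions respect set constraints and degenerate cases", {
  C <- rbind(c(80, 10, 0), c(10, 80, 10), c(0, 10, 80))
  m <- exact_msm(C)
  res <- transition_paths(m, 1, 3, stop_fraction = 1)
  expect_equal(flux_fraction_through(res, 2, pathways = res$pathways), 1)
  expect_equal(flux_fraction_through(res, integer(0)), 0)
  expect_error(flux_fraction_through(res, 1), "disjoint")
})
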