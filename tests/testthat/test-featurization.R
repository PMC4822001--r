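test_that("contact features reproduce hand-computable distances and the separation filter", {
  # two single-atom residues at a 3-4-5 right triangle
  coords <- rbind(c(0, 0, 0), c(3, 4, 0), c(100, 0, 0), c(0, 100, 0),
                  c(0, 0, 100))
  traj <- bead_frame(coords)
  cf <- contact_features(traj, min_separation = 1)
  p12 <- which(cf$pair_labels[, 1] == 1 & cf$pair_labels[, 2] == 2)
  expect_equal(cf$values[1, p12], 5.0)
  # 5-residue chain, min_separation = 3 -> exactly (1,4), (1,5), (2,5)
  cf3 <- contact_features(traj, min_separation = 3)
  expect_equal(unname(cf3$pair_labels),
               rbind(c(1, 4), c(1, 5), c(2, 5)))
})

test_that("contact features equal a brute-force all-pairs scan on the toy polymer", {
  tp <- toy_polymer(5, noise_sigma = 0.2, switch_prob = 0.4, seed = 6)
  cf <- contact_features(tp$trajectory, min_separation = 3)
  xyz <- tp$trajectory$coordinates
  for (f in 1:5) for (p in seq_len(nrow(cf$pair_labels))) {
    i <- cf$pair_labels[p, 1]; j <- cf$pair_labels[p, 2]
    # single-bead residues: the minimum heavy-atom distance is the bead
    # distance itself
    expect_equal(cf$values[f, p],
                 sqrt(sum((xyz[f, i, ] - xyz[f, j, ])^2)),
                 tolerance = 1e-12)
  }
})

test_that("contact features are stable under atom relabelling within a residue", {
  # two residues with two heavy atoms each; swap atom order in residue 1
  top <- data.frame(resid = c(1, 1, 5, 5), resname = "XXX",
                    atom = c("C1", "C2", "C1", "C2"), element = "C")
  xyz <- array(0, c(1, 4, 3))
  xyz[1, , ] <- rbind(c(0, 0, 0), c(1, 0, 0), c(4, 0, 0), c(9, 0, 0))
  t1 <- trajectory(xyz, top)
  xyz2 <- xyz[, c(2, 1, 3, 4), , drop = FALSE]
  t2 <- trajectory(xyz2, top)
  expect_equal(contact_features(t1, 1)$values,
               contact_features(t2, 1)$values)
})

test_that("a residue with no heavy atoms is rejected by name", {
  top <- data.frame(resid = c(1, 4), resname = "XXX", atom = "H1",
                    element = c("C", "H"))
  xyz <- array(rnorm(6), c(1, 2, 3))
  expect_error(contact_features(trajectory(xyz, top), 3),
               "residue 4")
})

test_that("pair_distance agrees with contact_features and with CA geometry", {
  tp <- toy_polymer(20, seed = 8)
  cf <- contact_features(tp$trajectory, min_separation = 3)
  p <- which(cf$pair_labels[, 1] == 2 & cf$pair_labels[, 2] == 9)
  expect_equal(pair_distance(tp$trajectory, c(2, 9), "min_heavy"),
               cf$values[, p], tolerance = 1e-9)
  ca <- bead_frame(rbind(c(0, 0, 0), c(0, 0, 7.5)))
  expect_equal(pair_distance(ca, c(1, 2), "c_alpha"), 7.5)
  expect_error(pair_distance(tp$trajectory, c(1, 99)), "99")
})

test_that("partial-unfolding classification follows the documented OR rule", {
  expect_false(classify_partial_unfolding(6.0, 9.0))
  expect_true(classify_partial_unfolding(11.5, 9.0))   # helix-G cutoff 11 A
  expect_true(classify_partial_unfolding(10.9, 15.1))  # site-2 cutoff 15 A
  expect_false(classify_partial_unfolding(10.9, 15.1, rule = "and"))
  expect_error(classify_partial_unfolding(-1, 5), "nonnegative")
  # monotonicity: increasing either distance never flips TRUE -> FALSE
  set.seed(1)
  d1 <- runif(200, 0, 20); d2 <- runif(200, 0, 20)
  base <- classify_partial_unfolding(d1, d2)
  expect_true(all(classify_partial_unfolding(d1 + 2, d2) >= base))
  expect_true(all(classify_partial_unfolding(d1, d2 + 2) >= base))
})

test_that("torsion angles match cis/trans geometry and an independent formulation", {
  # planar cis: all four atoms in a plane, 1 and 4 on the same side
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  traj_of <- function(m) bead_frame(m)
  expect_equal(unname(torsion_angles(traj_of(cis), list(t1 = 1:4))[1, 1]),
               0)
  expect_equal(abs(torsion_angles(traj_of(trans), list(1:4))[1, 1]), pi)
  set.seed(42)
  for (k in 1:25) {
    q <- matrix(rnorm(12), 4, 3)
    got <- torsion_angles(traj_of(q), list(1:4))[1, 1]
    expect_equal(got, dihedral_gs(q[1, ], q[2, ], q[3, ], q[4, ]),
                 tolerance = 1e-10)
  }
  expect_warning(torsion_angles(traj_of(cis), list(1:4, c(1, 2, 3, 9))),
                 "skipped")
})

test_that("subset RMSD is zero on congruent configurations", {
  set.seed(3)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(subset_rmsd(A, A), 0)
  # random rigid motion
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- A %*% R + matrix(c(5, -2, 3), 10, 3, byrow = TRUE)
  expect_lt(subset_rmsd(A, B), 1e-9)
})

test_that("subset RMSD behaves as a pseudo-metric and matches bio3d", {
  set.seed(4)
  frames <- replicate(3, matrix(rnorm(30), 10, 3), simplify = FALSE)
  d12 <- subset_rmsd(frames[[1]], frames[[2]])
  d21 <- subset_rmsd(frames[[2]], frames[[1]])
  d13 <- subset_rmsd(frames[[1]], frames[[3]])
  d23 <- subset_rmsd(frames[[2]], frames[[3]])
  expect_equal(d12, d21, tolerance = 1e-10)
  expect_lte(d13, d12 + d23 + 1e-10)
  # independent oracle: bio3d's superposition-based RMSD
  oracle <- bio3d::rmsd(as.vector(t(frames[[1]])),
                        as.vector(t(frames[[2]])),
                        fit = TRUE)
  expect_equal(d12, oracle, tolerance = 1e-3)
})

test_that("rmsd_matrix is symmetric with zero diagonal and matches subset_rmsd", {
  tp <- toy_polymer(6, seed = 5)
  M <- rmsd_matrix(tp$trajectory)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, 6))
  f1 <- bead_frame(matrix(tp$trajectory$coordinates[1, , ], ncol = 3))
  f4 <- bead_frame(matrix(tp$trajectory$coordinates[4, , ], ncol = 3))
  expect_equal(M[1, 4], subset_rmsd(f1, f4), tolerance = 1e-10)
})
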