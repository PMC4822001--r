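# Shared fixtures and independent oracles used across the suite.

# Exact reversible MSM from a symmetric count matrix: the detailed-balance
# MLE then equals counts / rowSums(counts) with pi proportional to the row
# sums, so models with exactly known T and pi can be built.
exact_msm <- function(counts, lag_ns = 1) {
  estimate_msm(structure(list(counts = counts, lag = 1L, lag_ns = lag_ns,
                              total_frames = sum(counts)),
                         class = "count_matrix"))
}

# Single-frame trajectory from a beads x 3 coordinate matrix (one CA
# pseudo-atom per residue).
bead_frame <- function(coords, frame_spacing = 0.1) {
  xyz <- array(0, c(1, nrow(coords), 3))
  xyz[1, , ] <- coords
  top <- data.frame(resid = seq_len(nrow(coords)), resname = "BEA",
                    atom = "CA", element = "C")
  trajectory(xyz, top, frame_spacing)
}

# Independent dihedral oracle: Gram-Schmidt projection formulation (the
# implementation uses atan2 of cross products).
dihedral_gs <- function(p1, p2, p3, p4) {
  a1 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  b2n <- b2 / sqrt(sum(b2^2))
  u <- a1 - sum(a1 * b2n) * b2n
  v <- b3 - sum(b3 * b2n) * b2n
  ang <- acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1))
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  # sign from the right-hand rule about b2; cis (eclipsed) = 0
  s <- sum(cr * b2n)
  if (s == 0) ang else sign(s) * ang
}

# All simple paths from any state in A to any state in B along positive
# edges of `cap`, with their bottleneck capacities. Exponential; use on
# tiny networks only.
enumerate_simple_paths <- function(cap, A, B) {
  n <- nrow(cap)
  out <- list()
  recurse <- function(path, width) {
    u <- path[length(path)]
    if (u %in% B) {
      out[[length(out) + 1]] <<- list(states = path, bottleneck = width)
      return(invisible())
    }
    for (v in which(cap[u, ] > 0)) {
      if (v %in% path) next
      recurse(c(path, v), min(width, cap[u, v]))
    }
  }
  for (a in A) recurse(a, Inf)
  out
}

# A random reversible transition matrix from a random symmetric weight
# matrix (every such chain satisfies detailed balance).
random_reversible_T <- function(n, seed) {
  set.seed(seed)
  W <- matrix(runif(n * n, 0.05, 1), n, n)
  W <- (W + t(W)) / 2
  W / rowSums(W)
}

# Naive O(n) sliding-window transition recount.
count_oracle <- function(states, lag, n_states) {
  counts <- matrix(0, n_states, n_states)
  for (t in seq_len(length(states) - lag))
    counts[states[t], states[t + lag]] <-
      counts[states[t], states[t + lag]] + 1
  counts
}
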