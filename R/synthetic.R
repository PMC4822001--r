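# Ground-truth generators. Each one is a pure function of its arguments
# including the seed: the global RNG state is saved and restored, so calling
# a generator never perturbs an enclosing simulation.

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.check_stochastic <- function(T, tol = 1e-8) {
  if (!is.matrix(T) || nrow(T) != ncol(T))
    stop("transition matrix must be square")
  if (any(T < 0))
    stop("transition matrix has negative entries in row ",
         which(apply(T, 1, function(r) any(r < 0)))[1])
  rs <- rowSums(T)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    stop("transition matrix row ", bad[1], " sums to ",
         format(rs[bad[1]], digits = 12), ", not 1")
  invisible(TRUE)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of `T` for eigenvalue 1, normalized to sum to 1.
#'
#' @param T square row-stochastic matrix.
#' @return numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(T) {
  .check_stochastic(T)
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10))
    stop("leading eigenvector is not nonnegative; chain may be reducible")
  pmax(v, 0) / sum(pmax(v, 0))
}

.is_irreducible <- function(T) {
  g <- igraph::graph_from_adjacency_matrix(T > 0, mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

#' Sample a discrete-state Markov chain
#'
#' Draws a state sequence from a known row-stochastic transition matrix.
#' Used as the exactly-known ground truth for MSM estimation.
#'
#' @param T square row-stochastic transition matrix.
#' @param n_steps number of states to generate (>= 1).
#' @param start 1-based start state, or `"stationary"` to draw the start
#'   from the stationary distribution (requires an irreducible chain).
#' @param seed RNG seed.
#' @return integer vector of 1-based state indices, length `n_steps`.
#' @examples
#' T <- matrix(c(0.95, 0.05, 0.10, 0.90), 2, byrow = TRUE)
#' s <- sample_markov_chain(T, 1000, start = 1, seed = 42)
#' table(s) / length(s)  # approaches the stationary split (2/3, 1/3)
#' @export
sample_markov_chain <- function(T, n_steps, start = "stationary", seed = 42) {
  .check_stochastic(T)
  if (n_steps < 1) stop("'n_steps' must be >= 1")
  .with_seed(seed, {
    if (identical(start, "stationary")) {
      if (!.is_irreducible(T))
        stop("start = \"stationary\" requires an irreducible chain")
      pi0 <- stationary_distribution(T)
      s0 <- sample.int(nrow(T), 1, prob = pi0)
    } else {
      s0 <- as.integer(start)
      if (s0 < 1 || s0 > nrow(T)) stop("start state out of range")
    }
    cumT <- t(apply(T, 1, cumsum))
    if (nrow(T) == 1L) cumT <- matrix(cumT, 1)
    .markov_chain_cpp(cumT, s0 - 1L, as.integer(n_steps)) + 1L
  })
}

#' Quartic multi-well potential specifications
#'
#' `double_well_1d(h)` defines the dimensionless potential
#' `beta*U(x) = h*(x^2 - 1)^2` with minima at x = -1, +1 and a barrier of
#' height `h` (in kT) at x = 0. `double_well_2d(h1, h2)` is the separable
#' two-dimensional analogue; with `h1 >> h2` the slow relaxation is along x.
#'
#' @param h,h1,h2 barrier heights in units of kT.
#' @return a potential specification consumed by [brownian_dynamics()].
#' @export
double_well_1d <- function(h) {
  stopifnot(is.numeric(h), h >= 0)
  structure(list(h = h), class = "quartic_potential")
}

#' @rdname double_well_1d
#' @export
double_well_2d <- function(h1, h2) {
  stopifnot(h1 >= 0, h2 >= 0)
  structure(list(h = c(h1, h2)), class = "quartic_potential")
}

#' Evaluate a quartic potential (in kT) at positions
#'
#' @param potential a specification from [double_well_1d()] or
#'   [double_well_2d()].
#' @param x numeric vector (1D) or matrix with one column per dimension.
#' @return beta*U at each position.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "quartic_potential"))
  h <- potential$h
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (ncol(x) != length(h)) stop("dimension mismatch with potential")
  rowSums(sweep((x^2 - 1)^2, 2, h, `*`))
}

#' Overdamped Brownian dynamics on a multi-well potential
#'
#' Integrates the overdamped Langevin equation
#' `dx = -D * grad(beta*U) dt + sqrt(2 D dt) dW` with the Euler-Maruyama
#' scheme on a quartic potential whose stationary density
#' `exp(-beta*U)` is known in closed form. A desk-scale stand-in for MD
#' with exact ground truth.
#'
#' @param potential a [double_well_1d()] / [double_well_2d()] specification.
#' @param beta multiplier applied to the potential (the specification is
#'   already dimensionless, so `beta = 1` by default).
#' @param diffusion diffusion coefficient D (length^2 / time).
#' @param dt integration time step.
#' @param n_steps number of steps; output has `n_steps + 1` frames.
#' @param x0 start position (default: the minimum at +1 in every dimension).
#' @param seed RNG seed.
#' @return numeric matrix `(n_steps + 1) x dim` of positions.
#' @export
brownian_dynamics <- function(potential, beta = 1, diffusion = 1, dt,
                              n_steps, x0 = NULL, seed = 42) {
  stopifnot(inherits(potential, "quartic_potential"),
            dt > 0, n_steps >= 1, diffusion > 0, beta > 0)
  h <- beta * potential$h
  dim <- length(h)
  if (is.null(x0)) x0 <- rep(1, dim)
  if (length(x0) != dim) stop("x0 has wrong dimension")
  .with_seed(seed,
    .brownian_quartic_cpp(h, as.numeric(x0), diffusion, dt,
                          as.integer(n_steps)))
}

# Two reference 12-bead geometries: an extended chain and a hairpin.
# Several inter-bead distances differ by far more than 4 A between them
# (e.g. beads 1-12: ~41.8 A extended vs ~5.5 A hairpin).
.polymer_references <- function() {
  n <- 12L
  spacing <- 3.8
  open <- cbind(x = (seq_len(n) - 1) * spacing, y = 0, z = 0)
  half <- n / 2
  compact <- rbind(
    cbind(x = (seq_len(half) - 1) * spacing, y = 0, z = 0),
    cbind(x = (half:1 - 1) * spacing, y = 5.5, z = 0))
  list(open = unname(open), compact = unname(compact))
}

#' Two-state toy bead polymer
#'
#' Generates a trajectory of a 12-bead chain that jumps between two
#' metastable reference geometries ("open" and "compact") under a symmetric
#' two-state Markov chain, with isotropic Gaussian coordinate noise. The
#' hidden labels are returned, so the full featurization-to-MSM pipeline can
#' be validated blind against known state populations and switch rates.
#'
#' @param n_frames number of frames.
#' @param switch_prob per-frame probability of switching reference geometry
#'   (symmetric, in (0, 1); the hidden chain has T12 = T21 = switch_prob).
#' @param noise_sigma isotropic Gaussian noise per coordinate, Angstrom.
#' @param seed RNG seed.
#' @param frame_spacing frame spacing in ns.
#' @return list with `trajectory` (a [trajectory()] of one CA bead per
#'   residue), `labels` (hidden state per frame, 1 = open, 2 = compact) and
#'   `references` (the two noise-free geometries).
#' @export
toy_polymer <- function(n_frames, switch_prob = 0.02, noise_sigma = 0.3,
                        seed = 42, frame_spacing = 0.1) {
  if (switch_prob <= 0 || switch_prob >= 1)
    stop("'switch_prob' must lie strictly between 0 and 1")
  refs <- .polymer_references()
  n_beads <- nrow(refs$open)
  ref_rmsd <- sqrt(mean(rowSums((refs$open - refs$compact)^2)))
  if (ref_rmsd < 2 * noise_sigma)
    warning("noise_sigma is large enough that the reference geometries ",
            "are not separable (inter-reference RMSD ",
            format(ref_rmsd, digits = 3), " A < 2*noise_sigma)")
  Tchain <- matrix(c(1 - switch_prob, switch_prob,
                     switch_prob, 1 - switch_prob), 2, byrow = TRUE)
  labels <- sample_markov_chain(Tchain, n_frames, start = 1, seed = seed)
  coords <- .with_seed(seed + 1, {
    noise <- array(rnorm(n_frames * n_beads * 3, sd = noise_sigma),
                   c(n_frames, n_beads, 3))
    base <- array(0, c(n_frames, n_beads, 3))
    for (s in 1:2) {
      idx <- which(labels == s)
      if (!length(idx)) next
      ref <- if (s == 1) refs$open else refs$compact
      for (d in 1:3) base[idx, , d] <- matrix(ref[, d], length(idx),
                                              n_beads, byrow = TRUE)
    }
    base + if (noise_sigma > 0) noise else 0
  })
  top <- data.frame(resid = seq_len(n_beads), resname = "BEA",
                    atom = "CA", element = "C")
  list(trajectory = trajectory(coords, top, frame_spacing),
       labels = labels, references = refs)
}

#' Correlated torsion-angle pairs
#'
#' Pairs of angles from a bivariate Gaussian with correlation `rho` and
#' standard deviation `sigma`, wrapped to (-pi, pi]. With the default
#' `sigma = 0.3` rad the wrapping correction to the mutual information is
#' below 1e-6 nat, so the Gaussian closed form
#' `MI = -0.5 * log(1 - rho^2)` serves as the exact reference.
#'
#' @param rho correlation in `[-1, 1]`.
#' @param n number of pairs.
#' @param seed RNG seed.
#' @param sigma marginal standard deviation in radians.
#' @return list with angle vectors `a` and `b` (radians in (-pi, pi]).
#' @export
correlated_torsions <- function(rho, n, seed = 42, sigma = 0.3) {
  if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]")
  .with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    a <- sigma * z1
    b <- sigma * (rho * z1 + sqrt(1 - rho^2) * z2)
    wrap <- function(x) ((x + pi) %% (2 * pi)) - pi
    list(a = wrap(a), b = wrap(b))
  })
}

#' Unit vectors uniform on a spherical cap
#'
#' Samples unit 3-vectors uniformly over the cap of semi-angle `theta0`
#' about +z. The generalized order parameter of this "diffusion in a cone"
#' ensemble is `S2 = (cos(theta0) * (1 + cos(theta0)) / 2)^2`, the standard
#' closed form used to validate [order_parameters_s2()].
#'
#' @param theta0 cone semi-angle in radians, in `[0, pi]`.
#' @param n number of vectors.
#' @param seed RNG seed.
#' @return `n x 3` matrix of unit vectors.
#' @export
cone_vectors <- function(theta0, n, seed = 42) {
  if (theta0 < 0 || theta0 > pi) stop("'theta0' must lie in [0, pi]")
  .with_seed(seed, {
    cost <- runif(n, min = cos(theta0), max = 1)
    phi <- runif(n, 0, 2 * pi)
    sint <- sqrt(pmax(0, 1 - cost^2))
    cbind(sint * cos(phi), sint * sin(phi), cost)
  })
}

#' Closed-form order parameter of the cone model
#' @param theta0 cone semi-angle, radians.
#' @return the S2 value of uniform orientation within the cone.
#' @export
cone_s2 <- function(theta0) (cos(theta0) * (1 + cos(theta0)) / 2)^2
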