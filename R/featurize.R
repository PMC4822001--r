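# Contact-map featurization: each frame becomes a vector of minimum
# heavy-atom distances over all residue pairs separated in sequence by at
# least `min_separation` residues. This vector representation |X> is the
# input space for tICA.

#' Contact-map minimum-distance features
#'
#' For every residue pair (i, j) with `j - i >= min_separation`, computes
#' the per-frame minimum Euclidean distance between the heavy atoms of the
#' two residues.
#'
#' @param traj a [trajectory()].
#' @param min_separation minimum sequence separation `j - i` for a pair to
#'   be included (default 3).
#' @return object of class `"contact_features"`: list with `values`
#'   (frames x d matrix, Angstrom), `pair_labels` (d x 2 matrix of residue
#'   index pairs, i < j) and `frame_spacing`.
#' @examples
#' tp <- toy_polymer(50, seed = 1)
#' cf <- contact_features(tp$trajectory)
#' dim(cf$values)
#' @export
contact_features <- function(traj, min_separation = 3) {
  stopifnot(inherits(traj, "trajectory"))
  res <- .residue_ids(traj$topology)
  nres <- length(res)
  # separation in residue sequence index, not in positional order
  pairs <- which(outer(seq_len(nres), seq_len(nres),
                       function(i, j) (res[j] - res[i]) >= min_separation),
                 arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  if (!nrow(pairs)) stop("no residue pair passes the separation filter")
  heavy <- lapply(res, function(r) .heavy_atoms(traj$topology, r))
  nf <- n_frames(traj)
  vals <- matrix(NA_real_, nf, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    ai <- heavy[[pairs[p, 1]]]
    aj <- heavy[[pairs[p, 2]]]
    dmin <- rep(Inf, nf)
    for (a in ai) for (b in aj) {
      d2 <- (traj$coordinates[, a, 1] - traj$coordinates[, b, 1])^2 +
        (traj$coordinates[, a, 2] - traj$coordinates[, b, 2])^2 +
        (traj$coordinates[, a, 3] - traj$coordinates[, b, 3])^2
      dmin <- pmin(dmin, d2)
    }
    vals[, p] <- sqrt(dmin)
  }
  labels <- cbind(i = res[pairs[, 1]], j = res[pairs[, 2]])
  structure(list(values = vals, pair_labels = labels,
                 frame_spacing = traj$frame_spacing),
            class = "contact_features")
}

#' @export
print.contact_features <- function(x, ...) {
  cat(sprintf("<contact_features> %d frames x %d residue pairs\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-frame distance between one residue pair
#'
#' @param traj a [trajectory()].
#' @param pair length-2 vector of residue sequence indices.
#' @param mode `"min_heavy"` (minimum heavy-atom distance, consistent with
#'   [contact_features()]) or `"c_alpha"` (CA-CA distance).
#' @return numeric vector, one distance (Angstrom) per frame.
#' @export
pair_distance <- function(traj, pair, mode = c("min_heavy", "c_alpha")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "trajectory"), length(pair) == 2)
  top <- traj$topology
  if (!all(pair %in% top$resid))
    stop("residue(s) not in topology: ",
         paste(setdiff(pair, top$resid), collapse = ", "))
  if (mode == "c_alpha") {
    idx <- vapply(pair, function(r) {
      ca <- which(top$resid == r & top$atom == "CA")
      if (!length(ca)) stop("residue ", r, " has no CA atom")
      ca[1]
    }, integer(1))
    return(sqrt(rowSums((traj$coordinates[, idx[1], , drop = FALSE] -
                         traj$coordinates[, idx[2], , drop = FALSE])^2,
                        dims = 1)))
  }
  ai <- .heavy_atoms(top, pair[1])
  aj <- .heavy_atoms(top, pair[2])
  dmin <- rep(Inf, n_frames(traj))
  for (a in ai) for (b in aj) {
    d2 <- (traj$coordinates[, a, 1] - traj$coordinates[, b, 1])^2 +
      (traj$coordinates[, a, 2] - traj$coordinates[, b, 2])^2 +
      (traj$coordinates[, a, 3] - traj$coordinates[, b, 3])^2
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Classify frames as partially unfolded
#'
#' Local-unfolding indicator based on two inter-CA distances that report on
#' unwinding of helix G (Met124-Ala128) and deformation of the second
#' calcium-binding site (Ala128-Gly134). A frame is partially unfolded when
#' either distance exceeds its lower cutoff (11 and 15 Angstrom
#' respectively): the two deformations are alternative local-unfolding
#' modes, so the rule combines them with OR.
#'
#' @param d_m124_a128 Met124-Ala128 CA distance(s), Angstrom.
#' @param d_a128_g134 Ala128-Gly134 CA distance(s), Angstrom.
#' @param cutoffs lower cutoffs, Angstrom (default `c(11, 15)`).
#' @param rule `"or"` (default) or `"and"`.
#' @return logical vector, TRUE = partially unfolded.
#' @export
classify_partial_unfolding <- function(d_m124_a128, d_a128_g134,
                                       cutoffs = c(11, 15),
                                       rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (any(d_m124_a128 < 0) || any(d_a128_g134 < 0))
    stop("distances must be nonnegative")
  a <- d_m124_a128 > cutoffs[1]
  b <- d_a128_g134 > cutoffs[2]
  if (rule == "or") a | b else a & b
}

# Signed dihedral angle about the 2-3 bond for per-frame coordinate
# matrices (IUPAC sign convention: cis = 0, trans = +/- pi).
.dihedral <- function(p1, p2, p3, p4) {
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  b0 <- p1 - p2
  b1 <- p3 - p2
  b1 <- b1 / sqrt(rowSums(b1^2))
  b2 <- p4 - p3
  v <- b0 - rowSums(b0 * b1) * b1
  w <- b2 - rowSums(b2 * b1) * b1
  atan2(rowSums(cross(b1, v) * w), rowSums(v * w))
}

#' Torsion angles from atom quadruples
#'
#' Computes signed dihedral angles for a list of four-atom index quadruples
#' (IUPAC convention: right-handed, cis = 0, trans = pi). Quadruples whose
#' atoms are missing from the topology are skipped with a warning and
#' recorded in the `skipped` attribute.
#'
#' @param traj a [trajectory()].
#' @param quadruples list of length-4 integer vectors of atom indices, or a
#'   4-column matrix (one torsion per row). Names are carried through.
#' @return matrix frames x torsions, radians in (-pi, pi]; attribute
#'   `skipped` lists any dropped torsion.
#' @export
torsion_angles <- function(traj, quadruples) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.matrix(quadruples))
    quadruples <- split(quadruples, row(quadruples))
  n_atoms <- nrow(traj$topology)
  ok <- vapply(quadruples, function(q)
    length(q) == 4 && all(q >= 1 & q <= n_atoms), logical(1))
  if (any(!ok))
    warning(sum(!ok), " torsion(s) skipped: atom indices out of range")
  kept <- quadruples[ok]
  out <- matrix(NA_real_, n_frames(traj), length(kept))
  for (k in seq_along(kept)) {
    q <- kept[[k]]
    grab <- function(a) matrix(traj$coordinates[, a, ], ncol = 3)
    out[, k] <- .dihedral(grab(q[1]), grab(q[2]), grab(q[3]), grab(q[4]))
  }
  colnames(out) <- names(kept)
  attr(out, "skipped") <- which(!ok)
  out
}

# Optimal-superposition rotation (Kabsch, proper rotation enforced):
# returns R minimizing ||A R - B|| over proper rotations.
.kabsch <- function(A, B) {
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' RMSD over a residue subset after optimal superposition
#'
#' Least-squares superposes the heavy atoms of the chosen residues in two
#' frames (translation + proper rotation) and returns the RMSD. This is the
#' metric behind the interface-topology macrostate models.
#'
#' @param frame_a,frame_b `atoms x 3` coordinate matrices sharing one
#'   topology, or `trajectory` objects with one frame each.
#' @param topology atom-level topology shared by both frames (not needed if
#'   trajectories are supplied).
#' @param residue_subset residue sequence indices to superpose over
#'   (default: all).
#' @return RMSD in Angstrom.
#' @export
subset_rmsd <- function(frame_a, frame_b, topology = NULL,
                        residue_subset = NULL) {
  as_mat <- function(x) {
    if (inherits(x, "trajectory")) {
      if (n_frames(x) != 1L) stop("supply single-frame trajectories")
      matrix(x$coordinates[1, , ], ncol = 3)
    } else as.matrix(x)
  }
  if (is.null(topology) && inherits(frame_a, "trajectory"))
    topology <- frame_a$topology
  A <- as_mat(frame_a); B <- as_mat(frame_b)
  if (!is.null(residue_subset)) {
    if (is.null(topology)) stop("residue subset requires a topology")
    idx <- unlist(lapply(residue_subset, function(r)
      .heavy_atoms(topology, r)))
    A <- A[idx, , drop = FALSE]
    B <- B[idx, , drop = FALSE]
  }
  if (nrow(A) != nrow(B))
    stop("atom-count mismatch between frames: ", nrow(A), " vs ", nrow(B))
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  R <- .kabsch(Ac, Bc)
  sqrt(mean(rowSums((Ac %*% R - Bc)^2)))
}

#' Pairwise subset-RMSD matrix over trajectory frames
#'
#' @param traj a [trajectory()].
#' @param residue_subset residues defining the RMSD (default all).
#' @param frames frame indices to include (default all).
#' @return symmetric matrix of pairwise RMSD, Angstrom.
#' @export
rmsd_matrix <- function(traj, residue_subset = NULL, frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  idx <- if (is.null(residue_subset)) seq_len(nrow(traj$topology)) else
    unlist(lapply(residue_subset, function(r)
      .heavy_atoms(traj$topology, r)))
  mats <- lapply(frames, function(f) {
    m <- matrix(traj$coordinates[f, idx, ], ncol = 3)
    sweep(m, 2, colMeans(m))
  })
  n <- length(mats)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    R <- .kabsch(mats[[i]], mats[[j]])
    out[i, j] <- out[j, i] <- sqrt(mean(rowSums((mats[[i]] %*% R -
                                                   mats[[j]])^2)))
  }
  out
}
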