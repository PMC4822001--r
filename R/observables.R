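# Experiment-facing observables computed from weighted conformational
# ensembles: generalized NMR order parameters (S2), torsion-angle mutual
# information with a shuffle-null correction, and comparison against
# experimental tables.

#' Generalized order parameter S2 of a bond-vector ensemble
#'
#' The standard isotropic-ensemble formula:
#' `S2 = (3 * (<x^2>^2 + <y^2>^2 + <z^2>^2 + 2<xy>^2 + 2<xz>^2 + 2<yz>^2) - 1) / 2`
#' with `< >` the (weighted) ensemble average of products of the unit
#' bond-vector components. `S2 = 1` for a rigid vector, approaches 0 for
#' isotropic disorder.
#'
#' @param vectors `n x 3` matrix of unit vectors (one ensemble member per
#'   row), or a 3D array `frames x residues x 3` for several vectors at
#'   once.
#' @param weights per-frame probability weights (default uniform). Must
#'   sum to 1 within 1e-8 (they are renormalized after the check).
#' @return a single S2 value, or a per-residue vector for array input.
#' @examples
#' order_parameters_s2(cone_vectors(pi / 4, 5000, seed = 2))
#' @export
order_parameters_s2 <- function(vectors, weights = NULL) {
  if (length(dim(vectors)) == 3L) {
    return(vapply(seq_len(dim(vectors)[2]), function(r)
      order_parameters_s2(matrix(vectors[, r, ], ncol = 3), weights),
      numeric(1)))
  }
  v <- as.matrix(vectors)
  if (ncol(v) != 3) stop("'vectors' must have 3 columns")
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12)) stop("zero-length bond vector(s)")
  if (any(abs(nrm - 1) > 1e-6))
    stop("bond vectors must be unit-norm (max deviation ",
         format(max(abs(nrm - 1)), digits = 3), ")")
  n <- nrow(v)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("one weight per frame required")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1")
  w <- weights / sum(weights)
  m <- function(a, b) sum(w * v[, a] * v[, b])
  (3 * (m(1, 1)^2 + m(2, 2)^2 + m(3, 3)^2 +
          2 * m(1, 2)^2 + 2 * m(1, 3)^2 + 2 * m(2, 3)^2) - 1) / 2
}

#' Per-frame MSM weights for ensemble averages
#'
#' The canonical reweighting of pooled frames by an MSM: each frame of
#' state i receives weight `pi_i / n_frames_in_state_i`, so the weighted
#' ensemble reproduces the model's equilibrium distribution.
#'
#' @param model a [estimate_msm()] model.
#' @param states per-frame state labels (original indices). Frames outside
#'   the active set get weight 0.
#' @return numeric weight per frame, summing to 1.
#' @export
msm_frame_weights <- function(model, states) {
  stopifnot(inherits(model, "msm_model"))
  idx <- match(states, model$active_set)
  w <- numeric(length(states))
  inside <- !is.na(idx)
  counts <- tabulate(idx[inside], nbins = length(model$pi))
  if (any(counts == 0 & model$pi > 0))
    stop("active state(s) without pooled frames: ",
         paste(model$active_set[counts == 0], collapse = ", "))
  w[inside] <- model$pi[idx[inside]] / counts[idx[inside]]
  w / sum(w)
}

# Bin edges for one angle series. "adaptive" = equal-mass (quantile) bins
# over the observed range, which keeps the discretization fine where the
# density lives; "fixed" = fixed-width bins over the full circle (-pi, pi].
.mi_edges <- function(x, bins, scheme) {
  if (scheme == "fixed") return(seq(-pi, pi, length.out = bins + 1))
  e <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                       names = FALSE))
  if (length(e) < 3) e <- range(x) + c(-1e-9, 1e-9)
  e
}

# Weighted 2D histogram MI in nats given per-series bin edges.
.mi_binned <- function(a, b, w, edges_a, edges_b) {
  na <- length(edges_a) - 1L
  nb <- length(edges_b) - 1L
  ia <- pmin(pmax(findInterval(a, edges_a, rightmost.closed = TRUE), 1), na)
  ib <- pmin(pmax(findInterval(b, edges_b, rightmost.closed = TRUE), 1), nb)
  acc <- rowsum(w, (ib - 1L) * na + ia)
  p <- numeric(na * nb)
  p[as.integer(rownames(acc))] <- acc
  p <- matrix(p, na, nb)
  p <- p / sum(p)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' Mutual information between two torsion-angle series
#'
#' Histogram estimator of `MI = sum p(a,b) log[p(a,b)/(p(a)p(b))]` on a
#' `bins x bins` grid, in nats. By default each axis is partitioned into
#' equal-mass (quantile) bins over the observed range, which keeps the
#' discretization loss small for torsions confined to one rotameric well;
#' `binning = "fixed"` uses fixed-width bins over the full circle
#' (-pi, pi] instead. The finite-sample bias is removed by a shuffle
#' null: the mean MI of `n_shuffle` independent permutations of one
#' series is subtracted and the result floored at 0.
#'
#' @param angles_a,angles_b angle series in radians.
#' @param weights per-frame weights (default uniform).
#' @param bins number of bins per axis (default 24).
#' @param correction `"shuffle_null"` (default) or `"none"`.
#' @param binning `"adaptive"` (equal-mass, default) or `"fixed"`.
#' @param n_shuffle number of permutations for the null (default 20).
#' @param seed RNG seed for the permutations.
#' @return mutual information in nats (scalar).
#' @examples
#' ct <- correlated_torsions(0.8, 20000, seed = 3)
#' torsion_mutual_information(ct$a, ct$b)  # near -0.5 * log(1 - 0.64)
#' @export
torsion_mutual_information <- function(angles_a, angles_b, weights = NULL,
                                       bins = 24,
                                       correction = c("shuffle_null",
                                                      "none"),
                                       binning = c("adaptive", "fixed"),
                                       n_shuffle = 20, seed = 42) {
  correction <- match.arg(correction)
  binning <- match.arg(binning)
  if (length(angles_a) != length(angles_b))
    stop("angle series must have equal length")
  if (bins < 2) stop("'bins' must be >= 2")
  n <- length(angles_a)
  if (n < bins^2 / 10)
    warning("fewer than bins^2/10 frames; MI estimate is undersampled")
  if (is.null(weights)) weights <- rep(1 / n, n)
  weights <- weights / sum(weights)
  ea <- .mi_edges(angles_a, bins, binning)
  eb <- .mi_edges(angles_b, bins, binning)
  mi <- .mi_binned(angles_a, angles_b, weights, ea, eb)
  if (correction == "none") return(mi)
  null_mi <- .with_seed(seed, vapply(seq_len(n_shuffle), function(k) {
    perm <- sample.int(n)
    .mi_binned(angles_a, angles_b[perm], weights, ea, eb)
  }, numeric(1)))
  max(mi - mean(null_mi), 0)
}

#' Aggregate torsion-level MI to residue-level coupling
#'
#' @param mi symmetric torsion x torsion MI matrix.
#' @param mapping integer (or factor) residue index per torsion.
#' @param mode `"max"` (default) or `"sum"` over the torsion pairs of a
#'   residue pair.
#' @return residue x residue coupling matrix with residue labels.
#' @export
aggregate_residue_coupling <- function(mi, mapping, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  mi <- as.matrix(mi)
  if (length(mapping) != nrow(mi))
    stop("'mapping' must assign a residue to every torsion")
  res <- sort(unique(mapping))
  agg <- matrix(0, length(res), length(res),
                dimnames = list(res, res))
  for (i in seq_along(res)) for (j in seq_along(res)) {
    block <- mi[mapping == res[i], mapping == res[j], drop = FALSE]
    agg[i, j] <- if (mode == "max") max(block) else sum(block)
  }
  agg
}

#' Correlate computed order parameters with experimental values
#'
#' Pearson correlation over residues present on both sides, plus
#' per-residue residuals and a listing of residues missing from either
#' set.
#'
#' @param computed named numeric vector of computed S2 (names = residue
#'   indices), or a data.frame with columns `resid`, `s2`.
#' @param experimental same format for the experimental values.
#' @return list with `r` (Pearson correlation), `residuals` (computed -
#'   experimental, named by residue), `n`, `missing_computed`,
#'   `missing_experimental`.
#' @export
correlate_with_experiment <- function(computed, experimental) {
  as_named <- function(x) {
    if (is.data.frame(x)) setNames(x$s2, x$resid)
    else if (!is.null(names(x))) x
    else stop("values must be named by residue index")
  }
  comp <- as_named(computed)
  expt <- as_named(experimental)
  shared <- intersect(names(comp), names(expt))
  if (length(shared) < 3)
    stop("need at least 3 overlapping residues, got ", length(shared))
  list(r = cor(comp[shared], expt[shared]),
       residuals = comp[shared] - expt[shared],
       n = length(shared),
       missing_computed = setdiff(names(expt), names(comp)),
       missing_experimental = setdiff(names(comp), names(expt)))
}
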