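# Discretization of the reduced space. Microstates come from greedy
# farthest-point k-centers in tIC space (a 2-approximation to the optimal
# covering radius); coarse interface-topology macrostates come from
# agglomerative clustering of a pairwise subset-RMSD matrix.

#' Greedy farthest-point k-centers clustering
#'
#' Picks the first center (by default frame 1, or uniformly at random under
#' `seed` when `first = "random"`), then repeatedly adds the point farthest
#' from its nearest existing center, until `k` centers exist. Every point
#' is assigned to its nearest center (Euclidean metric).
#'
#' @param points frames x p coordinate matrix (e.g. tIC projections).
#' @param k number of centers (<= number of frames).
#' @param seed RNG seed (used only when `first = "random"`).
#' @param first index of the first center, or `"random"`.
#' @param lengths optional integer vector partitioning the rows of
#'   `points` into consecutive source trajectories; assignments are then
#'   returned per source.
#' @return object of class `"kcenters"`: list with `centers` (k x p),
#'   `center_frames` (row indices of the chosen centers), `assignments`
#'   (per-frame 1-based state, or a list per source when `lengths` given),
#'   `covering_radius` (max distance of any point to its center).
#' @examples
#' pts <- cbind(c(0, 1, 9, 10))
#' k_centers(pts, k = 2)$assignments
#' @export
k_centers <- function(points, k, seed = 42, first = 1L, lengths = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("k = ", k, " exceeds number of frames (", n, ")")
  if (identical(first, "random"))
    first <- .with_seed(seed, sample.int(n, 1))
  centers <- integer(k)
  centers[1] <- as.integer(first)
  d2 <- rowSums(sweep(points, 2, points[centers[1], ], `-`)^2)
  assign <- rep(1L, n)
  if (k > 1) for (c in 2:k) {
    nxt <- which.max(d2)
    if (d2[nxt] == 0)
      message("duplicate points: effective number of centers is ", c - 1)
    centers[c] <- nxt
    nd2 <- rowSums(sweep(points, 2, points[nxt, ], `-`)^2)
    closer <- nd2 < d2
    assign[closer] <- c
    d2 <- pmin(d2, nd2)
  }
  assignments <- if (is.null(lengths)) assign else {
    stopifnot(sum(lengths) == n)
    split(assign, rep(seq_along(lengths), lengths))
  }
  structure(list(centers = points[centers, , drop = FALSE],
                 center_frames = centers,
                 assignments = assignments,
                 covering_radius = sqrt(max(d2)),
                 n_states = k),
            class = "kcenters")
}

#' @export
print.kcenters <- function(x, ...) {
  cat(sprintf("<kcenters> %d states, covering radius %.4g\n",
              x$n_states, x$covering_radius))
  invisible(x)
}

#' Interface-topology macrostates by hierarchical clustering
#'
#' Agglomerative clustering (average linkage by default) of a pairwise
#' RMSD matrix, cut at `n_macrostates` clusters. This is the coarse
#' five-state partition of the hydrophobic binding interface built from
#' equilibrium MSM trajectories.
#'
#' @param rmsd_mat symmetric pairwise RMSD matrix with zero diagonal
#'   (e.g. from [rmsd_matrix()]).
#' @param n_macrostates number of clusters (default 5).
#' @param linkage linkage criterion for [stats::hclust()]
#'   (default `"average"`).
#' @param weights optional per-frame probability weights used for the
#'   population estimates (default uniform).
#' @return object of class `"macrostates"`: list with `assignments`
#'   (per-frame label), `populations` (per-macrostate probability, sums to
#'   1), `representative_frames` (frame minimizing mean RMSD to its
#'   cluster), `n_macrostates`.
#' @export
hierarchical_macrostates <- function(rmsd_mat, n_macrostates = 5,
                                     linkage = "average", weights = NULL) {
  rmsd_mat <- as.matrix(rmsd_mat)
  if (!isSymmetric(unname(rmsd_mat), tol = 1e-8))
    stop("RMSD matrix must be symmetric")
  n <- nrow(rmsd_mat)
  if (n_macrostates > n) stop("more macrostates than frames")
  if (is.null(weights)) weights <- rep(1 / n, n)
  weights <- weights / sum(weights)
  hc <- hclust(as.dist(rmsd_mat), method = linkage)
  labels <- cutree(hc, k = n_macrostates)
  pops <- vapply(seq_len(n_macrostates), function(m)
    sum(weights[labels == m]), numeric(1))
  reps <- vapply(seq_len(n_macrostates), function(m) {
    idx <- which(labels == m)
    idx[which.min(rowMeans(rmsd_mat[idx, idx, drop = FALSE]))]
  }, integer(1))
  structure(list(assignments = labels, populations = pops,
                 representative_frames = reps,
                 n_macrostates = n_macrostates, linkage = linkage),
            class = "macrostates")
}

#' @export
print.macrostates <- function(x, ...) {
  cat(sprintf("<macrostates> %d states, populations: %s\n",
              x$n_macrostates,
              paste(format(x$populations, digits = 3), collapse = " ")))
  invisible(x)
}

#' Assign new frames to existing macrostates
#'
#' Nearest-representative assignment for frames not included in the
#' pairwise matrix (the O(n^2) clustering is done on a subsample; the rest
#' of an MSM trajectory is assigned here).
#'
#' @param macro a [hierarchical_macrostates()] model.
#' @param rmsd_to_reps frames x n_macrostates matrix of RMSD from each new
#'   frame to each representative frame.
#' @return integer vector of macrostate labels.
#' @export
assign_macrostates <- function(macro, rmsd_to_reps) {
  stopifnot(inherits(macro, "macrostates"),
            ncol(rmsd_to_reps) == macro$n_macrostates)
  apply(rmsd_to_reps, 1, which.min)
}
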