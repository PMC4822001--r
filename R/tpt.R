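# Transition path theory on an estimated MSM. Committors come from the
# boundary-value linear system; the net reactive flux is decomposed into
# pathways by deterministic widest-path (max-bottleneck) subtraction.

.check_sets <- function(model, A, B) {
  n <- nrow(model$T)
  A <- as.integer(A); B <- as.integer(B)
  if (!length(A) || !length(B)) stop("A and B must be non-empty")
  if (length(intersect(A, B))) stop("A and B must be disjoint")
  if (any(c(A, B) < 1 | c(A, B) > n))
    stop("state set references states outside the model (1..", n, ")")
  list(A = A, B = B)
}

#' Forward and backward committors
#'
#' The forward committor `q_plus[i]` is the probability that a trajectory
#' started in state i reaches the sink set B before the source set A. It
#' solves the linear system `(T q)_i = q_i` for i outside A and B with
#' boundary values 0 on A and 1 on B. The backward committor is computed
#' from the time-reversed chain; for a reversible model it equals
#' `1 - q_plus`.
#'
#' @param model a [estimate_msm()] model.
#' @param A,B disjoint non-empty sets of (active-set-relative, 1-based)
#'   state indices.
#' @return list with `q_plus` and `q_minus`, each length n.
#' @export
committors <- function(model, A, B) {
  stopifnot(inherits(model, "msm_model"))
  s <- .check_sets(model, A, B); A <- s$A; B <- s$B
  T <- model$T
  n <- nrow(T)
  interior <- setdiff(seq_len(n), c(A, B))
  q_plus <- numeric(n)
  q_plus[B] <- 1
  if (length(interior)) {
    M <- diag(length(interior)) - T[interior, interior, drop = FALSE]
    rhs <- rowSums(T[interior, B, drop = FALSE])
    sol <- tryCatch(solve(M, rhs), error = function(e)
      stop("committor system is singular (is B reachable from every ",
           "interior state?): ", conditionMessage(e)))
    q_plus[interior] <- sol
  }
  # time-reversed chain: Trev_ij = pi_j T_ji / pi_i
  Trev <- t(T * model$pi) / model$pi
  q_minus <- numeric(n)
  q_minus[A] <- 1
  if (length(interior)) {
    M <- diag(length(interior)) - Trev[interior, interior, drop = FALSE]
    rhs <- rowSums(Trev[interior, A, drop = FALSE])
    q_minus[interior] <- solve(M, rhs)
  }
  list(q_plus = q_plus, q_minus = q_minus)
}

#' Net reactive flux between two state sets
#'
#' Gross flux `f_ij = pi_i * q_minus_i * T_ij * q_plus_j` for i != j; the
#' net flux is `max(f_ij - f_ji, 0)`. The total A -> B flux is the net
#' flux leaving A (probability per lag time), which equals the net flux
#' entering B.
#'
#' @param model a [estimate_msm()] model.
#' @param A,B source and sink sets.
#' @param q optional committors from [committors()] (recomputed if
#'   missing).
#' @return object of class `"tpt_flux"`: list with `net_flux` (n x n),
#'   `gross_flux`, `total_flux`, `q_plus`, `q_minus`, `A`, `B`.
#' @export
reactive_flux <- function(model, A, B, q = NULL) {
  stopifnot(inherits(model, "msm_model"))
  s <- .check_sets(model, A, B); A <- s$A; B <- s$B
  if (is.null(q)) q <- committors(model, A, B)
  T <- model$T
  f <- (model$pi * q$q_minus) %o% q$q_plus * T
  diag(f) <- 0
  net <- pmax(f - t(f), 0)
  total <- sum(net[A, -A, drop = FALSE])
  structure(list(net_flux = net, gross_flux = f, total_flux = total,
                 q_plus = q$q_plus, q_minus = q$q_minus, A = A, B = B),
            class = "tpt_flux")
}

# Widest (max-bottleneck) A->B path on a capacity matrix; deterministic
# Dijkstra-style search, ties broken toward the smallest state index so
# the decomposition is reproducible. Returns NULL if no path remains.
.widest_path <- function(cap, A, B) {
  n <- nrow(cap)
  width <- rep(-Inf, n)
  prev <- rep(NA_integer_, n)
  width[A] <- Inf
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & width > 0)
    if (!length(cand)) return(NULL)
    u <- cand[order(-width[cand], cand)][1]
    if (u %in% B) break
    visited[u] <- TRUE
    for (v in which(cap[u, ] > 0)) {
      w <- min(width[u], cap[u, v])
      if (w > width[v] || (w == width[v] && !is.na(prev[v]) &&
                           u < prev[v])) {
        width[v] <- w
        prev[v] <- u
      }
    }
  }
  path <- u
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  list(path = path, bottleneck = width[u])
}

#' Decompose the net flux into its strongest pathways
#'
#' Iterative bottleneck decomposition: find the widest (maximum minimum
#' capacity) A -> B path through the net-flux network, record it with its
#' bottleneck flux, subtract that flux along the path, repeat until the
#' recorded pathways carry at least `stop_fraction` of the total flux or
#' no path remains.
#'
#' @param flux a [reactive_flux()] result.
#' @param stop_fraction fraction of total flux to account for
#'   (default 0.9).
#' @param max_paths safety cap on the number of pathways.
#' @return data.frame-free list of pathways: each element has `states`
#'   (1-based state sequence from A to B) and `flux`; the list carries
#'   attributes `total_flux` and `captured_flux`.
#' @export
top_pathways <- function(flux, stop_fraction = 0.9, max_paths = 1000) {
  stopifnot(inherits(flux, "tpt_flux"))
  cap <- flux$net_flux
  # remove edges into A and out of B so pathways end on first arrival
  cap[, flux$A] <- 0
  cap[flux$B, ] <- 0
  total <- flux$total_flux
  paths <- list()
  captured <- 0
  if (total <= 0) {
    warning("total flux is zero; no pathways")
  } else while (captured < stop_fraction * total &&
                length(paths) < max_paths) {
    wp <- .widest_path(cap, flux$A, flux$B)
    if (is.null(wp) || wp$bottleneck <= 0) break
    f <- wp$bottleneck
    for (e in seq_len(length(wp$path) - 1))
      cap[wp$path[e], wp$path[e + 1]] <-
        cap[wp$path[e], wp$path[e + 1]] - f
    paths[[length(paths) + 1]] <- list(states = wp$path, flux = f)
    captured <- captured + f
  }
  attr(paths, "total_flux") <- total
  attr(paths, "captured_flux") <- captured
  paths
}

#' Fraction of reactive flux visiting an intermediate set
#'
#' Of the decomposed pathways, the fraction of total flux carried by
#' pathways that contain at least one state of `intermediate_set`.
#'
#' @param flux a [reactive_flux()] result.
#' @param intermediate_set state indices, disjoint from A and B.
#' @param pathways optional precomputed [top_pathways()] list; by default
#'   pathways are decomposed to `stop_fraction = 1` so the fraction is
#'   over the full flux.
#' @return scalar in `[0, 1]`.
#' @export
flux_fraction_through <- function(flux, intermediate_set, pathways = NULL) {
  stopifnot(inherits(flux, "tpt_flux"))
  intermediate_set <- as.integer(intermediate_set)
  if (length(intersect(intermediate_set, c(flux$A, flux$B))))
    stop("intermediate set must be disjoint from A and B")
  if (!length(intermediate_set)) return(0)
  if (is.null(pathways))
    pathways <- top_pathways(flux, stop_fraction = 1)
  total <- attr(pathways, "total_flux")
  if (total <= 0) return(0)
  through <- vapply(pathways, function(p)
    if (any(p$states %in% intermediate_set)) p$flux else 0, numeric(1))
  sum(through) / total
}

#' One-call transition path analysis
#'
#' Convenience wrapper: committors, reactive flux and pathway
#' decomposition in one object.
#'
#' @inheritParams reactive_flux
#' @param stop_fraction passed to [top_pathways()].
#' @return object of class `"tpt_result"` combining the
#'   [reactive_flux()] fields with `pathways`.
#' @export
transition_paths <- function(model, A, B, stop_fraction = 0.9) {
  flux <- reactive_flux(model, A, B)
  res <- unclass(flux)
  res$pathways <- top_pathways(flux, stop_fraction = stop_fraction)
  class(res) <- c("tpt_result", "tpt_flux")
  res
}

#' @export
print.tpt_flux <- function(x, ...) {
  cat(sprintf("<tpt> total flux %.4g per lag, |A| = %d, |B| = %d\n",
              x$total_flux, length(x$A), length(x$B)))
  if (!is.null(x$pathways))
    cat(sprintf("%d pathways capturing %.1f%% of flux\n",
                length(x$pathways),
                100 * attr(x$pathways, "captured_flux") / x$total_flux))
  invisible(x)
}
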