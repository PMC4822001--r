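# Markov state model estimation. Transition counts are collected with a
# sliding window; the transition matrix is the detailed-balance-constrained
# maximum-likelihood estimate obtained by the standard self-consistent
# iteration on the largest strongly connected component of the count graph.

#' Count state-to-state transitions at a lag
#'
#' Sliding-window counts: every frame t with t + lag in range contributes
#' one (s_t, s_{t+lag}) pair. Pairs never cross trajectory boundaries.
#'
#' @param dtrajs integer vector of 1-based state labels, or a list of them
#'   (one per trajectory).
#' @param lag lag in frames (>= 1).
#' @param n_states total number of states (default: largest label seen).
#' @param frame_spacing ns per frame, carried into the model (default 1).
#' @return object of class `"count_matrix"`: list with `counts` (n x n),
#'   `lag` (frames), `lag_ns`, `total_frames`.
#' @examples
#' cm <- count_transitions(c(1, 1, 2, 2, 1, 2), lag = 1)
#' cm$counts
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL,
                              frame_spacing = 1) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag <- as.integer(lag)
  if (lag < 1) stop("'lag' must be >= 1 frame")
  dtrajs <- lapply(dtrajs, as.integer)
  if (is.null(n_states)) n_states <- max(unlist(dtrajs))
  usable <- vapply(dtrajs, length, integer(1)) > lag
  if (!any(usable)) stop("all trajectories are shorter than the lag")
  counts <- matrix(0, n_states, n_states)
  for (s in dtrajs[usable]) {
    n <- length(s)
    from <- s[seq_len(n - lag)]
    to <- s[(lag + 1):n]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    counts <- counts + unclass(tab)
  }
  dimnames(counts) <- NULL
  structure(list(counts = counts, lag = lag,
                 lag_ns = lag * frame_spacing,
                 total_frames = sum(vapply(dtrajs, length, integer(1)))),
            class = "count_matrix")
}

# Largest strongly connected component of the positive-count graph;
# ties broken toward the component with the larger total count.
.largest_scc <- function(counts) {
  g <- igraph::graph_from_adjacency_matrix(counts > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership, comp$no)
  weight <- vapply(seq_len(comp$no), function(c) {
    idx <- which(comp$membership == c)
    sum(counts[idx, idx])
  }, numeric(1))
  best <- order(-sizes, -weight)[1]
  sort(which(comp$membership == best))
}

#' Estimate a reversible Markov state model
#'
#' Restricts the counts to the largest strongly connected component
#' (ergodic trimming), then computes the detailed-balance-constrained
#' maximum-likelihood transition matrix by the self-consistent fixed-point
#' iteration: with `c_ij` the counts, `c_i` their row sums and `x_ij` the
#' estimated unconditional transition probabilities,
#' `x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j)` until the update changes
#' no element by more than `tol` (relative). Then `T_ij = x_ij / x_i` and
#' the stationary distribution is `pi_i = x_i`. Eigenvalues are computed
#' from the symmetric conjugate `D^(1/2) T D^(-1/2)` and are therefore
#' real; they are sorted descending with the Perron eigenvalue 1 first.
#'
#' @param counts a [count_transitions()] object (or a bare count matrix).
#' @param tol convergence tolerance on the relative change (default 1e-10).
#' @param max_iter iteration cap (default 1e6).
#' @param reversible if `FALSE`, uses naive symmetrization
#'   `(C + t(C))/2` instead of the maximum-likelihood iteration
#'   (comparison mode).
#' @return object of class `"msm_model"`: list with `T` (row-stochastic),
#'   `pi`, `eigenvalues`, `timescales` (ns, via [implied_timescales()]),
#'   `active_set` (original state indices retained), `lag`, `lag_ns`,
#'   `counts`.
#' @examples
#' s <- sample_markov_chain(matrix(c(.9, .1, .2, .8), 2, byrow = TRUE),
#'                          5000, seed = 3)
#' m <- estimate_msm(count_transitions(s, lag = 1))
#' m$T
#' @export
estimate_msm <- function(counts, tol = 1e-10, max_iter = 1e6,
                         reversible = TRUE) {
  if (is.matrix(counts))
    counts <- structure(list(counts = counts, lag = 1L, lag_ns = 1,
                             total_frames = NA_integer_),
                        class = "count_matrix")
  stopifnot(inherits(counts, "count_matrix"))
  C <- counts$counts
  if (sum(C) == 0) stop("count matrix has no transitions")
  active <- .largest_scc(C)
  if (!length(active)) stop("no connected set of states")
  C <- C[active, active, drop = FALSE]
  n <- nrow(C)
  if (!reversible) {
    S <- (C + t(C)) / 2
    T <- S / rowSums(S)
    pi <- rowSums(S) / sum(S)
  } else if (n == 1L) {
    T <- matrix(1, 1, 1); pi <- 1
  } else {
    Csym <- C + t(C)
    ci <- rowSums(C)
    X <- Csym / sum(Csym)          # initial reversible guess
    for (it in seq_len(max_iter)) {
      xi <- rowSums(X)
      denom <- outer(ci / xi, ci / xi, `+`)
      Xnew <- Csym / denom
      Xnew <- Xnew / sum(Xnew)
      diag(Xnew)[Csym[cbind(1:n, 1:n)] == 0] <- 0
      delta <- max(abs(Xnew - X) / pmax(X, 1e-300))
      X <- Xnew
      if (delta < tol) break
    }
    if (delta >= tol)
      stop("reversible MLE did not converge in ", max_iter,
           " iterations (residual ", format(delta, digits = 3), ")")
    pi <- rowSums(X)
    T <- X / pi
  }
  # Both estimators satisfy detailed balance, so the spectrum is real and
  # obtainable from the symmetric conjugate D^(1/2) T D^(-1/2).
  s <- sqrt(pi)
  Tsym <- (s %o% (1 / s)) * T
  Tsym <- (Tsym + t(Tsym)) / 2
  ev <- sort(eigen(Tsym, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  model <- structure(
    list(T = T, pi = pi, eigenvalues = ev, active_set = active,
         lag = counts$lag, lag_ns = counts$lag_ns, counts = counts$counts),
    class = "msm_model")
  model$timescales <- suppressWarnings(implied_timescales(model))
  model
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("<msm_model> %d states (of %d), lag %.4g ns\n",
              nrow(x$T), nrow(x$counts), x$lag_ns))
  cat("slowest timescales (ns):",
      format(head(x$timescales, 3), digits = 4), "\n")
  invisible(x)
}

#' Implied relaxation timescales
#'
#' For each non-Perron eigenvalue mu of T(tau), the implied timescale is
#' `-tau / log(mu)`. Eigenvalues within 1e-12 of 1 map to `Inf`;
#' nonpositive eigenvalues have no defined timescale and are returned as
#' `NA` with a warning.
#'
#' @param model a [estimate_msm()] model, or a numeric vector of
#'   eigenvalues (then `lag_ns` must be given).
#' @param lag_ns lag time in ns (taken from the model when omitted).
#' @return numeric vector of timescales in ns, sorted decreasing, one per
#'   non-Perron eigenvalue.
#' @export
implied_timescales <- function(model, lag_ns = NULL) {
  if (inherits(model, "msm_model")) {
    mu <- model$eigenvalues[-1]
    lag_ns <- model$lag_ns
  } else {
    mu <- model
    if (is.null(lag_ns)) stop("'lag_ns' required with bare eigenvalues")
  }
  out <- rep(NA_real_, length(mu))
  out[mu >= 1 - 1e-12] <- Inf
  ok <- mu > 0 & mu < 1 - 1e-12
  out[ok] <- -lag_ns / log(mu[ok])
  if (any(mu <= 0))
    warning(sum(mu <= 0), " nonpositive eigenvalue(s) have no implied ",
            "timescale")
  sort(out, decreasing = TRUE, na.last = TRUE)
}

#' Implied timescales versus lag and Markovian lag suggestion
#'
#' Builds an MSM at each candidate lag and tabulates the slowest implied
#' timescales. The suggested Markovian lag is the smallest tested lag whose
#' slowest timescale changes by less than `rel_tol` (default 10%) relative
#' to each of the next two tested lags.
#'
#' @param dtrajs discrete trajectory (or list).
#' @param lags integer vector of at least 3 candidate lags, in frames.
#' @param n_timescales how many slow timescales to keep per lag.
#' @param frame_spacing ns per frame.
#' @param rel_tol plateau criterion (default 0.1).
#' @return object of class `"lag_scan"`: list with `table` (data.frame:
#'   lag_frames, lag_ns, ts1, ts2, ...), `suggested_lag` (frames, NA if no
#'   plateau found).
#' @export
lag_scan <- function(dtrajs, lags, n_timescales = 3, frame_spacing = 1,
                     rel_tol = 0.1) {
  lags <- sort(unique(as.integer(lags)))
  if (length(lags) < 3) stop("need at least 3 lags to assess convergence")
  rows <- lapply(lags, function(l) {
    ts <- tryCatch({
      m <- estimate_msm(count_transitions(dtrajs, l,
                                          frame_spacing = frame_spacing))
      suppressWarnings(head(m$timescales, n_timescales))
    }, error = function(e) {
      warning("lag ", l, " skipped: ", conditionMessage(e))
      rep(NA_real_, n_timescales)
    })
    length(ts) <- n_timescales
    c(lag_frames = l, lag_ns = l * frame_spacing, ts)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab)[-(1:2)] <- paste0("ts", seq_len(n_timescales))
  suggested <- NA_integer_
  t1 <- tab$ts1
  for (i in seq_len(length(lags) - 2)) {
    if (any(!is.finite(t1[i:(i + 2)]))) next
    if (all(abs(t1[(i + 1):(i + 2)] - t1[i]) <= rel_tol * t1[i])) {
      suggested <- lags[i]
      break
    }
  }
  structure(list(table = tab, suggested_lag = suggested),
            class = "lag_scan")
}

#' @export
print.lag_scan <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("suggested Markovian lag:",
      if (is.na(x$suggested_lag)) "none found" else
        paste(x$suggested_lag, "frames"), "\n")
  invisible(x)
}

#' Free-energy landscape from an MSM-weighted histogram
#'
#' The equilibrium density over one or two order parameters is
#' `P(x, y) = sum_i pi_i * h_i(x, y)`, where `h_i` is the normalized
#' histogram of the order parameters restricted to microstate i. The free
#' energy is `F = -kT log P`, shifted so the minimum over occupied bins is
#' zero; empty bins are `NA`.
#'
#' @param model a [estimate_msm()] model.
#' @param states per-frame microstate labels (in original state indices,
#'   matching `model$active_set`); frames outside the active set are
#'   dropped.
#' @param x,y per-frame order parameter values (`y = NULL` for a 1D
#'   profile).
#' @param bins number of bins per axis (default 100).
#' @param kT thermal energy in kcal/mol (default 0.5924, i.e. 298 K).
#' @return object of class `"free_energy_grid"`: list with `x_edges`,
#'   `y_edges` (NULL in 1D), `F` (matrix or vector, kcal/mol), `P`,
#'   `kT`.
#' @export
free_energy_surface <- function(model, states, x, y = NULL, bins = 100,
                                kT = 0.5924) {
  stopifnot(inherits(model, "msm_model"), length(states) == length(x))
  keep <- states %in% model$active_set
  states <- match(states[keep], model$active_set)
  x <- x[keep]
  if (!is.null(y)) y <- y[keep]
  n_states <- nrow(model$T)
  missing_states <- setdiff(seq_len(n_states), unique(states))
  if (length(missing_states))
    stop("active state(s) without observable frames: ",
         paste(model$active_set[missing_states], collapse = ", "))
  x_edges <- seq(min(x), max(x), length.out = bins + 1)
  xb <- pmin(pmax(findInterval(x, x_edges, rightmost.closed = TRUE), 1),
             bins)
  if (is.null(y)) {
    P <- numeric(bins)
    for (i in seq_len(n_states)) {
      idx <- which(states == i)
      h <- tabulate(xb[idx], bins) / length(idx)
      P <- P + model$pi[i] * h
    }
    y_edges <- NULL
  } else {
    y_edges <- seq(min(y), max(y), length.out = bins + 1)
    yb <- pmin(pmax(findInterval(y, y_edges, rightmost.closed = TRUE), 1),
               bins)
    P <- matrix(0, bins, bins)
    for (i in seq_len(n_states)) {
      idx <- which(states == i)
      h <- matrix(0, bins, bins)
      tb <- table(factor(xb[idx], levels = 1:bins),
                  factor(yb[idx], levels = 1:bins))
      h[] <- tb / length(idx)
      P <- P + model$pi[i] * h
    }
  }
  F <- -kT * log(P)
  F[!is.finite(F)] <- NA
  F <- F - min(F, na.rm = TRUE)
  structure(list(x_edges = x_edges, y_edges = y_edges, F = F, P = P,
                 kT = kT),
            class = "free_energy_grid")
}

#' States to seed new sampling rounds
#'
#' The `n` states with the smallest stationary probability, ties broken by
#' state index — the adaptive-sampling rule of starting new simulations
#' from the least-populated states.
#'
#' @param model a [estimate_msm()] model.
#' @param n number of seed states.
#' @return integer vector of original state indices, ascending by
#'   population.
#' @export
adaptive_seed_states <- function(model, n) {
  stopifnot(inherits(model, "msm_model"))
  if (n > length(model$pi))
    stop("n = ", n, " exceeds number of active states (",
         length(model$pi), ")")
  ord <- order(model$pi, model$active_set)
  model$active_set[ord[seq_len(n)]]
}
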