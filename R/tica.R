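# Time-lagged independent component analysis. The slow linear subspace of
# the feature process is found by solving the generalized symmetric
# eigenproblem  C(dt) v = lambda C(0) v  on mean-free data, with the lagged
# covariance symmetrized. Eigenvectors (the tICs) are the columns of the
# projection matrix P; eigenvalues approximate the autocorrelation of each
# component at the chosen lag.

.as_feature_list <- function(features) {
  if (inherits(features, "contact_features"))
    return(list(values = list(features$values),
                pair_labels = features$pair_labels,
                frame_spacing = features$frame_spacing))
  if (is.matrix(features))
    return(list(values = list(features), pair_labels = NULL,
                frame_spacing = NULL))
  if (is.list(features) && all(vapply(features, function(f)
    is.matrix(f) || inherits(f, "contact_features"), logical(1)))) {
    labs <- NULL; fs <- NULL
    vals <- lapply(features, function(f) {
      if (inherits(f, "contact_features")) {
        labs <<- f$pair_labels; fs <<- f$frame_spacing; f$values
      } else f
    })
    return(list(values = vals, pair_labels = labs, frame_spacing = fs))
  }
  stop("'features' must be a matrix, contact_features, or a list of them")
}

#' Fit a tICA model
#'
#' Estimates the mean, instantaneous covariance C(0) and symmetrized
#' time-lagged covariance C(dt) of the feature series, then solves
#' `C(dt) v = lambda C(0) v`. Lagged pairs are drawn within each trajectory
#' only, never across trajectory boundaries. C(0) is ridge-regularized
#' (`eps = 1e-6 * trace/d`) so rank-deficient feature sets stay solvable.
#' Component signs are fixed by making each component's largest-magnitude
#' loading positive; components are normalized to unit variance under C(0)
#' and ordered by decreasing eigenvalue.
#'
#' @param features a frames x d matrix, a [contact_features()] object, or a
#'   list of either (multiple trajectories).
#' @param lag lag time in frames (integer >= 1). Alternatively give
#'   `delta_t` in ns and the frame spacing is taken from the features.
#' @param n_components number N of slow components to retain
#'   (default `min(d, 20)`).
#' @param delta_t optional lag in ns; converted to frames via the feature
#'   object's `frame_spacing` (rounded to the nearest frame with a warning
#'   if not exact).
#' @return object of class `"tica_model"` with fields `mean`,
#'   `cov_instantaneous`, `cov_lagged`, `components` (d x N matrix P),
#'   `eigenvalues`, `lag` (frames), `delta_t` (ns, if known),
#'   `pair_labels`.
#' @examples
#' tp <- toy_polymer(2000, seed = 7)
#' cf <- contact_features(tp$trajectory)
#' mod <- fit_tica(cf, lag = 10, n_components = 2)
#' mod$eigenvalues
#' @export
fit_tica <- function(features, lag = NULL, n_components = NULL,
                     delta_t = NULL) {
  fl <- .as_feature_list(features)
  if (is.null(lag)) {
    if (is.null(delta_t) || is.null(fl$frame_spacing))
      stop("give 'lag' in frames, or 'delta_t' in ns with features that ",
           "carry a frame_spacing")
    exact <- delta_t / fl$frame_spacing
    lag <- round(exact)
    if (abs(exact - lag) > 1e-9)
      warning("delta_t is not an integer number of frames; rounded to ",
              lag, " frames")
  }
  lag <- as.integer(lag)
  if (lag < 1) stop("'lag' must be >= 1 frame")
  usable <- vapply(fl$values, nrow, integer(1)) > lag
  if (!any(usable)) stop("all trajectories are shorter than the lag")
  vals <- fl$values[usable]
  d <- ncol(vals[[1]])
  if (is.null(n_components)) n_components <- min(d, 20L)
  if (n_components > d) stop("n_components exceeds feature dimension ", d)

  n_tot <- sum(vapply(vals, nrow, integer(1)))
  mu <- Reduce(`+`, lapply(vals, colSums)) / n_tot
  C0 <- matrix(0, d, d)
  Ct <- matrix(0, d, d)
  n_pairs <- 0
  for (X in vals) {
    Xc <- sweep(X, 2, mu)
    n <- nrow(Xc)
    C0 <- C0 + crossprod(Xc)
    A <- Xc[seq_len(n - lag), , drop = FALSE]
    B <- Xc[(lag + 1):n, , drop = FALSE]
    Ct <- Ct + crossprod(A, B)
    n_pairs <- n_pairs + (n - lag)
  }
  C0 <- C0 / n_tot
  Ct <- (Ct + t(Ct)) / (2 * n_pairs)
  eps <- 1e-6 * sum(diag(C0)) / d
  C0r <- C0 + diag(eps, d)

  # Generalized symmetric eigenproblem via Cholesky whitening.
  L <- chol(C0r)                      # C0r = t(L) %*% L
  Linv <- backsolve(L, diag(d))
  M <- t(Linv) %*% Ct %*% Linv
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)[seq_len(n_components)]
  V <- Linv %*% e$vectors[, ord, drop = FALSE]
  # unit variance under C0r, sign: largest |loading| positive
  for (k in seq_len(ncol(V))) {
    V[, k] <- V[, k] / sqrt(drop(t(V[, k]) %*% C0r %*% V[, k]))
    imax <- which.max(abs(V[, k]))
    if (V[imax, k] < 0) V[, k] <- -V[, k]
  }
  structure(
    list(mean = mu, cov_instantaneous = C0, cov_lagged = Ct,
         components = V, eigenvalues = e$values[ord],
         lag = lag,
         delta_t = if (!is.null(fl$frame_spacing))
           lag * fl$frame_spacing else delta_t,
         pair_labels = fl$pair_labels),
    class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("<tica_model> d = %d features, N = %d components, lag = %d frames\n",
              length(x$mean), ncol(x$components), x$lag))
  cat("eigenvalues:", format(head(x$eigenvalues, 5), digits = 4), "\n")
  invisible(x)
}

.feature_values <- function(X) {
  if (inherits(X, "contact_features")) X$values
  else if (is.matrix(X)) X
  else matrix(X, nrow = 1)
}

#' Project conformations onto the slow tICs
#'
#' Computes `t(P) %*% (x - mean)` for each frame, truncated to the first
#' `n` components.
#'
#' @param model a [fit_tica()] model.
#' @param X feature matrix (frames x d), [contact_features()] object, or a
#'   single length-d vector.
#' @param n number of components to keep (default: all retained).
#' @return frames x n matrix of tIC coordinates.
#' @export
tica_project <- function(model, X, n = NULL) {
  stopifnot(inherits(model, "tica_model"))
  V <- model$components
  if (is.null(n)) n <- ncol(V)
  if (n > ncol(V)) stop("model retains only ", ncol(V), " components")
  Xm <- .feature_values(X)
  if (ncol(Xm) != length(model$mean))
    stop("dimension mismatch: expected d = ", length(model$mean),
         " features, got ", ncol(Xm))
  sweep(Xm, 2, model$mean) %*% V[, seq_len(n), drop = FALSE]
}

#' Distance between two conformations in tIC space
#'
#' The Euclidean norm of the difference of the two projections over the
#' first `n` components: `|| t(P)|A> - t(P)|B> ||_2`.
#'
#' @param model a [fit_tica()] model.
#' @param A,B length-d feature vectors (or 1 x d matrices).
#' @param n number of components (default: all retained).
#' @return nonnegative scalar.
#' @export
tic_distance <- function(model, A, B, n = NULL) {
  pa <- tica_project(model, rbind(c(A)), n)
  pb <- tica_project(model, rbind(c(B)), n)
  sqrt(sum((pa - pb)^2))
}

#' Feature loadings that dominate a tIC
#'
#' Returns the `k` features with the largest absolute weight in one
#' component, signed, labelled by residue pair when the model was fitted on
#' contact features.
#'
#' @param model a [fit_tica()] model.
#' @param component component index (1 = slowest).
#' @param k number of loadings to return (default 25).
#' @return data.frame with columns `feature`, `i`, `j` (residue pair, when
#'   known) and `weight`, ordered by decreasing `|weight|`.
#' @export
top_loadings <- function(model, component = 1, k = 25) {
  stopifnot(inherits(model, "tica_model"))
  if (component > ncol(model$components))
    stop("model retains only ", ncol(model$components), " components")
  w <- model$components[, component]
  if (k > length(w)) {
    warning("k exceeds feature dimension; truncated to ", length(w))
    k <- length(w)
  }
  ord <- order(abs(w), decreasing = TRUE)[seq_len(k)]
  out <- data.frame(feature = ord, weight = w[ord])
  if (!is.null(model$pair_labels)) {
    out$i <- model$pair_labels[ord, 1]
    out$j <- model$pair_labels[ord, 2]
    out <- out[, c("feature", "i", "j", "weight")]
  }
  rownames(out) <- NULL
  out
}
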