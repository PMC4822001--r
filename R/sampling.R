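# Kinetic Monte Carlo sampling of an estimated MSM: a state sequence is
# generated by repeated multinomial draws from the rows of T(tau), one
# draw per lag time; per-state conformation pools then turn the state
# sequence into a time series of any per-frame observable.

#' Sample a trajectory from an MSM by kinetic Monte Carlo
#'
#' From the current state i, the state one lag time later is drawn from
#' the multinomial distribution given by row i of the transition matrix.
#' Trajectories start from the most populated state at equilibrium unless
#' an explicit start state is given.
#'
#' @param model a [estimate_msm()] model.
#' @param n_steps number of KMC steps (the trajectory has `n_steps`
#'   states, each one lag time apart).
#' @param start `"most_populated"` (default) or a 1-based state index
#'   within the active model.
#' @param seed RNG seed.
#' @return object of class `"msm_trajectory"`: list with `states`
#'   (1-based, relative to the model's active set), `step_ns` (the lag),
#'   `seed`.
#' @examples
#' T <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
#' m <- estimate_msm(count_transitions(
#'   sample_markov_chain(T, 20000, seed = 5), lag = 1))
#' kmc <- sample_msm_trajectory(m, 1000, seed = 6)
#' table(kmc$states)
#' @export
sample_msm_trajectory <- function(model, n_steps,
                                  start = "most_populated", seed = 42) {
  stopifnot(inherits(model, "msm_model"), n_steps >= 1)
  n <- nrow(model$T)
  s0 <- if (identical(start, "most_populated")) which.max(model$pi)
        else as.integer(start)
  if (s0 < 1 || s0 > n)
    stop("start state ", s0, " outside the active model (1..", n, ")")
  states <- .with_seed(seed, {
    cumT <- t(apply(model$T, 1, cumsum))
    if (n == 1L) cumT <- matrix(cumT, 1)
    .markov_chain_cpp(cumT, s0 - 1L, as.integer(n_steps)) + 1L
  })
  structure(list(states = states, step_ns = model$lag_ns, seed = seed),
            class = "msm_trajectory")
}

#' @export
print.msm_trajectory <- function(x, ...) {
  cat(sprintf("<msm_trajectory> %d steps of %.4g ns\n",
              length(x$states), x$step_ns))
  invisible(x)
}

#' Realize a per-frame observable along an MSM trajectory
#'
#' For each KMC step, one conformation is drawn uniformly from the pool of
#' frames belonging to the visited state, and the observable value of that
#' frame is emitted. This converts an MSM into synthetic time series of
#' e.g. inter-residue distances.
#'
#' @param traj a [sample_msm_trajectory()] result (or bare integer state
#'   sequence).
#' @param frame_states per-frame state labels of the conformation pool
#'   (same index space as `traj$states`).
#' @param values per-frame observable values (vector, or matrix with one
#'   row per frame for multivariate observables).
#' @param seed RNG seed for the within-state frame draws.
#' @return data.frame with `time_ns`, `state`, `frame` (the drawn pool
#'   frame) and the observable column(s).
#' @export
realize_observables <- function(traj, frame_states, values, seed = 42) {
  states <- if (inherits(traj, "msm_trajectory")) traj$states
            else as.integer(traj)
  step_ns <- if (inherits(traj, "msm_trajectory")) traj$step_ns else 1
  vals <- if (is.matrix(values) || is.data.frame(values))
    as.matrix(values) else matrix(values, ncol = 1)
  if (nrow(vals) != length(frame_states))
    stop("'values' and 'frame_states' must cover the same frames")
  pools <- split(seq_along(frame_states), frame_states)
  visited <- unique(states)
  empty <- setdiff(as.character(visited), names(pools))
  if (length(empty))
    stop("no pooled frames for visited state(s): ",
         paste(empty, collapse = ", "))
  frames <- .with_seed(seed, vapply(states, function(s) {
    p <- pools[[as.character(s)]]
    if (length(p) == 1L) p else p[sample.int(length(p), 1)]
  }, integer(1)))
  out <- data.frame(time_ns = (seq_along(states) - 1) * step_ns,
                    state = states, frame = frames)
  obs <- vals[frames, , drop = FALSE]
  colnames(obs) <- if (!is.null(colnames(vals))) colnames(vals) else
    paste0("obs", seq_len(ncol(obs)))
  cbind(out, as.data.frame(obs))
}
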