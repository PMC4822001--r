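# End-to-end orchestration: a declarative configuration drives
# featurize -> tICA -> k-centers -> MSM -> (TPT | KMC | landscape), with
# every artifact checksummed into a manifest. Model containers round-trip
# through save_model()/load_model().

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults mirroring the calmodulin
#' C-lobe study settings: tICA lag 40 ns, 20 tICs, 100 microstates, MSM
#' lag 20 ns.
#'
#' @param delta_t_ns tICA lag time in ns.
#' @param n_tics number of tIC components retained.
#' @param n_clusters number of k-centers microstates.
#' @param msm_lag_ns MSM lag time in ns.
#' @param min_separation contact-map sequence separation filter.
#' @param landscape_bins bins per landscape axis.
#' @param kT thermal energy, kcal/mol.
#' @param seed master RNG seed.
#' @param tpt optional list with elements `A` and `B` (state sets) to run
#'   transition path analysis.
#' @param kmc_steps if > 0, length of the KMC trajectory to sample.
#' @param round_lag allow rounding non-integer lag/frame ratios
#'   (default TRUE; set FALSE to error instead).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(delta_t_ns = 40, n_tics = 20,
                            n_clusters = 100, msm_lag_ns = 20,
                            min_separation = 3, landscape_bins = 100,
                            kT = 0.5924, seed = 42, tpt = NULL,
                            kmc_steps = 0, round_lag = TRUE) {
  cfg <- list(delta_t_ns = delta_t_ns, n_tics = n_tics,
              n_clusters = n_clusters, msm_lag_ns = msm_lag_ns,
              min_separation = min_separation,
              landscape_bins = landscape_bins, kT = kT, seed = seed,
              tpt = tpt, kmc_steps = kmc_steps, round_lag = round_lag)
  class(cfg) <- "pipeline_config"
  cfg
}

.lag_frames <- function(lag_ns, frame_spacing, round_lag, what) {
  exact <- lag_ns / frame_spacing
  lag <- round(exact)
  if (abs(exact - lag) > 1e-9) {
    if (!round_lag)
      stop(what, " = ", lag_ns, " ns is not an integer number of frames ",
           "(frame spacing ", frame_spacing, " ns)")
    warning(what, " rounded to ", lag, " frames")
  }
  max(1L, as.integer(lag))
}

#' Run the analysis pipeline on a trajectory
#'
#' Executes featurization, tICA, k-centers discretization and MSM
#' estimation, then any optional downstream stage enabled in the
#' configuration (TPT, KMC sampling). Artifacts are written under
#' `out_dir` and listed in a checksummed manifest; with fixed seeds the
#' run is bit-reproducible.
#'
#' @param traj a [trajectory()] (e.g. from [toy_polymer()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent). `NULL` skips all
#'   file output.
#' @return list with `features`, `tica`, `clusters`, `msm`, and (when
#'   enabled) `tpt`, `kmc`; plus `manifest` (data.frame file/md5) when
#'   `out_dir` is given.
#' @export
run_pipeline <- function(traj, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(config, "pipeline_config"))
  fs <- traj$frame_spacing
  res <- list(config = config)

  cf <- contact_features(traj, min_separation = config$min_separation)
  res$features <- cf

  tica_lag <- .lag_frames(config$delta_t_ns, fs, config$round_lag,
                          "tICA delta_t")
  n_tics <- min(config$n_tics, ncol(cf$values))
  res$tica <- fit_tica(cf, lag = tica_lag, n_components = n_tics)

  proj <- tica_project(res$tica, cf)
  k <- config$n_clusters
  if (k > nrow(proj))
    stop("clustering precondition failed: n_clusters = ", k,
         " exceeds ", nrow(proj), " frames")
  res$clusters <- k_centers(proj, k = k, seed = config$seed)

  msm_lag <- .lag_frames(config$msm_lag_ns, fs, config$round_lag,
                         "MSM lag")
  counts <- count_transitions(res$clusters$assignments, msm_lag,
                              n_states = k, frame_spacing = fs)
  res$msm <- estimate_msm(counts)

  if (!is.null(config$tpt))
    res$tpt <- transition_paths(res$msm, config$tpt$A, config$tpt$B)
  if (config$kmc_steps > 0)
    res$kmc <- sample_msm_trajectory(res$msm, config$kmc_steps,
                                     seed = config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    save_artifact <- function(obj, name) {
      p <- file.path(out_dir, name)
      save_model(obj, p)
      paths <<- c(paths, p)
    }
    save_artifact(res$tica, "tica_model.rds")
    save_artifact(res$msm, "msm_model.rds")
    dtrj <- data.frame(frame = seq_along(res$clusters$assignments),
                       state = res$clusters$assignments)
    p <- file.path(out_dir, "discrete_trajectory.csv")
    write.csv(dtrj, p, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(res$tpt)) save_artifact(res$tpt, "tpt_result.rds")
    if (!is.null(res$kmc)) {
      p <- file.path(out_dir, "kmc_states.csv")
      write.csv(data.frame(step = seq_along(res$kmc$states),
                           state = res$kmc$states), p, row.names = FALSE)
      paths <- c(paths, p)
    }
    res$manifest <- data.frame(file = basename(paths),
                               md5 = unname(tools::md5sum(paths)))
  }
  res
}

.CONTAINER_VERSION <- 1L

#' Save / load model containers
#'
#' Serializes a model (tICA, MSM, TPT result, or any pipeline object) with
#' a format-version stamp; loading verifies the version and re-validates
#' key invariants (row-stochasticity of a transition matrix).
#'
#' @param object the model to save.
#' @param path file path.
#' @return `load_model` returns the restored object; `save_model` returns
#'   `path` invisibly.
#' @export
save_model <- function(object, path) {
  saveRDS(list(container_version = .CONTAINER_VERSION,
               class = class(object), object = object),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  wrapper <- readRDS(path)
  if (!is.list(wrapper) || is.null(wrapper$container_version))
    stop("not a conformakin model container: ", path)
  if (wrapper$container_version != .CONTAINER_VERSION)
    stop("container version ", wrapper$container_version,
         " not supported by this package version (expected ",
         .CONTAINER_VERSION, "); re-export the model")
  obj <- wrapper$object
  if (inherits(obj, "msm_model")) {
    rs <- rowSums(obj$T)
    if (any(abs(rs - 1) > 1e-10))
      stop("loaded transition matrix is not row-stochastic")
  }
  obj
}
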