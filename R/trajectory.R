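#' Trajectory container
#'
#' A minimal in-memory representation of a molecular-dynamics trajectory:
#' Cartesian coordinates per frame, an atom-level topology, and the time
#' spacing between consecutive frames.
#'
#' @param coordinates numeric array of dimension `frames x atoms x 3`,
#'   in Angstrom.
#' @param topology data.frame with one row per atom and columns
#'   `resid` (integer residue sequence index), `resname` (residue name),
#'   `atom` (atom name) and `element` (chemical element symbol; hydrogens
#'   must be labelled `"H"` so heavy atoms can be distinguished).
#' @param frame_spacing time between frames in nanoseconds
#'   (default 0.1 ns, i.e. one snapshot every 100 ps).
#'
#' @return An object of class `"trajectory"`: a list with the three fields
#'   above, validated.
#' @examples
#' top <- data.frame(resid = 1:2, resname = "BEA", atom = "CA", element = "C")
#' xyz <- array(0, c(5, 2, 3))
#' xyz[, 2, 1] <- 3.8
#' traj <- trajectory(xyz, top)
#' n_frames(traj)
#' @export
trajectory <- function(coordinates, topology, frame_spacing = 0.1) {
  if (length(dim(coordinates)) != 3L || dim(coordinates)[3] != 3L)
    stop("'coordinates' must be a frames x atoms x 3 array")
  if (!all(is.finite(coordinates)))
    stop("'coordinates' contains non-finite values")
  required <- c("resid", "resname", "atom", "element")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols))
    stop("topology lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (dim(coordinates)[2] != nrow(topology))
    stop("atom count mismatch: coordinates have ", dim(coordinates)[2],
         " atoms, topology has ", nrow(topology))
  if (!is.numeric(frame_spacing) || frame_spacing <= 0)
    stop("'frame_spacing' must be a positive time in ns")
  structure(
    list(coordinates = coordinates,
         topology = as.data.frame(topology),
         frame_spacing = frame_spacing),
    class = "trajectory")
}

#' @rdname trajectory
#' @param traj a `trajectory` object.
#' @export
n_frames <- function(traj) dim(traj$coordinates)[1]

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %d atoms, %d residues, %.4g ns/frame\n",
              n_frames(x), nrow(x$topology),
              length(unique(x$topology$resid)), x$frame_spacing))
  invisible(x)
}

# Indices of heavy atoms (element != H) for one residue; errors if none.
.heavy_atoms <- function(topology, resid) {
  idx <- which(topology$resid == resid & toupper(topology$element) != "H")
  if (!length(idx))
    stop("residue ", resid, " has no heavy atoms")
  idx
}

# Ordered unique residue indices of a topology.
.residue_ids <- function(topology) sort(unique(topology$resid))
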