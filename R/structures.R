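# Extraction of the calmodulin C-lobe (residues E82-A147) from published
# PDB structures and projection into a fitted tIC space, so experimental
# complex structures can be placed on the computed landscapes.

#' Extract the C-lobe from a PDB structure
#'
#' Reads one chain of a PDB file, keeps residues in `range` (default
#' 82-147, the calmodulin C-lobe), resolves alternate locations to the
#' highest-occupancy copy, and reports completeness. Structures below the
#' completeness threshold are refused rather than modelled: missing
#' residues must be completed externally.
#'
#' @param pdb_file path to a PDB file.
#' @param chain chain identifier.
#' @param range residue number range kept (default `c(82, 147)`).
#' @param model model number for multi-model (NMR) files (default 1).
#' @param min_completeness minimum fraction of expected residues
#'   (default 0.8).
#' @return object of class `"structure_record"`: list with `pdb_id`,
#'   `chain`, `trajectory` (single-frame [trajectory()] of the extracted
#'   heavy atoms), `completeness`, `missing_residues`.
#' @export
extract_clobe <- function(pdb_file, chain, range = c(82, 147), model = 1,
                          min_completeness = 0.8) {
  pdb <- bio3d::read.pdb(pdb_file, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  atoms <- pdb$atom
  if (!chain %in% atoms$chain)
    stop("chain '", chain, "' not present in ", pdb_file)
  keep <- atoms$chain == chain & atoms$resno >= range[1] &
    atoms$resno <= range[2] & atoms$type == "ATOM"
  atoms <- atoms[keep, , drop = FALSE]
  if (!nrow(atoms)) stop("no atoms in residue range for chain ", chain)
  # resolve altlocs: keep the highest-occupancy alternative per atom
  altkey <- paste(atoms$resno, atoms$elety)
  ord <- order(altkey, -atoms$o)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$resno, atoms$elety)), ,
                 drop = FALSE]
  atoms <- atoms[order(atoms$resno, atoms$eleno), , drop = FALSE]
  # multi-model: pick coordinates of the requested model
  if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) >= model &&
      model > 1) {
    xyz_model <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    rows <- match(rownames(atoms), rownames(pdb$atom))
    coords <- xyz_model[rows, , drop = FALSE]
  } else {
    coords <- cbind(atoms$x, atoms$y, atoms$z)
  }
  expected <- range[1]:range[2]
  present <- sort(unique(atoms$resno))
  missing_res <- setdiff(expected, present)
  completeness <- length(present) / length(expected)
  if (completeness < min_completeness)
    stop(sprintf(
      "chain %s covers only %.1f%% of residues %d-%d (missing: %s); %s",
      chain, 100 * completeness, range[1], range[2],
      paste(missing_res, collapse = ", "),
      "supply a completed model"))
  heavy <- toupper(substr(trimws(atoms$elesy), 1, 1)) != "H"
  atoms <- atoms[heavy, , drop = FALSE]
  coords <- coords[heavy, , drop = FALSE]
  top <- data.frame(resid = atoms$resno, resname = atoms$resid,
                    atom = atoms$elety, element = trimws(atoms$elesy))
  xyz <- array(coords, c(1, nrow(coords), 3))
  # array() above fills frame-major; with one frame the layout is direct
  xyz[1, , ] <- coords
  structure(list(
    pdb_id = toupper(sub("\\.pdb$", "", basename(pdb_file),
                         ignore.case = TRUE)),
    chain = chain,
    trajectory = trajectory(xyz, top, frame_spacing = 1),
    completeness = completeness,
    missing_residues = missing_res),
    class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record> %s chain %s: %d residues, %.1f%% complete\n",
              x$pdb_id, x$chain,
              length(unique(x$trajectory$topology$resid)),
              100 * x$completeness))
  invisible(x)
}

#' Project extracted structures into a fitted tIC space
#'
#' Featurizes each record with [contact_features()] (same separation
#' filter as the model) and applies [tica_project()]. The records must
#' yield exactly the residue pairs the model was trained on.
#'
#' @param model a [fit_tica()] model carrying `pair_labels`.
#' @param records a `structure_record` or list of them (or single-frame
#'   [trajectory()] objects).
#' @param n number of tIC coordinates to return (default 2).
#' @param min_separation separation filter used when featurizing
#'   (default 3, must match the model).
#' @return data.frame with `id` and columns `tic1..ticn`.
#' @export
project_structures <- function(model, records, n = 2, min_separation = 3) {
  stopifnot(inherits(model, "tica_model"))
  if (inherits(records, "structure_record") ||
      inherits(records, "trajectory")) records <- list(records)
  rows <- lapply(records, function(rec) {
    traj <- if (inherits(rec, "structure_record")) rec$trajectory else rec
    cf <- contact_features(traj, min_separation = min_separation)
    if (!is.null(model$pair_labels)) {
      key <- function(m) apply(m, 1, paste, collapse = "-")
      if (nrow(cf$pair_labels) != nrow(model$pair_labels))
        stop("structure yields ", nrow(cf$pair_labels),
             " residue pairs but the model expects ",
             nrow(model$pair_labels))
      bad <- which(key(cf$pair_labels) != key(model$pair_labels))
      if (length(bad))
        stop("feature mismatch with the model's residue pairs (first ",
             "differing pair: ",
             paste(cf$pair_labels[bad[1], ], collapse = "-"), ")")
    }
    tica_project(model, cf, n = n)[1, ]
  })
  ids <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    if (inherits(r, "structure_record")) paste0(r$pdb_id, ":", r$chain)
    else paste0("structure", i)
  }, character(1))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0("tic", seq_len(ncol(out)))
  cbind(data.frame(id = ids), out)
}
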