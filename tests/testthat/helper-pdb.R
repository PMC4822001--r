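# Minimal PDB text writer for synthetic single-chain CA-trace fixtures.
# Each row of `atoms` needs: resno, x, y, z; optional altloc ("" default)
# and occ (1.00 default).
write_fake_pdb <- function(path, atoms, chain = "A") {
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1.0
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    paste0("ATOM  ", sprintf("%5d", i), " ",
           sprintf("%-4s", " CA "),
           sprintf("%1s", substr(paste0(a$altloc, " "), 1, 1)),
           sprintf("%3s", "ALA"), " ", chain,
           sprintf("%4d", a$resno), "    ",
           sprintf("%8.3f%8.3f%8.3f", a$x, a$y, a$z),
           sprintf("%6.2f%6.2f", a$occ, 0),
           "          ", sprintf("%2s", "C"))
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# helical CA trace over a residue range (finite, self-avoiding)
helix_atoms <- function(resnos) {
  t <- seq_along(resnos)
  data.frame(resno = resnos,
             x = 2.3 * cos(t), y = 2.3 * sin(t), z = 1.5 * t)
}
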