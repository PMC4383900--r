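# Test helpers: synthetic PDB text and hand-built fingerprint objects.

# Minimal PDB ATOM/HETATM record (CA only unless elety given)
pdb_atom_line <- function(serial, resname, chain, resno, x, y, z,
                          record = "ATOM", altloc = " ", elety = " CA ",
                          icode = " ", element = " C") {
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, elety, altloc, resname, chain, resno, icode,
          x, y, z, 1.00, 0.00, element)
}

# straight 5-residue chain; residues/resnos/records customizable
write_test_pdb <- function(path, resnames = rep("ALA", 5L),
                           resnos = seq_along(resnames),
                           records = rep("ATOM", length(resnames)),
                           chain = "A", models = 1L) {
  lines <- character(0)
  for (m in seq_len(models)) {
    if (models > 1L) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_along(resnames)) {
      lines <- c(lines, pdb_atom_line(i, resnames[i], chain, resnos[i],
                                      3.8 * i + (m - 1L) * 100, 0, 0,
                                      record = records[i]))
    }
    if (models > 1L) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  path
}

# fingerprint_matrix with a prescribed dominant-label field, for
# testing the element/notation logic in isolation
fake_fingerprint <- function(n, blocks, full_label = NULL) {
  dom <- matrix(NA_character_, n, n)
  for (k in 1:(n - 1)) for (l in (k + 1):n) dom[k, l] <- "0_1"
  for (b in blocks)
    for (k in b$k[1]:b$k[2]) for (l in b$l[1]:b$l[2])
      if (k < l) dom[k, l] <- b$label
  if (!is.null(full_label)) dom[1, n] <- full_label
  idx <- which(!is.na(dom), arr.ind = TRUE)
  cells <- data.frame(k = idx[, 1], l = idx[, 2],
                      dominant = dom[idx], frequency = 1,
                      masked = FALSE, stringsAsFactors = FALSE)
  cells <- cells[order(cells$k, cells$l), ]
  structure(list(n = n, cells = cells, dom = dom, freq_maps = list(),
                 putative = FALSE,
                 masked_cells = cells[0, c("k", "l")],
                 seed = 1L,
                 params = list(n_closures = 0L, stride = 1L,
                               inflation = 10, arc_step_deg = 10)),
            class = "fingerprint_matrix")
}
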