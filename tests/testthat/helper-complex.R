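# Synthetic protein-ligand complex fixtures, built in code. These are
# geometric stand-ins (real coordinates of published complexes are not
# bundled): a hand-placed dimethyl-ether ligand with protein atoms at
# chosen distances, so every measured value is known by construction.

pdbLine <- function(record, serial, name, alt, resid, chain, resno,
                    x, y, z, occ, elem) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resid, chain, resno, x, y, z, occ, 0,
          elem)
}

# Ether ligand (C1-O1-C2; the O1 is an ssO atom) plus CYS285:SG placed
# 3.50 A from O1, MET364:SD 4.70 A from O1, LEU340:O 4.20 A from C1.
writeSyntheticComplex <- function(path, withAltloc = FALSE,
                                  transform = identity) {
  lig <- rbind(C1 = c(-1.42, 0, 0), O1 = c(0, 0, 0), C2 = c(0.55, 1.31, 0))
  prot <- rbind(SG = c(0, -3.50, 0), SD = c(4.70, 0, 0),
                O = c(-1.42, 4.20, 0))
  lig <- t(apply(lig, 1, transform))
  prot <- t(apply(prot, 1, transform))
  lines <- c(
    pdbLine("ATOM", 1, "SG", if (withAltloc) "A" else " ", "CYS", "A", 285,
            prot["SG", 1], prot["SG", 2], prot["SG", 3],
            if (withAltloc) 0.7 else 1, "S"),
    if (withAltloc)
      pdbLine("ATOM", 2, "SG", "B", "CYS", "A", 285,
              prot["SG", 1] + 2, prot["SG", 2], prot["SG", 3], 0.3, "S"),
    pdbLine("ATOM", 3, "SD", " ", "MET", "A", 364,
            prot["SD", 1], prot["SD", 2], prot["SD", 3], 1, "S"),
    pdbLine("ATOM", 4, "O", " ", "LEU", "A", 340,
            prot["O", 1], prot["O", 2], prot["O", 3], 1, "O"),
    pdbLine("HETATM", 5, "C1", " ", "LIG", "A", 1,
            lig["C1", 1], lig["C1", 2], lig["C1", 3], 1, "C"),
    pdbLine("HETATM", 6, "O1", " ", "LIG", "A", 1,
            lig["O1", 1], lig["O1", 2], lig["O1", 3], 1, "O"),
    pdbLine("HETATM", 7, "C2", " ", "LIG", "A", 1,
            lig["C2", 1], lig["C2", 2], lig["C2", 3], 1, "C"),
    "END")
  writeLines(lines, path)
  invisible(path)
}

rigidTransform <- function(p) {
  theta <- 0.83
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  as.numeric(R %*% p + c(5.5, -2.25, 11))
}
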