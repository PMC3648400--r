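# Contact verification in protein-ligand complexes: select ligand atoms by
# E-state type and measure heavy-atom distances to named protein atoms.
# Hydrogen is invisible to X-ray crystallography, so every measurement is
# between heavy atoms.

.pdbHetatmLine <- function(serial, name, resid, resno, x, y, z, elem) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("HETATM%5d %s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resid, resno, x, y, z, 1, 0, elem)
}

# Resolve altloc duplicates: keep the highest-occupancy record per atom
# name (ties: first). `altloc` forces a specific conformer id instead.
.resolveAltloc <- function(df, altloc = NULL) {
  if (!nrow(df)) return(df)
  alt <- df$alt
  alt[is.na(alt)] <- ""
  if (!is.null(altloc)) {
    keep <- alt %in% c("", altloc)
    df <- df[keep, , drop = FALSE]
  } else if (any(nzchar(alt))) {
    key <- paste(df$resid, df$resno, df$elety)
    pos <- seq_len(nrow(df))
    ord <- order(-df$o, pos, method = "radix")
    keep <- ord[!duplicated(key[ord])]
    df <- df[sort(keep), , drop = FALSE]
  }
  dup <- duplicated(paste(df$resid, df$resno, df$elety))
  if (any(dup))
    stop("ambiguous atom records (unresolved altlocs) for: ",
         paste(unique(paste0(df$resid[dup], df$resno[dup], ":",
                             df$elety[dup])), collapse = ", "),
         "; pass altloc = <id>", call. = FALSE)
  df
}

#' Load a protein-ligand complex from a PDB file
#'
#' The ligand (a HETATM residue code) is extracted, its bond orders are
#' perceived from the 3D geometry by Open Babel (PDB files carry no bond
#' orders) so E-state typing is possible, and every ligand heavy atom gets
#' its E-state type. Alternatively a SMILES plus an atom-name map can
#' override geometric perception. Altloc conformers default to the
#' highest-occupancy record.
#'
#' Note on the published worked examples: the rosiglitazone complex is PDB
#' entry 2PRG (ligand code BRL); the tyrosine-agonist complex is cited
#' with contradictory labels ("1K74 ligand", accession "1K47") — 1K74 is
#' the real PPARgamma entry and is the accession this package's examples
#' use.
#'
#' @param pdbFile path to a PDB file.
#' @param ligand hetero residue code of the ligand (e.g. \code{"BRL"}).
#' @param ligandSmiles optional SMILES overriding geometric bond
#'   perception; requires \code{atomMap}.
#' @param atomMap named integer vector mapping PDB atom names to heavy-atom
#'   indices of the graph parsed from \code{ligandSmiles}.
#' @param altloc force an alternate-location id instead of the
#'   highest-occupancy default.
#' @return a \code{\linkS4class{LigandComplex}}.
#' @export
loadComplex <- function(pdbFile, ligand, ligandSmiles = NULL,
                        atomMap = NULL, altloc = NULL) {
  if (!file.exists(pdbFile)) stop("file not found: ", pdbFile, call. = FALSE)
  pdb <- bio3d::read.pdb(pdbFile, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  isH <- !is.na(at$elesy) & toupper(at$elesy) == "H"
  at <- at[!isH, , drop = FALSE]
  het <- at[at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
            drop = FALSE]
  if (!nrow(het) || !ligand %in% het$resid) {
    found <- sort(unique(het$resid))
    stop("ligand residue '", ligand, "' not found; hetero residues ",
         "present: ", if (length(found)) paste(found, collapse = ", ")
         else "(none)", call. = FALSE)
  }
  lig <- het[het$resid == ligand, , drop = FALSE]
  # one copy: first chain/resno combination
  firstKey <- paste(lig$chain[1], lig$resno[1])
  lig <- lig[paste(lig$chain, lig$resno) == firstKey, , drop = FALSE]
  lig <- .resolveAltloc(lig, altloc)
  prot <- .resolveAltloc(at[at$type == "ATOM", , drop = FALSE], altloc)

  if (!is.null(ligandSmiles)) {
    g <- parseSmiles(ligandSmiles, name = ligand)
    if (is.null(atomMap))
      stop("ligandSmiles override requires atomMap (PDB atom name -> ",
           "graph atom index)", call. = FALSE)
    if (!all(lig$elety %in% names(atomMap)))
      stop("atomMap is missing ligand atom(s): ",
           paste(setdiff(lig$elety, names(atomMap)), collapse = ", "),
           call. = FALSE)
    idx <- unname(atomMap[lig$elety])
    if (!identical(toupper(g@atoms$element[idx]), toupper(lig$elesy)))
      stop("atomMap elements do not match the PDB ligand records",
           call. = FALSE)
    types <- esAtomTypes(g)[idx]
  } else {
    lines <- vapply(seq_len(nrow(lig)), function(k)
      .pdbHetatmLine(k, lig$elety[k], "LIG", 1,
                     lig$x[k], lig$y[k], lig$z[k], lig$elesy[k]), "")
    sdf <- .obabelRun(c(lines, "END"), "pdb", "sdf", "-h")
    mol2 <- .obabelRun(c(lines, "END"), "pdb", "mol2", "-h")
    gl <- .graphsFromSdfText(sdf, NULL, largestFragment = FALSE,
                             mol2Lines = mol2)
    g <- gl[[1]]
    if (nrow(g@atoms) != nrow(lig))
      stop("bond perception returned ", nrow(g@atoms),
           " heavy atoms for ", nrow(lig), " ligand records", call. = FALSE)
    if (!identical(toupper(g@atoms$element), toupper(lig$elesy)))
      stop("element mismatch between PDB ligand and perceived graph",
           call. = FALSE)
    g@name <- ligand
    types <- esAtomTypes(g)
  }
  ligandAtoms <- data.frame(name = lig$elety, element = lig$elesy,
                            x = lig$x, y = lig$y, z = lig$z,
                            esType = types, stringsAsFactors = FALSE)
  protein <- data.frame(resid = prot$resid, resno = prot$resno,
                        elety = prot$elety, x = prot$x, y = prot$y,
                        z = prot$z, stringsAsFactors = FALSE)
  new("LigandComplex", protein = protein, ligandAtoms = ligandAtoms,
      ligand = g, source = pdbFile, ligandId = ligand)
}

# Parse a "CYS285:SG"-style selection.
.parseSelection <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z]{1,3})([0-9]+):([A-Za-z0-9']+)$", s))[[1]]
  if (length(m) != 4)
    stop("cannot parse protein selection '", s,
         "'; expected e.g. 'CYS285:SG'", call. = FALSE)
  list(resid = toupper(m[2]), resno = as.integer(m[3]), elety = m[4])
}

#' Measure heavy-atom contacts from ligand atoms of one E-state type
#'
#' Euclidean distances (in Angstroms, reported to 0.01) from every ligand
#' heavy atom of the requested E-state type to each named protein atom.
#'
#' @param cx a \code{\linkS4class{LigandComplex}}.
#' @param esType E-state type symbol selecting ligand atoms (e.g.
#'   \code{"ssO"}).
#' @param selections character vector of protein atoms as
#'   \code{"CYS285:SG"} (residue name + number : atom name).
#' @return data.frame(ligandAtom, esType, residue, proteinAtom, distance).
#' @export
measureContacts <- function(cx, esType, selections) {
  ligSel <- cx@ligandAtoms[cx@ligandAtoms$esType == esType, , drop = FALSE]
  if (!nrow(ligSel))
    stop("no ligand atom of E-state type '", esType, "'; types present: ",
         paste(sort(unique(cx@ligandAtoms$esType)), collapse = " "),
         call. = FALSE)
  rows <- list()
  for (s in selections) {
    sel <- .parseSelection(s)
    hit <- cx@protein[cx@protein$resid == sel$resid &
                      cx@protein$resno == sel$resno &
                      cx@protein$elety == sel$elety, , drop = FALSE]
    if (nrow(hit) == 0)
      stop("protein atom not found: ", s, call. = FALSE)
    if (nrow(hit) > 1)
      stop("protein selection '", s, "' is ambiguous (", nrow(hit),
           " records); pass altloc to loadComplex", call. = FALSE)
    for (k in seq_len(nrow(ligSel))) {
      d <- sqrt((ligSel$x[k] - hit$x)^2 + (ligSel$y[k] - hit$y)^2 +
                (ligSel$z[k] - hit$z)^2)
      rows[[length(rows) + 1L]] <-
        data.frame(ligandAtom = ligSel$name[k], esType = esType,
                   residue = paste0(sel$resid, sel$resno),
                   proteinAtom = sel$elety, distance = round(d, 2),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
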