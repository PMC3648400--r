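# Molecule parsing and topological services.
#
# Chemistry perception is delegated to Open Babel: it reads SMILES/SDF,
# kekulizes, and adds explicit hydrogens; hydrogens are then folded back
# into per-atom counts. Aromaticity follows Open Babel's own perception
# (its MOL2 'ar' bond flags, restricted to ring bonds); E-state types of
# the form aaO/aaN/aaCH/aaaC depend on this model, which is stamped into
# reports as the perception provenance.

.ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")

.ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                  Br = 79.904, I = 126.904)

# Lightweight SMILES token validation with positions. This is a syntax
# checker, not a chemistry parser: obabel does the parsing, but it silently
# truncates inputs like "C(", so malformed strings must be caught here.
.validateSmiles <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s))
    stop("parse error: empty SMILES", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  parenStack <- integer()
  ringOpen <- list()
  inBracket <- FALSE
  bracketStart <- 0L
  bracketContent <- ""
  i <- 1L
  err <- function(pos, what)
    stop(sprintf("parse error in SMILES '%s' at position %d: %s",
                 s, pos, what), call. = FALSE)
  toggleRing <- function(num, pos) {
    key <- as.character(num)
    if (is.null(ringOpen[[key]])) ringOpen[[key]] <<- pos
    else ringOpen[[key]] <<- NULL
  }
  while (i <= n) {
    ch <- chars[i]
    if (inBracket) {
      if (ch == "[") err(i, "nested '['")
      if (ch == "]") {
        if (!nzchar(gsub("[^A-Za-z*]", "", bracketContent)))
          err(bracketStart, "bracket atom without an element")
        inBracket <- FALSE
      } else bracketContent <- paste0(bracketContent, ch)
      i <- i + 1L
      next
    }
    if (ch == "[") {
      inBracket <- TRUE; bracketStart <- i; bracketContent <- ""
    } else if (ch == "]") {
      err(i, "unmatched ']'")
    } else if (ch == "(") {
      parenStack <- c(parenStack, i)
    } else if (ch == ")") {
      if (!length(parenStack)) err(i, "unmatched ')'")
      parenStack <- parenStack[-length(parenStack)]
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}", paste0(chars[i + 1L], chars[i + 2L])))
        err(i, "'%' must be followed by two digits")
      toggleRing(paste0(chars[i + 1L], chars[i + 2L]), i)
      i <- i + 2L
    } else if (grepl("[0-9]", ch)) {
      toggleRing(ch, i)
    } else if (ch %in% c("C", "B")) {
      if (i < n && ((ch == "C" && chars[i + 1L] == "l") ||
                    (ch == "B" && chars[i + 1L] == "r"))) i <- i + 1L
    } else if (ch %in% c("N", "O", "P", "S", "F", "I",
                         "c", "n", "o", "p", "s", "b")) {
      # organic-subset atom
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", ".", "@", "+", "*")) {
      # bond / stereo / separator tokens, left to obabel
    } else {
      err(i, sprintf("unexpected character '%s'", ch))
    }
    i <- i + 1L
  }
  if (inBracket) err(bracketStart, "unmatched '['")
  if (length(parenStack)) err(parenStack[1], "unmatched '('")
  if (length(ringOpen))
    err(ringOpen[[1]], sprintf("unclosed ring bond '%s'", names(ringOpen)[1]))
  invisible(TRUE)
}

# Aromatic edge keys ("i j", i < j, original atom indexing) for one
# molecule: Open Babel's 'ar' bond flags restricted to ring bonds.
# Acyclic bonds obabel writes as 'ar'/'am' (carboxyl, amidine, amide
# resonance) are thereby excluded, so kekule orders from the SDF pass
# stay authoritative for them.
.aromaticEdgesFromMol2 <- function(mol2Bonds, element) {
  if (is.null(mol2Bonds)) return(character())
  ar <- mol2Bonds[mol2Bonds$type == "ar", , drop = FALSE]
  if (!nrow(ar)) return(character())
  heavy <- mol2Bonds[element[mol2Bonds$i] != "H" &
                     element[mol2Bonds$j] != "H", , drop = FALSE]
  ig <- igraph::graph_from_edgelist(cbind(heavy$i, heavy$j),
                                    directed = FALSE)
  br <- igraph::bridges(ig)
  ringKeys <- {
    el <- igraph::as_edgelist(ig)
    keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    if (length(br)) keys[-as.integer(br)] else keys
  }
  intersect(paste(pmin(ar$i, ar$j), pmax(ar$i, ar$j)), ringKeys)
}

# Build MolecularGraph objects from explicit-H SDF text produced by
# obabel, with aromaticity taken from the matching MOL2 conversion.
.graphsFromSdfText <- function(sdfLines, ids, largestFragment = FALSE,
                               mol2Lines = NULL) {
  recs <- lapply(.splitSdfRecords(sdfLines), .parseSdfRecord)
  if (!length(recs)) stop("no molecules could be parsed", call. = FALSE)
  mol2 <- if (!is.null(mol2Lines)) .parseMol2(mol2Lines) else NULL
  if (!is.null(mol2) && length(mol2) != length(recs))
    stop("SDF and MOL2 conversions disagree on molecule count",
         call. = FALSE)
  got <- vapply(recs, function(r) r$title, "")
  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    rec <- recs[[k]]
    heavy <- which(rec$element != "H")
    if (!length(heavy)) stop("molecule '", got[k], "' has no heavy atoms",
                             call. = FALSE)
    newIdx <- integer(length(rec$element))
    newIdx[heavy] <- seq_along(heavy)
    b <- rec$bonds
    isH <- rec$element[b$i] == "H" | rec$element[b$j] == "H"
    nH <- integer(length(heavy))
    if (any(isH)) {
      hb <- b[isH, , drop = FALSE]
      heavyEnd <- ifelse(rec$element[hb$i] == "H", hb$j, hb$i)
      tab <- table(factor(newIdx[heavyEnd], levels = seq_along(heavy)))
      nH <- as.integer(tab)
    }
    hb2 <- b[!isH, , drop = FALSE]
    aromKeys <- if (!is.null(mol2)) {
      if (!identical(mol2[[k]]$element[mol2[[k]]$element != "H"],
                     rec$element[heavy]))
        stop("SDF/MOL2 atom order mismatch for molecule '", got[k], "'",
             call. = FALSE)
      .aromaticEdgesFromMol2(mol2[[k]]$bonds, mol2[[k]]$element)
    } else character()
    edgeKey <- paste(pmin(hb2$i, hb2$j), pmax(hb2$i, hb2$j))
    order <- c("single", "double", "triple")[pmin(hb2$order, 3L)]
    order[edgeKey %in% aromKeys] <- "aromatic"
    aromAtoms <- unique(c(hb2$i[order == "aromatic"],
                          hb2$j[order == "aromatic"]))
    atomsDf <- data.frame(
      element = rec$element[heavy],
      charge = rec$charge[heavy],
      nH = nH,
      aromatic = seq_along(rec$element)[heavy] %in% aromAtoms,
      stringsAsFactors = FALSE)
    bondsDf <- data.frame(i = newIdx[pmin(hb2$i, hb2$j)],
                          j = newIdx[pmax(hb2$i, hb2$j)],
                          order = order, stringsAsFactors = FALSE)
    g <- new("MolecularGraph", atoms = atomsDf, bonds = bondsDf,
             name = got[k], smiles = "")
    g <- .resolveFragments(g, largestFragment)
    out[[k]] <- g
  }
  names(out) <- got
  # map back onto requested ids (obabel keeps titles)
  if (!is.null(ids)) {
    missing <- setdiff(ids, got)
    if (length(missing))
      stop("parse error: obabel could not convert molecule(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    out <- out[ids]
  }
  out
}

# Enforce single connected component, or keep the largest fragment.
.resolveFragments <- function(g, largestFragment = FALSE) {
  if (nrow(g@atoms) <= 1) return(g)
  ig <- .toIgraph(g)
  comp <- igraph::components(ig)
  if (comp$no == 1) return(g)
  if (!largestFragment)
    stop(sprintf(paste0("molecule '%s' has %d disconnected components ",
                        "(sizes %s); salts/mixtures are rejected unless ",
                        "largestFragment = TRUE"),
                 g@name, comp$no, paste(comp$csize, collapse = ", ")),
         call. = FALSE)
  keepComp <- which.max(comp$csize)
  keep <- which(comp$membership == keepComp)
  newIdx <- integer(nrow(g@atoms))
  newIdx[keep] <- seq_along(keep)
  b <- g@bonds[g@bonds$i %in% keep & g@bonds$j %in% keep, , drop = FALSE]
  b$i <- newIdx[b$i]; b$j <- newIdx[b$j]
  new("MolecularGraph", atoms = g@atoms[keep, , drop = FALSE],
      bonds = b, name = g@name, smiles = g@smiles)
}

.toIgraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g@bonds)) g@bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(g@atoms))))
}

#' Parse a SMILES string into a MolecularGraph
#'
#' Open Babel performs the chemical parsing (valence model, implicit
#' hydrogens, kekulization); aromaticity is then perceived by Hueckel-type
#' ring perception on the kekulized graph. Hydrogens are folded into
#' per-atom counts and never appear as graph nodes.
#'
#' @param smiles a single SMILES string.
#' @param name optional compound id stored in the graph.
#' @param largestFragment if the input has several disconnected fragments
#'   (salts, mixtures), keep the largest instead of rejecting.
#' @return a \code{\linkS4class{MolecularGraph}}.
#' @examples
#' g <- parseSmiles("CCO")           # ethanol: C(H3)-C(H2)-O(H)
#' atoms(g)$nH                        # 3 2 1
#' @export
parseSmiles <- function(smiles, name = NULL, largestFragment = FALSE) {
  .validateSmiles(smiles)
  if (is.null(name)) name <- "mol1"
  res <- parseSmilesSet(stats::setNames(smiles, name),
                        largestFragment = largestFragment)
  res[[1]]
}

#' Parse a vector of SMILES in one batch
#'
#' @param smiles named character vector (names become compound ids; unnamed
#'   inputs get \code{mol<i>}).
#' @inheritParams parseSmiles
#' @return named list of \code{MolecularGraph} objects, in input order.
#' @export
parseSmilesSet <- function(smiles, largestFragment = FALSE) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  for (s in smiles) .validateSmiles(s)
  safe <- sprintf("tmr%06d", seq_along(smiles))
  input <- paste(smiles, safe)
  sdf <- .obabelRun(input, "smi", "sdf", "-h")
  mol2 <- .obabelRun(input, "smi", "mol2", "-h")
  gl <- .graphsFromSdfText(sdf, safe, largestFragment, mol2Lines = mol2)
  for (k in seq_along(gl)) {
    gl[[k]]@name <- ids[k]
    gl[[k]]@smiles <- unname(smiles[k])
  }
  names(gl) <- ids
  gl
}

#' Read molecules from a SMILES file
#'
#' One molecule per line: SMILES, optionally followed by whitespace and an
#' id. Blank lines and lines starting with '#' are skipped.
#'
#' @param path file path.
#' @inheritParams parseSmiles
#' @return named list of \code{MolecularGraph} objects.
#' @export
readSmilesFile <- function(path, largestFragment = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no molecules in ", path, call. = FALSE)
  parts <- strsplit(lines, "[[:space:]]+")
  smi <- vapply(parts, `[`, "", 1)
  ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  ids[is.na(ids)] <- paste0("mol", which(is.na(ids)))
  parseSmilesSet(stats::setNames(smi, ids), largestFragment = largestFragment)
}

#' Read molecules from an SDF (V2000) file
#'
#' Structures are normalized through Open Babel (explicit hydrogens added,
#' then folded into counts) so SDF- and SMILES-sourced graphs follow the
#' same perception model.
#'
#' @param path file path.
#' @inheritParams parseSmiles
#' @return named list of \code{MolecularGraph} objects (named by the SDF
#'   title line, falling back to \code{mol<i>}).
#' @export
readSdfFile <- function(path, largestFragment = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  input <- readLines(path, warn = FALSE)
  sdf <- .obabelRun(input, "sdf", "sdf", "-h")
  mol2 <- .obabelRun(input, "sdf", "mol2", "-h")
  gl <- .graphsFromSdfText(sdf, NULL, largestFragment, mol2Lines = mol2)
  ids <- names(gl)
  blank <- !nzchar(ids)
  ids[blank] <- paste0("mol", which(blank))
  names(gl) <- ids
  for (k in seq_along(gl)) gl[[k]]@name <- ids[k]
  gl
}

#' Topological distance matrix of the heavy-atom graph
#'
#' Shortest-path bond counts between all heavy-atom pairs (symmetric, zero
#' diagonal).
#'
#' @param g a \code{MolecularGraph} with one connected component.
#' @return integer matrix of bond counts.
#' @export
graphDistanceMatrix <- function(g) {
  n <- nrow(g@atoms)
  if (n == 1) return(matrix(0, 1, 1))
  ig <- .toIgraph(g)
  comp <- igraph::components(ig)
  if (comp$no > 1)
    stop(sprintf("graph '%s' is disconnected (component sizes %s)",
                 g@name, paste(comp$csize, collapse = ", ")), call. = FALSE)
  d <- igraph::distances(ig)
  d <- d[as.character(seq_len(n)), as.character(seq_len(n))]
  unname(d)
}

#' Number of heavy-atom neighbors of an atom
#'
#' @param g a \code{MolecularGraph}.
#' @param i atom index (1-based).
#' @return integer count of bonds to non-hydrogen neighbors.
#' @export
heavyDegree <- function(g, i) {
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > nrow(g@atoms))
    stop("atom index out of range: ", i, call. = FALSE)
  sum(g@bonds$i == i | g@bonds$j == i)
}

#' Canonical SMILES of a molecular graph
#'
#' Echoed in reports; also used by round-trip checks. Uses Open Babel
#' canonicalization of the stored input SMILES.
#'
#' @param g a \code{MolecularGraph} built from SMILES.
#' @return canonical SMILES string.
#' @export
canonicalSmiles <- function(g) {
  if (!nzchar(g@smiles))
    stop("graph has no stored SMILES (SDF-sourced); canonical echo ",
         "is only available for SMILES input", call. = FALSE)
  out <- .obabelRun(paste(g@smiles, "m"), "smi", "can")
  strsplit(trimws(out[1]), "[[:space:]]+")[[1]][1]
}

#' Molecular weight (average atomic masses, hydrogens included)
#'
#' @param g a \code{MolecularGraph}.
#' @return numeric, g/mol.
#' @export
molecularWeight <- function(g) {
  a <- g@atoms
  unknown <- setdiff(unique(a$element), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("no mass for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sum(.ATOMIC_MASS[a$element]) + sum(a$nH) * .ATOMIC_MASS[["H"]]
}

#' Number of ring bonds
#'
#' Bonds that are part of at least one cycle (non-bridge edges).
#'
#' @param g a \code{MolecularGraph}.
#' @return integer.
#' @export
ringBondCount <- function(g) {
  if (!nrow(g@bonds)) return(0L)
  ig <- .toIgraph(g)
  length(igraph::E(ig)) - length(igraph::bridges(ig))
}
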