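#' @import methods
NULL

#' MolecularGraph: a typed heavy-atom molecular graph
#'
#' Central container for descriptor computation. Atoms are heavy atoms only;
#' hydrogens exist as per-atom counts (the E-state grammar reads heavy-atom
#' topology plus H counts). Aromaticity is a per-atom flag and a bond order
#' level, assigned at parse time by ring perception.
#'
#' @slot atoms data.frame with columns \code{element} (symbol),
#'   \code{charge} (formal charge, integer), \code{nH} (attached hydrogen
#'   count), \code{aromatic} (logical).
#' @slot bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices, i < j) and \code{order} (one of \code{"single"},
#'   \code{"double"}, \code{"triple"}, \code{"aromatic"}).
#' @slot name compound identifier.
#' @slot smiles the input SMILES the graph was built from ("" if from SDF).
#'
#' @examples
#' g <- parseSmiles("CCO")
#' atoms(g)
#' bonds(g)
#' @export
setClass("MolecularGraph",
  representation(atoms = "data.frame", bonds = "data.frame",
                 name = "character", smiles = "character"),
  prototype(atoms = data.frame(), bonds = data.frame(),
            name = NA_character_, smiles = ""))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  need <- c("element", "charge", "nH", "aromatic")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (nrow(b)) {
    if (!all(c("i", "j", "order") %in% names(b)))
      return("bonds must have columns i, j, order")
    if (any(b$i < 1 | b$j < 1 | b$i > nrow(a) | b$j > nrow(a)))
      msgs <- c(msgs, "bond atom indices out of range")
    if (any(b$i == b$j))
      msgs <- c(msgs, "a bond joins an atom to itself")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key))
      msgs <- c(msgs, "more than one bond for an atom pair")
    ar <- b$order == "aromatic"
    if (any(ar & !(a$aromatic[b$i] & a$aromatic[b$j])))
      msgs <- c(msgs, "aromatic bond between atoms not flagged aromatic")
    if (!all(b$order %in% c("single", "double", "triple", "aromatic")))
      msgs <- c(msgs, "unknown bond order")
  }
  if (nrow(a) && any(a$nH < 0))
    msgs <- c(msgs, "negative attached-hydrogen count")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn MolecularGraph number of heavy atoms
#' @param x,object a \code{MolecularGraph}
#' @export
heavyAtomCount <- function(x) nrow(x@atoms)

#' @describeIn MolecularGraph atom table accessor
#' @export
atoms <- function(x) x@atoms

#' @describeIn MolecularGraph bond table accessor
#' @export
bonds <- function(x) x@bonds

#' @describeIn MolecularGraph compound name accessor
#' @export
moleculeName <- function(x) x@name

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph", if (!is.na(object@name)) object@name else "",
      "\n  heavy atoms:", nrow(object@atoms),
      " bonds:", nrow(object@bonds),
      " aromatic atoms:", sum(object@atoms$aromatic), "\n")
  if (nzchar(object@smiles)) cat("  smiles:", object@smiles, "\n")
})

#' DescriptorMatrix: compounds by named molecular descriptors
#'
#' Rectangular numeric matrix (no missing cells) of descriptor values with
#' compound ids as row names. Carries the charge model used for the
#' charge-derived columns, a flag vector marking constant columns (kept in
#' the matrix but excluded from regression screens), and the list of
#' compounds excluded during the build with the logged reason.
#'
#' @slot values numeric matrix, rownames = compound ids, colnames unique.
#' @slot constant named logical, one entry per column.
#' @slot chargeMethod partial-charge model name stamped into reports.
#' @slot excluded data.frame(id, reason) of compounds dropped at build time.
#' @export
setClass("DescriptorMatrix",
  representation(values = "matrix", constant = "logical",
                 chargeMethod = "character", excluded = "data.frame"),
  prototype(chargeMethod = "gasteiger",
            excluded = data.frame(id = character(), reason = character())))

setValidity("DescriptorMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have row and column names")
  if (anyDuplicated(colnames(v))) return("descriptor names must be unique")
  if (anyNA(v)) return("missing cells are not allowed")
  if (length(object@constant) != ncol(v))
    return("constant flag vector must match column count")
  TRUE
})

#' @describeIn DescriptorMatrix the numeric matrix
#' @param x a \code{DescriptorMatrix}
#' @export
descriptorValues <- function(x) x@values

#' @describeIn DescriptorMatrix descriptor (column) names
#' @export
descriptorNames <- function(x) colnames(x@values)

#' @describeIn DescriptorMatrix names of constant (zero-variance) columns
#' @export
constantDescriptors <- function(x) names(which(x@constant))

#' @describeIn DescriptorMatrix compounds excluded at build time
#' @export
excludedCompounds <- function(x) x@excluded

#' @describeIn DescriptorMatrix compound ids (row names)
#' @export
compoundIds <- function(x) rownames(x@values)

setMethod("show", "DescriptorMatrix", function(object) {
  cat("DescriptorMatrix:", nrow(object@values), "compounds x",
      ncol(object@values), "descriptors\n",
      " charge model:", object@chargeMethod, "\n",
      " constant columns:", sum(object@constant),
      " excluded compounds:", nrow(object@excluded), "\n")
})

#' AnalogSetSpec: configuration of the synthetic analog-series generator
#'
#' Describes an analog series sharing a core scaffold whose tail is
#' decorated with moieties carrying distinct E-state signatures, and the
#' activity model \eqn{Y = \beta_0 + \beta_g RNCG + \sum_k \gamma_k
#' count_k + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}.
#'
#' @slot n compound count (>= 10).
#' @slot scaffold SMILES with a \code{{T}} placeholder for the tail.
#' @slot moieties named list; each element has \code{unit} (SMILES fragment
#'   appended into the tail chain), \code{esType} (declared E-state
#'   signature), \code{gamma} (activity-log units per count), \code{counts}
#'   (integer pool sampled per compound) and optional \code{rare} (number of
#'   compounds that carry exactly one copy; the rest carry none).
#' @slot bulkCoef coefficient on the computed Jurs_RNCG of each compound.
#' @slot intercept baseline pEC50.
#' @slot sigma Gaussian noise SD on the log-activity scale (>= 0).
#' @slot seed default RNG seed for generation.
#' @export
setClass("AnalogSetSpec",
  representation(n = "numeric", scaffold = "character", moieties = "list",
                 bulkCoef = "numeric", intercept = "numeric",
                 sigma = "numeric", seed = "numeric"))

setValidity("AnalogSetSpec", function(object) {
  if (length(object@n) != 1 || object@n < 10)
    return("n must be a single value >= 10")
  if (object@sigma < 0) return("sigma must be >= 0")
  if (!grepl("{T}", object@scaffold, fixed = TRUE))
    return("scaffold must contain the tail placeholder {T}")
  for (nm in names(object@moieties)) {
    m <- object@moieties[[nm]]
    if (!all(c("unit", "esType", "gamma") %in% names(m)))
      return(sprintf("moiety '%s' needs unit, esType, gamma", nm))
  }
  TRUE
})

setMethod("show", "AnalogSetSpec", function(object) {
  cat("AnalogSetSpec: n =", object@n, " sigma =", object@sigma,
      " bulk coef =", object@bulkCoef, "\n  moieties:\n")
  for (nm in names(object@moieties)) {
    m <- object@moieties[[nm]]
    cat(sprintf("   %-10s unit=%-12s type=%-6s gamma=%+.2f%s\n", nm,
                m$unit, m$esType, m$gamma,
                if (!is.null(m$rare)) sprintf(" (rare: %d compounds)", m$rare)
                else ""))
  }
})

#' LigandComplex: a protein-ligand complex prepared for contact analysis
#'
#' @slot protein data.frame of protein heavy atoms (resid, resno, elety,
#'   x, y, z).
#' @slot ligandAtoms data.frame of ligand heavy atoms (atom name, element,
#'   coordinates, assigned E-state type).
#' @slot ligand the ligand as a \code{MolecularGraph}.
#' @slot source path of the coordinate file.
#' @slot ligandId the hetero residue code selected.
#' @export
setClass("LigandComplex",
  representation(protein = "data.frame", ligandAtoms = "data.frame",
                 ligand = "MolecularGraph", source = "character",
                 ligandId = "character"))

setMethod("show", "LigandComplex", function(object) {
  cat("LigandComplex from", object@source, "\n  ligand:", object@ligandId,
      "(", nrow(object@ligandAtoms), "heavy atoms )",
      "\n  protein heavy atoms:", nrow(object@protein), "\n  ES types:",
      paste(sort(unique(object@ligandAtoms$esType)), collapse = " "), "\n")
})
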