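# Electrotopological-state (E-state) engine.
#
# Each heavy atom gets (1) a bond-pattern atom type such as ssO, sssN, aaCH
# or dssC, and (2) an E-state value S = intrinsic state I plus topological
# perturbations from every other heavy atom. ES_Count_<type> and
# ES_Sum_<type> aggregates over a molecule form the "detector array" of the
# second screening stage.
#
# Conventions:
#  * I = ((2/N)^2 * delta_v + 1) / delta, delta = heavy-atom degree,
#    delta_v = valence electrons - attached H - formal charge,
#    N = principal quantum number.
#  * S_i = I_i + sum_{j != i} (I_i - I_j) / r_ij^2 with r_ij = topological
#    distance + 1, summed over ALL heavy-atom pairs (no cutoff).
#  * Type prefix letters: t (triple), d (double), a (aromatic), s (single),
#    one letter per bond, ordered t, d, a, s to match the canonical
#    published names (dssC, aasC, tsC); hydrogen suffix H/H2/H3 appended
#    when attached hydrogens are present.

.VALENCE_ELECTRONS <- c(B = 3, C = 4, N = 5, O = 6, F = 7,
                        P = 5, S = 6, Cl = 7, Br = 7, I = 7)

.PRINCIPAL_QN <- c(B = 2, C = 2, N = 2, O = 2, F = 2,
                   P = 3, S = 3, Cl = 3, Br = 4, I = 5)

.checkSupportedElements <- function(g) {
  bad <- setdiff(unique(g@atoms$element), names(.VALENCE_ELECTRONS))
  if (length(bad))
    stop("unsupported element(s) for E-state typing in '", g@name, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' E-state atom type of one atom
#'
#' The symbol is the bond-prefix string (one letter per bond to a heavy
#' neighbor: t = triple, d = double, a = aromatic, s = single, in that
#' order) followed by the element symbol and, when hydrogens are attached,
#' an H/H2/H3 suffix. Examples: the oxygen of dimethyl ether is
#' \code{ssO}; a trimethylamine nitrogen is \code{sssN}; a furan oxygen is
#' \code{aaO}; a formaldehyde oxygen is \code{dO}.
#'
#' @param g a \code{MolecularGraph}.
#' @param i atom index.
#' @return the type symbol, e.g. \code{"ssCH2"}.
#' @export
typeAtom <- function(g, i) {
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > nrow(g@atoms))
    stop("atom index out of range: ", i, call. = FALSE)
  esAtomTypes(g)[i]
}

#' E-state atom types of every heavy atom
#'
#' @param g a \code{MolecularGraph}.
#' @return character vector, one symbol per heavy atom.
#' @export
esAtomTypes <- function(g) {
  .checkSupportedElements(g)
  a <- g@atoms
  prefOrder <- c(triple = 1L, double = 2L, aromatic = 3L, single = 4L)
  prefChar <- c(triple = "t", double = "d", aromatic = "a", single = "s")
  prefixes <- character(nrow(a))
  if (nrow(g@bonds)) {
    for (k in seq_len(nrow(g@bonds))) {
      bi <- g@bonds$i[k]; bj <- g@bonds$j[k]; o <- g@bonds$order[k]
      prefixes[bi] <- paste0(prefixes[bi], prefChar[[o]])
      prefixes[bj] <- paste0(prefixes[bj], prefChar[[o]])
    }
    prefixes <- vapply(strsplit(prefixes, ""), function(p) {
      lv <- c(t = 1L, d = 2L, a = 3L, s = 4L)
      paste(p[order(lv[p])], collapse = "")
    }, "")
  }
  suffix <- ifelse(a$nH == 0, "",
                   ifelse(a$nH == 1, "H", paste0("H", a$nH)))
  paste0(prefixes, a$element, suffix)
}

.deltas <- function(g) {
  a <- g@atoms
  delta <- integer(nrow(a))
  if (nrow(g@bonds)) {
    tab <- table(factor(c(g@bonds$i, g@bonds$j), levels = seq_len(nrow(a))))
    delta <- as.integer(tab)
  }
  zv <- .VALENCE_ELECTRONS[a$element]
  deltaV <- unname(zv) - a$nH - a$charge
  list(delta = delta, deltaV = deltaV,
       N = unname(.PRINCIPAL_QN[a$element]))
}

#' Intrinsic state of one atom
#'
#' \eqn{I = ((2/N)^2 \delta^v + 1) / \delta}. For second-row elements
#' (N = 2) this reduces to \eqn{(\delta^v + 1)/\delta}.
#'
#' @param g a \code{MolecularGraph}.
#' @param i atom index.
#' @return numeric intrinsic state (> 0).
#' @export
intrinsicState <- function(g, i) {
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > nrow(g@atoms))
    stop("atom index out of range: ", i, call. = FALSE)
  intrinsicStates(g)[i]
}

#' Intrinsic states of every heavy atom
#'
#' @param g a \code{MolecularGraph}.
#' @return numeric vector.
#' @export
intrinsicStates <- function(g) {
  .checkSupportedElements(g)
  d <- .deltas(g)
  if (any(d$delta < 1))
    stop("intrinsic state undefined: atom(s) ",
         paste(which(d$delta < 1), collapse = ", "), " in '", g@name,
         "' have no heavy neighbors", call. = FALSE)
  ((2 / d$N)^2 * d$deltaV + 1) / d$delta
}

#' Per-atom E-state values
#'
#' \eqn{S_i = I_i + \sum_{j \ne i} (I_i - I_j) / r_{ij}^2} with
#' \eqn{r_{ij}} = topological distance + 1 (bonded neighbors have r = 2).
#' The perturbations are pairwise antisymmetric, so
#' \eqn{\sum_i S_i = \sum_i I_i} exactly.
#'
#' @param g a \code{MolecularGraph} (one connected component).
#' @return data.frame with columns \code{index}, \code{element},
#'   \code{type}, \code{delta}, \code{deltaV}, \code{N}, \code{I},
#'   \code{S}.
#' @examples
#' ev <- estateValues(parseSmiles("CCC"))  # propane: 2.125, 1.25, 2.125
#' ev$S
#' @export
estateValues <- function(g) {
  .checkSupportedElements(g)
  d <- .deltas(g)
  I <- intrinsicStates(g)
  D <- graphDistanceMatrix(g)  # errors on disconnected graphs
  R2 <- (D + 1)^2
  P <- outer(I, I, "-") / R2
  diag(P) <- 0
  S <- I + rowSums(P)
  data.frame(index = seq_along(I), element = g@atoms$element,
             type = esAtomTypes(g), delta = d$delta, deltaV = d$deltaV,
             N = d$N, I = I, S = S, stringsAsFactors = FALSE)
}

#' ES_Count / ES_Sum descriptor vector of a molecule
#'
#' For every E-state type present (or every type in \code{registry}, to
#' build rectangular matrices across a compound set): the count of atoms of
#' that type and the sum of their E-state values. Types absent from the
#' molecule are reported as 0/0 when a registry is supplied.
#'
#' @param g a \code{MolecularGraph}.
#' @param registry optional character vector of type symbols fixing the
#'   descriptor set (see \code{\link{esTypeRegistry}}).
#' @return named numeric vector \code{ES_Count_<type>}, \code{ES_Sum_<type>}.
#' @export
esDescriptorVector <- function(g, registry = NULL) {
  ev <- estateValues(g)
  types <- if (is.null(registry)) sort(unique(ev$type)) else registry
  cnt <- vapply(types, function(t) sum(ev$type == t), 0)
  sm <- vapply(types, function(t) sum(ev$S[ev$type == t]), 0)
  stats::setNames(c(cnt, sm),
                  c(paste0("ES_Count_", types), paste0("ES_Sum_", types)))
}

#' Union of E-state types over a compound set
#'
#' @param mols list of \code{MolecularGraph} objects.
#' @return sorted character vector of type symbols.
#' @export
esTypeRegistry <- function(mols) {
  sort(unique(unlist(lapply(mols, esAtomTypes))))
}
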