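# Partial charges, the Jurs RNCG filter descriptor, and the descriptor
# matrix assembled for screening.
#
# RNCG (relative negative charge) = |most negative atomic charge| divided
# by the summed magnitude of all negative charges. It is 1 exactly when a
# single atom carries all negative charge, scale-invariant, and grows as
# the same total negative charge concentrates on fewer atoms. Charges
# default to Gasteiger-Marsili (the method needs a charge-coherent
# ordering, not any particular model; the model name is stamped into every
# report).

#' Atomic partial charges with hydrogens folded onto heavy atoms
#'
#' @param g a \code{MolecularGraph} built from SMILES.
#' @param method charge model; currently \code{"gasteiger"}.
#' @return numeric vector of per-heavy-atom charges (elementary charge
#'   units), hydrogen charges summed onto their heavy neighbor.
#' @examples
#' q <- assignPartialCharges(parseSmiles("CCO"))
#' which.min(q)  # the oxygen
#' @export
assignPartialCharges <- function(g, method = "gasteiger") {
  assignPartialChargesSet(list(g), method = method)[[1]]
}

#' Batch partial charges for a list of molecules
#'
#' One Open Babel invocation for the whole set.
#'
#' @param mols list of \code{MolecularGraph} objects with stored SMILES.
#' @inheritParams assignPartialCharges
#' @return list of numeric charge vectors, one per molecule.
#' @export
assignPartialChargesSet <- function(mols, method = "gasteiger") {
  method <- match.arg(method, "gasteiger")
  smi <- vapply(mols, function(g) g@smiles, "")
  if (any(!nzchar(smi)))
    stop("molecule(s) without stored SMILES: ",
         paste(vapply(mols[!nzchar(smi)], function(g) g@name, ""),
               collapse = ", "), call. = FALSE)
  lines <- paste(smi, sprintf("tmr%06d", seq_along(smi)))
  mol2 <- .obabelRun(lines, "smi", "mol2",
                     c("-h", "--partialcharge", method))
  parsed <- .parseMol2(mol2)
  if (length(parsed) != length(mols))
    stop("charge model '", method, "' failed: got ", length(parsed),
         " of ", length(mols), " molecules back", call. = FALSE)
  out <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    p <- parsed[[k]]
    heavy <- which(p$element != "H")
    if (length(heavy) != nrow(mols[[k]]@atoms))
      stop("charge assignment failed for molecule '", mols[[k]]@name,
           "': atom count mismatch", call. = FALSE)
    if (!identical(p$element[heavy], mols[[k]]@atoms$element))
      stop("charge assignment failed for molecule '", mols[[k]]@name,
           "': element order mismatch", call. = FALSE)
    q <- p$charge[heavy]
    hIdx <- which(p$element == "H")
    if (length(hIdx) && !is.null(p$bonds)) {
      newIdx <- integer(length(p$element)); newIdx[heavy] <- seq_along(heavy)
      for (h in hIdx) {
        nb <- c(p$bonds$j[p$bonds$i == h], p$bonds$i[p$bonds$j == h])
        nb <- nb[p$element[nb] != "H"]
        if (length(nb)) q[newIdx[nb[1]]] <- q[newIdx[nb[1]]] + p$charge[h]
      }
    }
    out[[k]] <- q
  }
  names(out) <- vapply(mols, function(g) g@name, "")
  out
}

#' Jurs RNCG: relative negative charge
#'
#' \eqn{RNCG = |q_{maxneg}| / \sum |q_{neg}|} over the atomic partial
#' charges of a molecule. Lies in (0, 1]; equals 1 when a single atom
#' carries all negative charge; invariant to positive rescaling of the
#' charge vector.
#'
#' @param q numeric vector of atomic partial charges.
#' @return numeric in (0, 1].
#' @examples
#' rncg(c(-0.3, -0.1, 0.4))  # 0.75
#' @export
rncg <- function(q) {
  stopifnot(is.numeric(q), length(q) >= 1)
  neg <- q[q < 0]
  if (!length(neg))
    stop("RNCG undefined: no atom carries negative charge", call. = FALSE)
  max(abs(neg)) / sum(abs(neg))
}

#' Descriptor pool configuration for the screening matrix
#'
#' The matrix always contains Jurs_RNCG and every ES_Count/ES_Sum pair
#' present in the compound set; \code{extras} adds simple bulk competitors
#' (echoing the size-, ring- and polarity-type descriptor families that
#' compete in stage-1 screens) so dominance screening faces realistic
#' competition.
#'
#' @param extras character vector drawn from \code{"HeavyAtomCount"},
#'   \code{"MolecularWeight"}, \code{"RingBondCount"},
#'   \code{"PolarAtomFraction"}.
#' @param chargeMethod partial-charge model for Jurs_RNCG.
#' @return a list used by \code{\link{buildDescriptorMatrix}}.
#' @export
descriptorPool <- function(extras = c("HeavyAtomCount", "MolecularWeight",
                                      "RingBondCount", "PolarAtomFraction"),
                           chargeMethod = "gasteiger") {
  known <- c("HeavyAtomCount", "MolecularWeight", "RingBondCount",
             "PolarAtomFraction")
  extras <- as.character(extras)
  bad <- setdiff(extras, known)
  if (length(bad))
    stop("unknown pool extras: ", paste(bad, collapse = ", "), call. = FALSE)
  list(extras = extras, chargeMethod = chargeMethod)
}

#' Read a descriptor pool configuration from a YAML file
#'
#' Expected keys: \code{extras} (list of names) and \code{charge_method}.
#'
#' @param path YAML file.
#' @return a pool list as from \code{\link{descriptorPool}}.
#' @export
readDescriptorPool <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read pool config files",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  descriptorPool(
    extras = if (!is.null(cfg$extras)) unlist(cfg$extras) else character(),
    chargeMethod = if (!is.null(cfg$charge_method)) cfg$charge_method
                   else "gasteiger")
}

.extraDescriptor <- function(g, name) {
  switch(name,
    HeavyAtomCount = heavyAtomCount(g),
    MolecularWeight = molecularWeight(g),
    RingBondCount = ringBondCount(g),
    PolarAtomFraction = sum(g@atoms$element %in% c("N", "O")) /
      nrow(g@atoms),
    stop("unknown extra descriptor: ", name, call. = FALSE))
}

#' Build the compounds-by-descriptors matrix
#'
#' Columns are Jurs_RNCG, the union of ES_Count/ES_Sum descriptors over the
#' set (zeros filled for types a molecule lacks), and the configured pool
#' extras. Compounds on which any descriptor fails (e.g. RNCG undefined
#' because no atom is negative) are excluded with a logged reason.
#' Constant columns are retained but flagged.
#'
#' @param mols list of \code{MolecularGraph} objects (with stored SMILES).
#' @param pool a \code{\link{descriptorPool}} configuration.
#' @return a \code{\linkS4class{DescriptorMatrix}}.
#' @export
buildDescriptorMatrix <- function(mols, pool = descriptorPool()) {
  stopifnot(is.list(mols), length(mols) >= 1)
  ids <- vapply(mols, function(g) g@name, "")
  if (anyDuplicated(ids))
    stop("duplicate compound ids in molecule list", call. = FALSE)
  registry <- esTypeRegistry(mols)
  charges <- assignPartialChargesSet(mols, method = pool$chargeMethod)
  rows <- list()
  excluded <- data.frame(id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (k in seq_along(mols)) {
    row <- tryCatch({
      es <- esDescriptorVector(mols[[k]], registry = registry)
      jr <- rncg(charges[[k]])
      ex <- vapply(pool$extras, function(e) .extraDescriptor(mols[[k]], e), 0)
      c(Jurs_RNCG = jr, es, ex)
    }, error = function(e) e)
    if (inherits(row, "error")) {
      message("descriptor failure, excluding '", ids[k], "': ",
              conditionMessage(row))
      excluded <- rbind(excluded,
                        data.frame(id = ids[k],
                                   reason = conditionMessage(row)))
    } else rows[[ids[k]]] <- row
  }
  if (!length(rows))
    stop("no compound survived descriptor computation", call. = FALSE)
  m <- do.call(rbind, rows)
  const <- apply(m, 2, function(col) max(col) - min(col) == 0)
  new("DescriptorMatrix", values = m, constant = const,
      chargeMethod = pool$chargeMethod, excluded = excluded)
}

#' Write a DescriptorMatrix as TSV (column 1 = id)
#'
#' @param x a \code{DescriptorMatrix}.
#' @param path output file.
#' @export
writeDescriptorMatrix <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# charge_model: ", x@chargeMethod), con)
  df <- data.frame(id = rownames(x@values), x@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DescriptorMatrix from TSV
#'
#' @param path TSV as written by \code{\link{writeDescriptorMatrix}}.
#' @return a \code{DescriptorMatrix} (charge model recovered from the
#'   comment header when present).
#' @export
readDescriptorMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cm <- grep("^# charge_model:", lines, value = TRUE)
  method <- if (length(cm)) trimws(sub("^# charge_model:", "", cm[1]))
            else "unknown"
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  const <- apply(m, 2, function(col) max(col) - min(col) == 0)
  new("DescriptorMatrix", values = m, constant = const,
      chargeMethod = method,
      excluded = data.frame(id = character(), reason = character()))
}
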