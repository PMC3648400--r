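# Synthetic analog series with planted structural modifications.
#
# Emulates a congeneric SAR series: every compound shares a
# thiazolidinedione-like core ("head") and differs in a tail assembled
# from moiety units with known E-state signatures (ether -> ssO, tertiary
# amine -> sssN, aromatic-oxygen heterocycle -> aaO, methylene -> ssCH2).
# Activity follows Y = b0 + b_bulk * RNCG + sum_k gamma_k * count_k + eps,
# eps ~ N(0, sigma^2), with EC50 emitted as 10^(-Y). The bulk term uses
# the compound's own computed RNCG so the stage-1 filter has a real signal
# to find; the planted gammas are what stage 2 must recover.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default moiety library of the analog-set generator
#'
#' Four tail moieties with distinct E-state signatures. Effect sizes: the
#' ether (\code{ssO}) is a strong negative modification, the tertiary
#' amine (\code{sssN}) a positive one, the methylene a zero-effect
#' structural nuisance, and the oxazole a rare strongly positive
#' modification carried by exactly two compounds (a planted "analog
#' outlier" pair).
#'
#' @return named list of moiety definitions.
#' @export
defaultMoieties <- function() {
  list(
    ether = list(unit = "OC", esType = "ssO", gamma = -1.5, counts = 0:3),
    amine = list(unit = "CN(C)", esType = "sssN", gamma = 1.0, counts = 0:2),
    methylene = list(unit = "C", esType = "ssCH2", gamma = 0, counts = 0:4),
    oxazole = list(unit = "C(c2ocnc2)", esType = "aaO", gamma = 2.0,
                   rare = 2L))
}

#' Default analog-set specification
#'
#' n = 150 compounds on a thiazolidinedione-like scaffold,
#' gamma_ssO = -1.5, gamma_sssN = +1.0, sigma = 0.3, intercept 6 (a
#' typical pEC50), bulk coefficient 25 on the computed Jurs_RNCG (spans
#' roughly one log unit of activity over the series).
#'
#' @param ... slots to override (\code{n}, \code{sigma}, \code{moieties},
#'   \code{bulkCoef}, \code{intercept}, \code{scaffold}, \code{seed}).
#' @return an \code{\linkS4class{AnalogSetSpec}}.
#' @export
analogSetSpec <- function(...) {
  args <- list(...)
  defaults <- list(n = 150, scaffold = "O=C1NC(=O)SC1Cc1ccc({T})cc1",
                   moieties = defaultMoieties(), bulkCoef = 25,
                   intercept = 6, sigma = 0.3, seed = 1)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  do.call(new, c(list(Class = "AnalogSetSpec"), defaults))
}

#' Read an analog-set specification from a YAML file
#'
#' Recognized keys: \code{n} (or \code{n_compounds}), \code{sigma},
#' \code{bulk_coef},
#' \code{intercept}, \code{scaffold}, \code{seed}, and \code{moieties} (a
#' map of name to \code{unit}, \code{es_type}, \code{gamma}, and either
#' \code{counts} (list of integers) or \code{rare} (compound count)).
#' Omitted keys keep the defaults of \code{\link{analogSetSpec}}.
#'
#' @param path YAML file.
#' @return an \code{\linkS4class{AnalogSetSpec}}.
#' @export
readAnalogSetSpec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read spec files", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 coerces a bare key `n` to boolean FALSE; accept both
  # spellings and undo the coercion
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  if (!is.null(cfg$n_compounds)) cfg$n <- cfg$n_compounds
  args <- list()
  for (k in c("n", "sigma", "intercept", "scaffold", "seed"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  if (!is.null(cfg$bulk_coef)) args$bulkCoef <- cfg$bulk_coef
  if (!is.null(cfg$moieties)) {
    args$moieties <- lapply(cfg$moieties, function(m) {
      out <- list(unit = m$unit, esType = m$es_type, gamma = m$gamma)
      if (!is.null(m$rare)) out$rare <- as.integer(m$rare)
      else out$counts <- as.integer(unlist(m$counts))
      out
    })
  }
  do.call(analogSetSpec, args)
}

# Tail SMILES for one compound given its per-moiety counts.
.tailSmiles <- function(spec, counts) {
  units <- character()
  for (nm in names(spec@moieties))
    units <- c(units, rep(spec@moieties[[nm]]$unit, counts[[nm]]))
  paste0(paste(units, collapse = ""), "C")
}

.assembleSmiles <- function(spec, counts) {
  sub("{T}", .tailSmiles(spec, counts), spec@scaffold, fixed = TRUE)
}

# Self-consistency gate: adding one unit of a moiety must raise the count
# of its declared ES type by exactly one on the emitted structure.
.checkMoietySignatures <- function(spec) {
  zero <- lapply(spec@moieties, function(m) 0L)
  probes <- c(list(baseline = .assembleSmiles(spec, zero)),
              lapply(names(spec@moieties), function(nm) {
                ct <- zero; ct[[nm]] <- 1L
                .assembleSmiles(spec, ct)
              }))
  names(probes) <- c("baseline", names(spec@moieties))
  gl <- parseSmilesSet(unlist(probes))
  typeCount <- function(g, t) sum(esAtomTypes(g) == t)
  for (nm in names(spec@moieties)) {
    t <- spec@moieties[[nm]]$esType
    d <- typeCount(gl[[nm]], t) - typeCount(gl[["baseline"]], t)
    if (d != 1L)
      stop(sprintf(paste0("moiety '%s' (unit '%s') is chemically ",
                          "incompatible with the scaffold: one unit ",
                          "changes the %s count by %d, not 1"),
                   nm, spec@moieties[[nm]]$unit, t, d), call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a synthetic analog set with planted truth
#'
#' Deterministic for a fixed seed. Per compound: moiety counts are drawn
#' (rare moieties go into exactly their declared number of compounds), the
#' SMILES is assembled, Gasteiger charges give the compound's Jurs_RNCG,
#' and the activity model produces EC50 values. A self-consistency gate
#' verifies that each moiety's declared E-state signature matches the
#' typing of the emitted structures.
#'
#' @param spec an \code{\linkS4class{AnalogSetSpec}}.
#' @param seed RNG seed (default: the spec's own).
#' @param check run the signature self-consistency gate (default TRUE).
#' @return list with \code{smiles} (named vector), \code{molecules}
#'   (list of \code{MolecularGraph}), \code{activities}
#'   (data.frame id, ec50_molar, Y), \code{counts} (per-compound moiety
#'   counts), \code{rncg} (computed Jurs_RNCG vector) and \code{truth}
#'   (see \code{\link{plantedTruth}}).
#' @export
generateAnalogSet <- function(spec, seed = spec@seed, check = TRUE) {
  validObject(spec)
  if (check) .checkMoietySignatures(spec)
  n <- as.integer(spec@n)
  ids <- sprintf("cmpd%03d", seq_len(n))
  .withSeed(seed, {
    counts <- data.frame(row.names = ids)
    for (nm in names(spec@moieties)) {
      m <- spec@moieties[[nm]]
      counts[[nm]] <- if (!is.null(m$rare)) {
        v <- integer(n); v[sample.int(n, m$rare)] <- 1L; v
      } else sample(m$counts, n, replace = TRUE)
    }
    smi <- vapply(seq_len(n),
                  function(i) .assembleSmiles(spec,
                                              as.list(counts[i, , drop = FALSE])),
                  "")
    names(smi) <- ids
    mols <- parseSmilesSet(smi)
    q <- assignPartialChargesSet(mols)
    rn <- vapply(q, rncg, 0)
    gammas <- vapply(spec@moieties, function(m) m$gamma, 0)
    Y <- spec@intercept + spec@bulkCoef * rn +
      as.vector(as.matrix(counts) %*% gammas) +
      stats::rnorm(n, 0, spec@sigma)
    list(smiles = smi, molecules = mols,
         activities = activityTable(ids, 10^(-Y)),
         counts = counts, rncg = rn, truth = plantedTruth(spec))
  })
}

#' Planted truth of an analog-set specification
#'
#' The E-state types a successful stage-2 screen should surface: every
#' moiety with a nonzero effect, with the sign of its effect, ordered by
#' effect magnitude; rare moieties (planted in at most a handful of
#' compounds) are flagged as expected "analog outlier" markers with their
#' support.
#'
#' @param spec an \code{AnalogSetSpec}.
#' @return data.frame(esType, gamma, sign, rare, expectedSupport);
#'   zero rows when all effects are zero.
#' @export
plantedTruth <- function(spec) {
  rows <- lapply(names(spec@moieties), function(nm) {
    m <- spec@moieties[[nm]]
    if (m$gamma == 0) return(NULL)
    data.frame(moiety = nm, esType = m$esType, gamma = m$gamma,
               sign = .signChar(m$gamma), rare = !is.null(m$rare),
               expectedSupport = if (!is.null(m$rare)) as.integer(m$rare)
                                 else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(moiety = character(), esType = character(),
                      gamma = numeric(), sign = character(),
                      rare = logical(), expectedSupport = integer()))
  out <- out[order(-abs(out$gamma), out$esType), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an analog set to disk
#'
#' Emits \code{<prefix>.smi} (SMILES + id), \code{<prefix>.activities.tsv}
#' (id, ec50_molar) and \code{<prefix>.truth.json}. Full precision is kept
#' so \eqn{-\log_{10}} round-trips.
#'
#' @param set output of \code{\link{generateAnalogSet}}.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeAnalogSet <- function(set, prefix) {
  smiPath <- paste0(prefix, ".smi")
  actPath <- paste0(prefix, ".activities.tsv")
  truthPath <- paste0(prefix, ".truth.json")
  writeLines(paste(set$smiles, names(set$smiles)), smiPath)
  act <- data.frame(id = set$activities$id,
                    ec50_molar = sprintf("%.17g", set$activities$ec50_molar))
  utils::write.table(act, actPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(set$truth, truthPath, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(smiPath, actPath, truthPath))
}

#' Random small organic molecules for property testing
#'
#' Assembles valid SMILES from a fragment alphabet (chains, branches,
#' aromatic rings, heteroatoms, halogens); used by conservation and
#' oracle-equivalence suites that need many diverse structures.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @param maxFragments chain length in fragments (2 to maxFragments).
#' @return named character vector of SMILES.
#' @export
randomMolecules <- function(n, seed = 1, maxFragments = 5) {
  middles <- c("C", "CC", "CO", "CN", "CS", "C(C)", "C(F)", "C(Cl)",
               "c1ccccc1", "C(=O)", "CN(C)", "C(Br)", "CCO")
  terminals <- c("C", "O", "N", "Cl", "C#N", "C(=O)O", "c1ccoc1",
                 "c1ccncc1", "C(F)(F)F", "S", "c1cc[nH]c1")
  .withSeed(seed, {
    smi <- vapply(seq_len(n), function(i) {
      k <- sample(1:(maxFragments - 1), 1)
      paste0("C", paste(sample(middles, k, replace = TRUE), collapse = ""),
             sample(terminals, 1))
    }, "")
    names(smi) <- sprintf("rnd%04d", seq_len(n))
    smi
  })
}
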