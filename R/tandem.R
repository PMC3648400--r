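# The tandem screen itself.
#
# Stage 1 ("filter"): single-descriptor least-squares fits of activity,
# Y = b0 + b_ch * X_ch, ranked by r^2, repeated over property-ordered
# subsamples of increasing size to tally which descriptor dominates the
# bulk of the series.
#
# Stage 2 ("detector"): with the filter descriptor held in the model,
# two-predictor context equations Y = b0 + b_f * filter + b_ES * ES are
# fitted one E-state descriptor at a time and ranked by fit R^2; the sign
# of b_ES is the reported tendency of that structural modification.
# Exactly one ES descriptor enters an equation: the dependency diagnostics
# show how combining correlated ES descriptors flips coefficient signs and
# destroys interpretability.

.signChar <- function(x) ifelse(is.na(x), NA_character_,
                                ifelse(x > 0, "+", ifelse(x < 0, "-", "0")))

#' Read an activity table (compound id, EC50 in molar units)
#'
#' CSV or TSV with columns \code{id} and \code{ec50_molar} (a plain
#' \code{ec50} column is accepted). Missing, non-numeric or non-positive
#' EC50 values, and rows whose optional \code{flag}/\code{status} column
#' says \code{uncertain} or \code{indeterminate}, are dropped with a logged
#' count. The regression response is \eqn{Y = -\log_{10}(EC_{50})}.
#'
#' @param path file path; tab-separated if the extension is .tsv or the
#'   header contains a tab, comma-separated otherwise.
#' @return data.frame(id, ec50_molar, Y).
#' @export
readActivityTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1, warn = FALSE)
  sep <- if (grepl("\t", first) || grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  if (!"id" %in% names(df))
    stop("activity table needs an 'id' column", call. = FALSE)
  ecCol <- intersect(c("ec50_molar", "ec50"), names(df))[1]
  if (is.na(ecCol))
    stop("activity table needs an 'ec50_molar' column", call. = FALSE)
  n0 <- nrow(df)
  flagCol <- intersect(c("flag", "status"), names(df))[1]
  if (!is.na(flagCol)) {
    bad <- tolower(trimws(df[[flagCol]])) %in% c("uncertain", "indeterminate")
    df <- df[!bad, , drop = FALSE]
  }
  ec <- suppressWarnings(as.numeric(df[[ecCol]]))
  keep <- is.finite(ec) & ec > 0
  dropped <- n0 - sum(keep)
  if (dropped > 0)
    message("dropped ", dropped,
            " compound(s) with indeterminate or non-positive EC50")
  activityTable(df$id[keep], ec[keep])
}

#' Construct an activity table in memory
#'
#' @param id compound ids.
#' @param ec50_molar EC50 values in molar units (> 0).
#' @return data.frame(id, ec50_molar, Y) with \eqn{Y = -\log_{10}(EC_{50})}.
#' @export
activityTable <- function(id, ec50_molar) {
  stopifnot(length(id) == length(ec50_molar))
  if (any(!is.finite(ec50_molar) | ec50_molar <= 0))
    stop("EC50 values must be positive and finite", call. = FALSE)
  data.frame(id = as.character(id), ec50_molar = ec50_molar,
             Y = -log10(ec50_molar), stringsAsFactors = FALSE)
}

# Align a DescriptorMatrix with an activity table on compound id.
.alignActivities <- function(D, a, minN = 3) {
  m <- descriptorValues(D)
  common <- intersect(rownames(m), a$id)
  if (length(common) < minN)
    stop("fewer than ", minN, " compounds shared between descriptor ",
         "matrix and activity table", call. = FALSE)
  common <- rownames(m)[rownames(m) %in% common]  # keep matrix order
  list(X = m[common, , drop = FALSE],
       y = a$Y[match(common, a$id)], ids = common)
}

#' Ordinary least squares with an intercept
#'
#' @param X numeric matrix or data.frame of predictor columns (no
#'   intercept column; one is added).
#' @param y numeric response.
#' @return list with \code{coefficients} (intercept first),
#'   \code{r.squared}, \code{fitted}, \code{residuals}.
#' @export
fitLeastSquares <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y))
    stop("rows of X must match length of y", call. = FALSE)
  if (nrow(X) <= ncol(X) + 1)
    stop("need more observations than predictors plus intercept",
         call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0)
    stop("degenerate response: y is constant (SST = 0)", call. = FALSE)
  A <- cbind("(Intercept)" = 1, X)
  fit <- stats::lm.fit(A, y)
  if (fit$rank < ncol(A)) {
    aliased <- names(fit$coefficients)[is.na(fit$coefficients)]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sse <- sum(fit$residuals^2)
  list(coefficients = fit$coefficients, r.squared = 1 - sse / sst,
       fitted = fit$fitted.values, residuals = fit$residuals)
}

#' Stage-1 screen: one single-descriptor fit per descriptor
#'
#' Fits \eqn{Y = \beta_0 + \beta_{ch} X_{ch}} for every non-constant
#' descriptor and ranks by \eqn{r^2} (descending; ties broken
#' lexicographically by descriptor name). For a one-predictor fit
#' \eqn{r^2} equals the squared Pearson correlation.
#'
#' @param D a \code{\linkS4class{DescriptorMatrix}}.
#' @param a an activity table (see \code{\link{activityTable}}).
#' @return data.frame(descriptor, beta0, beta, r.squared, rank), sorted by
#'   rank; excluded constant descriptors in attribute \code{"excluded"}.
#' @export
screenSingleDescriptors <- function(D, a) {
  al <- .alignActivities(D, a)
  X <- al$X
  usable <- colnames(X)[apply(X, 2, function(v) max(v) - min(v) > 0)]
  skipped <- setdiff(colnames(X), usable)
  if (!length(usable))
    stop("no usable (non-constant) descriptors", call. = FALSE)
  res <- lapply(usable, function(nm) {
    f <- fitLeastSquares(X[, nm, drop = FALSE], al$y)
    data.frame(descriptor = nm, beta0 = unname(f$coefficients[1]),
               beta = unname(f$coefficients[2]), r.squared = f$r.squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ord <- order(-out$r.squared, out$descriptor, method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded") <- skipped
  out
}

#' Property-ordered subsample of a compound set
#'
#' Compounds are sorted by the named descriptor (descending by default)
#' and the top \code{size} taken; ties keep input order (stable sort).
#'
#' @param D a \code{DescriptorMatrix}.
#' @param a activity table (only compounds present in both are ranked).
#' @param property descriptor column used for ordering.
#' @param size number of compounds to keep (>= 3).
#' @param decreasing sort direction (default: largest first).
#' @return character vector of compound ids.
#' @export
subsetByProperty <- function(D, a, property, size, decreasing = TRUE) {
  al <- .alignActivities(D, a)
  if (!property %in% colnames(al$X))
    stop("property '", property, "' is not a descriptor column",
         call. = FALSE)
  if (size < 3) stop("subset size must be >= 3", call. = FALSE)
  if (size > nrow(al$X))
    stop("subset size exceeds compound count", call. = FALSE)
  ord <- order(al$X[, property], decreasing = decreasing, method = "radix")
  al$ids[ord[seq_len(size)]]
}

#' Stage-1 dominance tally over property-ordered subsamples
#'
#' For every data size, one subsample is drawn per ordering property (top
#' \code{size} compounds by that property) and screened with
#' \code{\link{screenSingleDescriptors}}; the rank-1 descriptor of each
#' subsample is recorded. The tally reports, per size: the modal dominant
#' descriptor, how often the focal descriptor was dominant, how often the
#' dominant descriptor matched the focal family pattern, how often the
#' focal descriptor was near-dominant (rank at most \code{nearRank}), and
#' the number of subsamples screened.
#'
#' @param D a \code{DescriptorMatrix}.
#' @param a activity table.
#' @param sizes integer vector of subsample sizes.
#' @param focal focal descriptor name (default \code{"Jurs_RNCG"}).
#' @param family regex matched against the dominant descriptor to count
#'   family dominance (default \code{"^Jurs"}).
#' @param nearRank focal rank threshold counted as near-dominant.
#' @param orderProperties descriptors used for ordering subsamples;
#'   default: every non-constant column (the screening pool orders its own
#'   subsamples).
#' @param decreasing subsample sort direction.
#' @return data.frame(size, modalDominant, focalDominant, familyDominant,
#'   nearDominant, totalSubsets).
#' @export
dominanceTally <- function(D, a, sizes, focal = "Jurs_RNCG",
                           family = "^Jurs", nearRank = 4,
                           orderProperties = NULL, decreasing = TRUE) {
  al <- .alignActivities(D, a)
  if (is.null(orderProperties))
    orderProperties <- colnames(al$X)[apply(al$X, 2,
                                            function(v) max(v) - min(v) > 0)]
  if (!focal %in% colnames(al$X))
    stop("focal descriptor '", focal, "' not in matrix", call. = FALSE)
  rows <- lapply(sizes, function(sz) {
    dominant <- character(); focalRank <- integer()
    for (p in orderProperties) {
      scr <- tryCatch({
        ids <- subsetByProperty(D, a, p, sz, decreasing = decreasing)
        Dsub <- new("DescriptorMatrix",
                    values = al$X[ids, , drop = FALSE],
                    constant = rep(FALSE, ncol(al$X)),
                    chargeMethod = D@chargeMethod,
                    excluded = data.frame(id = character(),
                                          reason = character()))
        asub <- data.frame(id = ids, Y = al$y[match(ids, al$ids)])
        screenSingleDescriptors(Dsub, asub)
      }, error = function(e) e)
      if (inherits(scr, "error")) {
        message("subset (property ", p, ", size ", sz, ") skipped: ",
                conditionMessage(scr))
        next
      }
      dominant <- c(dominant, scr$descriptor[1])
      fr <- scr$rank[scr$descriptor == focal]
      focalRank <- c(focalRank, if (length(fr)) fr else NA_integer_)
    }
    if (!length(dominant)) return(NULL)
    tab <- sort(table(dominant), decreasing = TRUE)
    data.frame(size = sz, modalDominant = names(tab)[1],
               focalDominant = sum(dominant == focal),
               familyDominant = sum(grepl(family, dominant)),
               nearDominant = sum(!is.na(focalRank) & focalRank <= nearRank),
               totalSubsets = length(dominant), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stage-2: rank context equations, one E-state descriptor at a time
#'
#' Fits \eqn{Y = \beta_0 + \beta_f \cdot filter + \beta_{ES} \cdot ES} for
#' every usable ES_Count/ES_Sum column, ranks equations by fit \eqn{R^2}
#' (descending, ties lexicographic), and reports the sign of
#' \eqn{\beta_{ES}} as the tendency of the structural modification.
#' Constant ES columns and ES columns collinear with the filter are
#' excluded with a logged reason.
#'
#' @param D a \code{DescriptorMatrix}.
#' @param a activity table.
#' @param filter filter descriptor column (default \code{"Jurs_RNCG"}).
#' @return data.frame(descriptor, beta0, betaFilter, betaES, r.squared,
#'   rank, sign), sorted by rank; exclusions in attribute
#'   \code{"excluded"} (data.frame descriptor, reason).
#' @export
prioritizeContextEquations <- function(D, a, filter = "Jurs_RNCG") {
  al <- .alignActivities(D, a, minN = 4)
  X <- al$X
  if (!filter %in% colnames(X))
    stop("filter descriptor '", filter, "' not in matrix", call. = FALSE)
  fcol <- X[, filter]
  if (max(fcol) - min(fcol) == 0)
    stop("filter descriptor '", filter, "' is constant", call. = FALSE)
  esNames <- grep("^ES_(Count|Sum)_", colnames(X), value = TRUE)
  if (!length(esNames)) stop("no ES descriptors in matrix", call. = FALSE)
  excluded <- data.frame(descriptor = character(), reason = character(),
                         stringsAsFactors = FALSE)
  rows <- list()
  for (nm in esNames) {
    v <- X[, nm]
    if (max(v) - min(v) == 0) {
      excluded <- rbind(excluded, data.frame(descriptor = nm,
                                             reason = "constant"))
      next
    }
    f <- tryCatch(fitLeastSquares(cbind(filter = fcol, es = v), al$y),
                  error = function(e) e)
    if (inherits(f, "error")) {
      excluded <- rbind(excluded,
                        data.frame(descriptor = nm,
                                   reason = "collinear with filter"))
      next
    }
    rows[[nm]] <- data.frame(descriptor = nm,
                             beta0 = unname(f$coefficients[1]),
                             betaFilter = unname(f$coefficients[2]),
                             betaES = unname(f$coefficients[3]),
                             r.squared = f$r.squared,
                             stringsAsFactors = FALSE)
  }
  if (nrow(excluded))
    message("excluded ES descriptor(s): ",
            paste(excluded$descriptor, "(", excluded$reason, ")",
                  collapse = ", "))
  if (!length(rows))
    stop("no usable ES descriptor for context equations", call. = FALSE)
  out <- do.call(rbind, rows)
  ord <- order(-out$r.squared, out$descriptor, method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$sign <- .signChar(out$betaES)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Monitor table: the top-k ranked context equations
#'
#' @param ranked output of \code{\link{prioritizeContextEquations}}.
#' @param k rows to keep (default 12, the conventional monitor size).
#' @return data.frame(rank, descriptor, sign, r.squared).
#' @export
monitorTable <- function(ranked, k = 12) {
  stopifnot(nrow(ranked) >= 1, k >= 1)
  top <- utils::head(ranked, k)
  data.frame(rank = top$rank, descriptor = top$descriptor,
             sign = top$sign, r.squared = top$r.squared,
             stringsAsFactors = FALSE)
}

#' Dependency diagnostics for the top-ranked ES descriptors
#'
#' Combining correlated ES descriptors in one equation makes coefficient
#' signs unreliable; these diagnostics expose the three failure modes:
#' (1) Count/Sum pairs of the same type (description dependency on the
#' same modification), (2) coefficient sign flips between the combined
#' multi-ES fit and the single-ES context equations, and (3) rare-moiety
#' descriptors supported by only a handful of compounds ("analog
#' outliers").
#'
#' @param D a \code{DescriptorMatrix}.
#' @param a activity table.
#' @param top character vector of ES descriptor names (>= 2), or the
#'   ranked data.frame from \code{\link{prioritizeContextEquations}} (its
#'   top rows are used).
#' @param filter filter descriptor kept in the combined fit.
#' @param k when \code{top} is a ranked data.frame, how many top rows.
#' @param rareSupport support count at or below which a descriptor is
#'   flagged as a rare-moiety "analog outlier" marker.
#' @return list with \code{correlations} (Pearson matrix among the top ES
#'   columns), \code{pairs} (data.frame of flagged pairs),
#'   \code{combined} (per-coefficient data.frame with \code{signFlip}),
#'   \code{support} (data.frame descriptor, support, rare) and
#'   \code{singular} (TRUE when the combined design was rank-deficient —
#'   itself dependency evidence).
#' @export
dependencyDiagnostics <- function(D, a, top, filter = "Jurs_RNCG", k = 12,
                                  rareSupport = 3) {
  singleSign <- NULL
  if (is.data.frame(top)) {
    tk <- utils::head(top, k)
    singleSign <- stats::setNames(tk$sign, tk$descriptor)
    top <- tk$descriptor
  }
  if (length(top) < 2) stop("need at least 2 top ES names", call. = FALSE)
  al <- .alignActivities(D, a, minN = 4)
  missing <- setdiff(c(top, filter), colnames(al$X))
  if (length(missing))
    stop("column(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(singleSign)) {
    pc <- prioritizeContextEquations(D, a, filter = filter)
    singleSign <- stats::setNames(pc$sign, pc$descriptor)[top]
  }
  E <- al$X[, top, drop = FALSE]
  cm <- stats::cor(E)
  # flagged pairs: same-type Count/Sum, and |r| >= 0.95
  baseType <- sub("^ES_(Count|Sum)_", "", top)
  pairs <- list()
  for (p in seq_along(top)) for (q in seq_len(p - 1L)) {
    sameType <- baseType[p] == baseType[q]
    r <- cm[p, q]
    if (sameType || (is.finite(r) && abs(r) >= 0.95))
      pairs[[length(pairs) + 1L]] <-
        data.frame(descriptor1 = top[q], descriptor2 = top[p], r = r,
                   sameTypePair = sameType, stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(descriptor1 = character(), descriptor2 = character(),
               r = numeric(), sameTypePair = logical())
  # combined multi-ES fit; singular designs are evidence, not failure
  A <- cbind("(Intercept)" = 1, filter = al$X[, filter], E)
  colnames(A) <- c("(Intercept)", filter, top)
  cf <- stats::lm.fit(A, al$y)
  singular <- cf$rank < ncol(A)
  co <- cf$coefficients[top]
  combined <- data.frame(descriptor = top, beta = unname(co),
                         sign = .signChar(unname(co)),
                         singleSign = unname(singleSign[top]),
                         stringsAsFactors = FALSE)
  combined$signFlip <- !is.na(combined$sign) &
    !is.na(combined$singleSign) & combined$sign != combined$singleSign
  support <- data.frame(descriptor = top,
                        support = apply(E, 2, function(v) sum(v != 0)),
                        stringsAsFactors = FALSE)
  support$rare <- support$support <= rareSupport
  rownames(support) <- NULL
  list(correlations = cm, pairs = pairs, combined = combined,
       support = support, singular = singular)
}
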