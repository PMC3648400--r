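# Pipeline orchestration: run both tandem stages end to end and emit the
# report bundle (TSV tables + JSON manifest). All tables are
# tab-separated with a '#'-prefixed header noting the run hash and charge
# model, so reports from one run are mutually attributable.

#' Assemble and validate a pipeline run configuration
#'
#' Either \code{molecules} + \code{activities} (file paths) or a synthetic
#' \code{spec} must be given. File existence is checked here, before any
#' computation.
#'
#' @param molecules SMILES (.smi) or SDF file of the compound set.
#' @param activities CSV/TSV activity table (id, ec50_molar).
#' @param spec an \code{\linkS4class{AnalogSetSpec}} to simulate instead
#'   of reading files.
#' @param pool descriptor pool configuration.
#' @param filter filter descriptor name.
#' @param sizes stage-1 subsample sizes (default: 10, 20, ... up to 10
#'   below the compound count).
#' @param topK monitor-table size.
#' @param seed RNG seed (simulation).
#' @param outDir output directory (created if missing).
#' @param largestFragment keep largest fragment of disconnected inputs.
#' @return a validated run-config list.
#' @export
runConfig <- function(molecules = NULL, activities = NULL, spec = NULL,
                      pool = descriptorPool(), filter = "Jurs_RNCG",
                      sizes = NULL, topK = 12, seed = 1,
                      outDir = "tandemro_out", largestFragment = FALSE) {
  if (is.null(spec)) {
    if (is.null(molecules) || is.null(activities))
      stop("config error: need molecules + activities files, or a spec",
           call. = FALSE)
    for (f in c(molecules, activities))
      if (!file.exists(f))
        stop("config error: file not found: ", f, call. = FALSE)
  } else stopifnot(is(spec, "AnalogSetSpec"))
  if (topK < 1) stop("config error: topK must be >= 1", call. = FALSE)
  structure(list(molecules = molecules, activities = activities,
                 spec = spec, pool = pool, filter = filter, sizes = sizes,
                 topK = topK, seed = seed, outDir = outDir,
                 largestFragment = largestFragment),
            class = "tandemroRunConfig")
}

.writeReport <- function(df, path, hash, chargeMethod) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("# run: ", hash),
               paste0("# charge_model: ", chargeMethod)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full tandem pipeline and write the report bundle
#'
#' Stages: descriptor matrix, stage-1 screen, dominance tally, stage-2
#' context-equation prioritization with monitor table, dependency
#' diagnostics, JSON run manifest. Any stage error aborts with a
#' stage-named message and removes partial outputs.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisibly, a list with all computed objects and the manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "tandemroRunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  result <- tryCatch({
    note <- function(p) { written <<- c(written, p); p }

    stage <- "input"
    if (!is.null(config$spec)) {
      set <- generateAnalogSet(config$spec, seed = config$seed)
      mols <- set$molecules
      act <- set$activities
      note(writeAnalogSet(set, file.path(config$outDir, "simulated"))[1])
      written <- c(written,
                   file.path(config$outDir,
                             c("simulated.activities.tsv",
                               "simulated.truth.json")))
    } else {
      mols <- if (grepl("\\.sdf$", config$molecules, ignore.case = TRUE))
        readSdfFile(config$molecules, config$largestFragment)
      else readSmilesFile(config$molecules, config$largestFragment)
      act <- readActivityTable(config$activities)
    }

    stage <- "config manifest"
    cfgPath <- file.path(config$outDir, "config.json")
    cfgOut <- config
    cfgOut$spec <- if (!is.null(config$spec))
      list(n = config$spec@n, sigma = config$spec@sigma,
           bulkCoef = config$spec@bulkCoef,
           intercept = config$spec@intercept,
           scaffold = config$spec@scaffold,
           moieties = config$spec@moieties)
    jsonlite::write_json(unclass(cfgOut), note(cfgPath), auto_unbox = TRUE,
                         digits = NA, na = "null", force = TRUE)
    # hash the scientific configuration only (output location excluded, so
    # identical runs in different directories are byte-identical)
    cfgHash <- cfgOut
    cfgHash$outDir <- NULL
    hashFile <- tempfile()
    jsonlite::write_json(unclass(cfgHash), hashFile, auto_unbox = TRUE,
                         digits = NA, na = "null", force = TRUE)
    hash <- unname(tools::md5sum(hashFile))
    unlink(hashFile)

    stage <- "descriptor matrix"
    D <- buildDescriptorMatrix(mols, pool = config$pool)
    note(writeDescriptorMatrix(D, file.path(config$outDir,
                                            "descriptors.tsv")))

    stage <- "stage-1 screen"
    scr <- screenSingleDescriptors(D, act)
    note(.writeReport(scr, file.path(config$outDir, "screen.tsv"),
                      hash, D@chargeMethod))

    stage <- "stage-1 dominance tally"
    nAligned <- length(intersect(rownames(descriptorValues(D)), act$id))
    sizes <- config$sizes
    if (is.null(sizes)) {
      top <- max(10, nAligned - 10)
      sizes <- seq(10, top, by = 10)
      sizes <- sizes[sizes <= nAligned]
    }
    tally <- dominanceTally(D, act, sizes, focal = config$filter)
    note(.writeReport(tally, file.path(config$outDir, "tally.tsv"),
                      hash, D@chargeMethod))

    stage <- "stage-2 context equations"
    ranked <- prioritizeContextEquations(D, act, filter = config$filter)
    note(.writeReport(ranked, file.path(config$outDir, "context.tsv"),
                      hash, D@chargeMethod))
    mon <- monitorTable(ranked, k = config$topK)
    note(.writeReport(mon, file.path(config$outDir, "monitor.tsv"),
                      hash, D@chargeMethod))

    stage <- "dependency diagnostics"
    dep <- dependencyDiagnostics(D, act, ranked, filter = config$filter,
                                 k = config$topK)
    depTab <- merge(dep$combined, dep$support, by = "descriptor",
                    sort = FALSE)
    note(.writeReport(depTab, file.path(config$outDir, "dependency.tsv"),
                      hash, D@chargeMethod))

    stage <- "run manifest"
    obv <- tryCatch(
      paste(suppressWarnings(
        system2(.obabelPath(), "-V", stdout = TRUE, stderr = FALSE)),
        collapse = " "),
      error = function(e) "unavailable")
    manifest <- list(
      package = "tandemro",
      version = as.character(utils::packageVersion("tandemro")),
      r_version = R.version.string,
      openbabel = obv,
      charge_model = D@chargeMethod,
      seed = config$seed,
      filter = config$filter,
      config_hash = hash,
      compounds = nrow(descriptorValues(D)),
      excluded = excludedCompounds(D)$id,
      outputs = basename(written))
    jsonlite::write_json(manifest,
                         note(file.path(config$outDir, "manifest.json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
    list(descriptors = D, activities = act, screen = scr, tally = tally,
         ranked = ranked, monitor = mon, dependency = dep,
         manifest = manifest)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
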