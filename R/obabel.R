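# Open Babel bridge. All chemistry I/O (SMILES/SDF/PDB reading, implicit-H
# assignment, kekulization, Gasteiger charges) is delegated to the obabel
# executable; this file shells out in batch and parses the returned text.

.obabelPath <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p))
    stop("the 'obabel' executable was not found on the PATH", call. = FALSE)
  p
}

# Run obabel on `input` text (written to a temp file with extension
# `informat`), producing `outformat`. Returns output lines.
.obabelRun <- function(input, informat, outformat, args = character()) {
  fin <- tempfile(fileext = paste0(".", informat))
  fout <- tempfile(fileext = paste0(".", outformat))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(input, fin)
  err <- tempfile(); on.exit(unlink(err), add = TRUE)
  status <- suppressWarnings(system2(.obabelPath(),
    c(shQuote(fin), paste0("-o", outformat), "-O", shQuote(fout), args),
    stdout = FALSE, stderr = err))
  if (!file.exists(fout) || status != 0)
    stop("obabel conversion failed: ",
         paste(readLines(err, warn = FALSE), collapse = " "), call. = FALSE)
  readLines(fout, warn = FALSE)
}

# Split concatenated SDF text into records (each a character vector).
.splitSdfRecords <- function(lines) {
  ends <- which(lines == "$$$$")
  if (!length(ends)) return(list())
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(function(s, e) lines[s:(e - 1L)], starts, ends)
}

# Parse one V2000 record into atom/bond tables plus formal charges.
.parseSdfRecord <- function(rec) {
  title <- trimws(rec[1])
  counts <- rec[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atomLines <- rec[5:(4 + na)]
  element <- trimws(substr(atomLines, 32, 34))
  xyz <- matrix(as.numeric(c(substr(atomLines, 1, 10),
                             substr(atomLines, 11, 20),
                             substr(atomLines, 21, 30))), ncol = 3)
  bonds <- if (nb > 0) {
    bl <- rec[(5 + na):(4 + na + nb)]
    data.frame(i = as.integer(substr(bl, 1, 3)),
               j = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else data.frame(i = integer(), j = integer(), order = integer())
  charge <- integer(na)
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    f <- scan(text = sub("^M  CHG *[0-9]+", "", ln), quiet = TRUE)
    if (length(f) >= 2) {
      idx <- f[seq(1, length(f), 2)]
      charge[idx] <- as.integer(f[seq(2, length(f), 2)])
    }
  }
  list(title = title, element = element, xyz = xyz, bonds = bonds,
       charge = charge)
}

# Parse a MOL2 text into per-molecule atom tables (element, charge).
.parseMol2 <- function(lines) {
  molStarts <- grep("^@<TRIPOS>MOLECULE", lines)
  out <- vector("list", length(molStarts))
  bounds <- c(molStarts, length(lines) + 1L)
  for (k in seq_along(molStarts)) {
    sec <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    ai <- grep("^@<TRIPOS>ATOM", sec)[1]
    bi <- grep("^@<TRIPOS>", sec)
    nxt <- bi[bi > ai][1]
    if (is.na(nxt)) nxt <- length(sec) + 1L
    atomLines <- sec[(ai + 1L):(nxt - 1L)]
    atomLines <- atomLines[nzchar(trimws(atomLines))]
    fields <- strsplit(trimws(atomLines), "[[:space:]]+")
    elem <- vapply(fields, function(f) sub("\\..*$", "", f[6]), "")
    q <- vapply(fields, function(f) as.numeric(f[9]), 0)
    # bond section (for folding H charges onto heavy neighbors)
    bsec <- grep("^@<TRIPOS>BOND", sec)[1]
    bondTab <- NULL
    if (!is.na(bsec)) {
      nxtb <- bi[bi > bsec][1]
      if (is.na(nxtb)) nxtb <- length(sec) + 1L
      bl <- sec[(bsec + 1L):(nxtb - 1L)]
      bl <- bl[nzchar(trimws(bl))]
      if (length(bl)) {
        bf <- strsplit(trimws(bl), "[[:space:]]+")
        bondTab <- data.frame(i = as.integer(vapply(bf, `[`, "", 2)),
                              j = as.integer(vapply(bf, `[`, "", 3)),
                              type = vapply(bf, `[`, "", 4),
                              stringsAsFactors = FALSE)
      }
    }
    out[[k]] <- list(element = elem, charge = q, bonds = bondTab)
  }
  out
}
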