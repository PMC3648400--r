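test_that("generation is deterministic and byte-identical per seed", {
  spec <- analogSetSpec(n = 15, seed = 3)
  s1 <- generateAnalogSet(spec, check = FALSE)
  s2 <- generateAnalogSet(spec, check = FALSE)
  expect_identical(s1$smiles, s2$smiles)
  expect_identical(s1$activities, s2$activities)
  d1 <- tempfile(); d2 <- tempfile()
  writeAnalogSet(s1, d1); writeAnalogSet(s2, d2)
  for (ext in c(".smi", ".activities.tsv", ".truth.json"))
    expect_identical(readLines(paste0(d1, ext)),
                     readLines(paste0(d2, ext)))
  s3 <- generateAnalogSet(spec, seed = 4, check = FALSE)
  expect_false(identical(s1$activities$ec50_molar,
                         s3$activities$ec50_molar))
})

test_that("noiseless single-moiety activities follow the planted model", {
  moi <- list(ether = list(unit = "OC", esType = "ssO", gamma = -1,
                           counts = 0:3))
  spec <- analogSetSpec(n = 12, sigma = 0, moieties = moi, seed = 5)
  set <- generateAnalogSet(spec)
  resid <- set$activities$Y - spec@intercept - spec@bulkCoef * set$rncg
  expect_equal(resid, -1 * set$counts$ether, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("EC50 emission round-trips through -log10 and through files", {
  set <- smallAnalogSet()$set
  expect_true(all(is.finite(set$activities$ec50_molar)))
  expect_true(all(set$activities$ec50_molar > 0))
  expect_equal(-log10(set$activities$ec50_molar), set$activities$Y,
               tolerance = 1e-12)
  prefix <- tempfile()
  writeAnalogSet(set, prefix)
  back <- readActivityTable(paste0(prefix, ".activities.tsv"))
  expect_equal(back$Y, set$activities$Y, tolerance = 1e-12)
})

test_that("planted truth lists nonzero effects with signs and rarity", {
  spec <- analogSetSpec()
  tr <- plantedTruth(spec)
  expect_equal(tr$sign[tr$esType == "ssO"], "-")
  expect_equal(tr$sign[tr$esType == "sssN"], "+")
  oxa <- tr[tr$esType == "aaO", ]
  expect_true(oxa$rare)
  expect_equal(oxa$expectedSupport, 2L)
  expect_false("ssCH2" %in% tr$esType)  # zero-effect moiety not in truth

  moiZero <- lapply(defaultMoieties(), function(m) { m$gamma <- 0; m })
  expect_equal(nrow(plantedTruth(analogSetSpec(moieties = moiZero))), 0L)
})

test_that("rare moieties land in exactly their declared support", {
  set <- smallAnalogSet()$set
  expect_equal(sum(set$counts$oxazole > 0), 2L)
  m <- descriptorValues(smallAnalogSet()$D)
  expect_equal(sum(m[, "ES_Count_aaO"] > 0), 2L)
})

test_that("declared moiety signatures match the emitted structures", {
  # the self-consistency gate passes for the default library ...
  expect_silent(tandemro:::.checkMoietySignatures(analogSetSpec(n = 10)))
  # ... and catches a wrong declaration, naming the fragment
  badMoi <- list(ether = list(unit = "OC", esType = "sssN", gamma = -1,
                              counts = 0:2))
  expect_error(generateAnalogSet(analogSetSpec(n = 10, moieties = badMoi)),
               "incompatible.*sssN")
})

test_that("generated molecules carry the declared per-compound counts", {
  set <- smallAnalogSet()$set
  m <- descriptorValues(smallAnalogSet()$D)
  base <- parseSmiles(sub("{T}", "C", analogSetSpec()@scaffold,
                          fixed = TRUE))
  baseSsO <- sum(esAtomTypes(base) == "ssO")
  expect_equal(unname(m[, "ES_Count_ssO"]),
               baseSsO + set$counts$ether, ignore_attr = TRUE)
  baseN <- sum(esAtomTypes(base) == "sssN")
  expect_equal(unname(m[, "ES_Count_sssN"]),
               baseN + set$counts$amine, ignore_attr = TRUE)
})

test_that("YAML spec files configure the generator", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("n: 12", "sigma: 0.05", "bulk_coef: 10",
               "moieties:", "  ether:", "    unit: OC",
               "    es_type: ssO", "    gamma: -2",
               "    counts: [0, 1, 2]"), cfg)
  spec <- readAnalogSetSpec(cfg)
  expect_equal(spec@n, 12)         # YAML 1.1 'n'-as-boolean is undone
  expect_equal(spec@sigma, 0.05)
  expect_equal(spec@bulkCoef, 10)
  expect_equal(names(spec@moieties), "ether")
  expect_equal(spec@moieties$ether$gamma, -2)
  set <- generateAnalogSet(spec, seed = 2)
  expect_equal(nrow(set$activities), 12L)
})

test_that("random molecule generator is seeded and all-parseable", {
  a <- randomMolecules(30, seed = 2)
  b <- randomMolecules(30, seed = 2)
  expect_identical(a, b)
  gl <- parseSmilesSet(a)
  expect_length(gl, 30)
})
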