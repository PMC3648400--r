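test_that("SMILES parsing builds the expected graphs", {
  g <- parseSmiles("CCO")
  expect_equal(atoms(g)$element, c("C", "C", "O"))
  expect_equal(atoms(g)$nH, c(3L, 2L, 1L))
  expect_equal(nrow(bonds(g)), 2L)
  expect_true(all(bonds(g)$order == "single"))

  furan <- parseSmiles("c1ccoc1")
  expect_equal(nrow(atoms(furan)), 5L)
  expect_true(all(atoms(furan)$aromatic))
  expect_equal(sum(atoms(furan)$element == "O"), 1L)
  expect_true(all(bonds(furan)$order == "aromatic"))
  expect_equal(nrow(bonds(furan)), 5L)
})

test_that("malformed SMILES are rejected with the token position", {
  expect_error(parseSmiles("C("), "position 2.*unmatched")
  expect_error(parseSmiles("CC)C"), "position 3")
  expect_error(parseSmiles("C1CC"), "unclosed ring")
  expect_error(parseSmiles("C[C"), "unmatched '\\['")
  expect_error(parseSmiles("CxC"), "unexpected character")
  expect_error(parseSmiles(""), "empty")
})

test_that("kekule aromatic input is perceived as aromatic", {
  g <- parseSmiles("C1=CC=CC=C1")
  expect_true(all(atoms(g)$aromatic))
  expect_equal(esAtomTypes(g), rep("aaCH", 6))
})

test_that("disconnected inputs are rejected unless largestFragment", {
  expect_error(parseSmiles("CCO.[Na]"), "disconnected")
  g <- parseSmiles("CC(=O)O.CCO", largestFragment = TRUE)
  expect_equal(nrow(atoms(g)), 4L)  # acetic acid kept, ethanol dropped
})

test_that("graph distances match a brute-force BFS oracle", {
  propane <- parseSmiles("CCC")
  D <- graphDistanceMatrix(propane)
  expect_equal(D[1, 3], 2)
  expect_equal(diag(D), rep(0, 3))

  for (g in parseFixtures()) {
    D <- graphDistanceMatrix(g)
    expect_equal(D, unname(bfsDistanceOracle(g)), ignore_attr = TRUE)
    expect_true(isSymmetric(unname(D)))
  }
  cyclo <- graphDistanceMatrix(parseSmiles("C1CCCCC1"))
  expect_true(all(cyclo <= 3))
})

test_that("heavy degree counts bonds to heavy neighbors", {
  expect_equal(heavyDegree(parseSmiles("CC(C)C"), 2), 3L)
  expect_equal(heavyDegree(parseSmiles("CCO"), 3), 1L)
  expect_equal(heavyDegree(parseSmiles("CC(C)(C)C"), 2), 4L)
  expect_error(heavyDegree(parseSmiles("CC"), 5), "out of range")
})

test_that("canonical-SMILES round trip preserves the graph signature", {
  for (nm in names(fixtureSmiles)) {
    g <- parseFixtures()[[nm]]
    g2 <- parseSmiles(canonicalSmiles(g))
    expect_equal(graphSignature(g2), graphSignature(g), label = nm)
  }
})

test_that("valence arithmetic holds for parsed neutral molecules", {
  # non-aromatic atoms: element valence = bond-order sum + H count.
  # Aromatic atoms are excluded: under the perception model an aromatic
  # bond has no integer order (pyrrole N carries two "aromatic" bonds yet
  # trivalent), so the check applies to the kekule-ordered remainder.
  valence <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1)
  orderVal <- c(single = 1, double = 2, triple = 3)
  for (nm in c("ethane", "ethanol", "aceticacid", "acetonitrile", "tzd",
               "isobutane", "neopentane", "chloromethane",
               "trimethylamine", "formaldehyde")) {
    g <- parseFixtures()[[nm]]
    a <- atoms(g)
    for (i in which(!a$aromatic)) {
      bs <- bonds(g)[bonds(g)$i == i | bonds(g)$j == i, ]
      tot <- sum(orderVal[bs$order]) + a$nH[i]
      expect_equal(tot, unname(valence[a$element[i]]),
                   label = paste(nm, "atom", i))
    }
  }
})

test_that("SMILES and SDF readers agree on the same molecules", {
  smiPath <- tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccoc1 furan", "# comment", ""), smiPath)
  fromSmi <- readSmilesFile(smiPath)
  expect_named(fromSmi, c("ethanol", "furan"))

  # write an SDF via obabel and read it back through the package
  sdfPath <- tempfile(fileext = ".sdf")
  system2(Sys.which("obabel"), c(shQuote(smiPath), "-osdf", "-O",
                                 shQuote(sdfPath)),
          stdout = FALSE, stderr = FALSE)
  fromSdf <- readSdfFile(sdfPath)
  expect_length(fromSdf, 2L)
  expect_equal(graphSignature(fromSdf[[1]]), graphSignature(fromSmi[[1]]))
  expect_equal(graphSignature(fromSdf[[2]]), graphSignature(fromSmi[[2]]))
})

test_that("batch parsing is deterministic and order-preserving", {
  smi <- randomMolecules(25, seed = 11)
  g1 <- parseSmilesSet(smi)
  g2 <- parseSmilesSet(smi)
  expect_identical(lapply(g1, atoms), lapply(g2, atoms))
  expect_identical(names(g1), names(smi))
})
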