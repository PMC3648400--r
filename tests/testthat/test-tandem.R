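# helper: wrap a plain matrix as a DescriptorMatrix
dmat <- function(m) {
  new("DescriptorMatrix", values = m,
      constant = apply(m, 2, function(v) max(v) - min(v) == 0),
      chargeMethod = "gasteiger",
      excluded = data.frame(id = character(), reason = character()))
}

test_that("activity ingestion drops indeterminate EC50 values", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tec50_molar\tflag",
               "a\t1e-6\tok", "b\t1e-8\tok", "c\t-1\tok",
               "d\tn.d.\tok", "e\t1e-7\tuncertain"), path)
  expect_message(a <- readActivityTable(path), "dropped 3")
  expect_equal(a$id, c("a", "b"))
  expect_equal(a$Y, c(6, 8))
  expect_error(activityTable("x", 0), "positive")
})

test_that("least squares matches the normal-equations oracle", {
  set.seed(5)
  for (k in 1:25) {
    n <- sample(20:100, 1)
    p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    f <- fitLeastSquares(X, y)
    expect_equal(unname(f$coefficients), normalEquationsOracle(X, y),
                 tolerance = 1e-8)
    expect_gte(f$r.squared, 0); expect_lte(f$r.squared, 1)
  }
  # exact fit
  x <- 1:10
  f <- fitLeastSquares(cbind(x = x), 3 + 2 * x)
  expect_equal(unname(f$coefficients), c(3, 2))
  expect_equal(f$r.squared, 1)
})

test_that("degenerate designs raise the documented errors", {
  x <- rnorm(10)
  expect_error(fitLeastSquares(cbind(x = x), rep(1, 10)),
               "degenerate response")
  expect_error(fitLeastSquares(cbind(a = x, b = 2 * x), rnorm(10)),
               "collinear column.*b")
  expect_error(fitLeastSquares(cbind(x = x[1:3]), rnorm(10)), "rows")
  expect_error(fitLeastSquares(matrix(rnorm(6), 3, 2), rnorm(3)),
               "more observations")
})

test_that("single-descriptor r-squared equals squared Pearson correlation", {
  set.seed(8)
  m <- cbind(A = rnorm(50), B = rnorm(50), C = rnorm(50))
  rownames(m) <- sprintf("c%02d", 1:50)
  y <- 2 * m[, "A"] + rnorm(50, 0, 0.5)
  a <- data.frame(id = rownames(m), Y = y)
  scr <- screenSingleDescriptors(dmat(m), a)
  for (nm in colnames(m)) {
    r2 <- scr$r.squared[scr$descriptor == nm]
    expect_equal(r2, cor(m[, nm], y)^2, tolerance = 1e-12)
  }
  expect_equal(scr$descriptor[1], "A")
  expect_equal(sort(scr$rank), 1:3)
})

test_that("a descriptor equal to Y dominates with r-squared 1", {
  set.seed(9)
  y <- rnorm(30)
  m <- cbind(exact = y, noise = rnorm(30), flat = rep(1, 30))
  rownames(m) <- sprintf("c%02d", 1:30)
  scr <- screenSingleDescriptors(dmat(m), data.frame(id = rownames(m), Y = y))
  expect_equal(scr$descriptor[scr$rank == 1], "exact")
  expect_equal(scr$r.squared[scr$rank == 1], 1)
  expect_false("flat" %in% scr$descriptor)  # constant excluded
  expect_equal(attr(scr, "excluded"), "flat")
})

test_that("an uninformative descriptor has near-zero r-squared", {
  set.seed(10)
  n <- 2000
  m <- cbind(indep = rnorm(n))
  rownames(m) <- sprintf("c%04d", 1:n)
  scr <- screenSingleDescriptors(dmat(m),
                                 data.frame(id = rownames(m), Y = rnorm(n)))
  expect_lt(scr$r.squared[1], 0.01)
})

test_that("property-ordered subsets take the top block, stably", {
  m <- cbind(p = c(5, 3, 9, 1, 7), q = c(2, 2, 2, 2, 2))
  rownames(m) <- letters[1:5]
  a <- data.frame(id = letters[1:5], Y = 1:5)
  D <- dmat(m)
  expect_equal(subsetByProperty(D, a, "p", 3), c("c", "e", "a"))
  expect_equal(subsetByProperty(D, a, "p", 5), c("c", "e", "a", "b", "d"))
  # ties keep input order
  expect_equal(subsetByProperty(D, a, "q", 3), c("a", "b", "c"))
  expect_error(subsetByProperty(D, a, "p", 2), ">= 3")
  expect_error(subsetByProperty(D, a, "p", 9), "exceeds")
  # ascending switch
  expect_equal(subsetByProperty(D, a, "p", 2 + 1, decreasing = FALSE),
               c("d", "b", "a"))
})

test_that("a perfectly linear descriptor dominates every subset", {
  set.seed(12)
  n <- 60
  m <- cbind(lin = rnorm(n), other = rnorm(n), third = rnorm(n))
  rownames(m) <- sprintf("c%02d", 1:n)
  y <- 5 - 2 * m[, "lin"]
  a <- data.frame(id = rownames(m), Y = y)
  tally <- dominanceTally(dmat(m), a, sizes = c(10, 30, 50),
                          focal = "lin", family = "^lin")
  expect_equal(tally$focalDominant, tally$totalSubsets)
  expect_equal(tally$familyDominant, tally$totalSubsets)
  expect_equal(tally$nearDominant, tally$totalSubsets)
  expect_true(all(tally$modalDominant == "lin"))
  expect_equal(tally$totalSubsets, rep(3L, 3))  # one subset per pool column
  # invariant: dominant <= family <= total
  expect_true(all(tally$focalDominant <= tally$familyDominant))
  expect_true(all(tally$familyDominant <= tally$totalSubsets))
})

test_that("context equations recover the planted modification", {
  sa <- smallAnalogSet()
  ranked <- prioritizeContextEquations(sa$D, sa$set$activities)
  top <- monitorTable(ranked, k = 12)
  expect_match(top$descriptor[1], "ssO")
  expect_equal(top$sign[1], "-")
  sssN <- top[grepl("sssN", top$descriptor), ]
  expect_gte(nrow(sssN), 1)
  expect_true(all(sssN$sign == "+"))
})

test_that("collinear and constant ES columns are excluded with reasons", {
  set.seed(13)
  n <- 40
  f <- rnorm(n)
  m <- cbind(Jurs_RNCG = f, ES_Count_dup = 2 * f + 1,
             ES_Count_flat = rep(3, n), ES_Count_ok = rnorm(n))
  rownames(m) <- sprintf("c%02d", 1:n)
  a <- data.frame(id = rownames(m), Y = f + rnorm(n, 0, 0.1))
  expect_message(ranked <- prioritizeContextEquations(dmat(m), a),
                 "excluded ES")
  expect_equal(ranked$descriptor, "ES_Count_ok")
  ex <- attr(ranked, "excluded")
  expect_setequal(ex$descriptor, c("ES_Count_dup", "ES_Count_flat"))
  mflat <- cbind(Jurs_RNCG = rep(1, n), ES_Count_x = f)
  rownames(mflat) <- rownames(m)
  expect_error(prioritizeContextEquations(dmat(mflat), a), "constant")
})

test_that("stage-2 ranking is invariant to affine rescaling of ES columns", {
  sa <- smallAnalogSet()
  m <- descriptorValues(sa$D)
  a <- sa$set$activities
  r0 <- prioritizeContextEquations(sa$D, a)
  m2 <- m
  m2[, "ES_Count_ssO"] <- 7 * m2[, "ES_Count_ssO"] + 3
  m2[, "ES_Sum_sssN"] <- -m2[, "ES_Sum_sssN"]
  r1 <- prioritizeContextEquations(dmat(m2), a)
  expect_equal(r1$descriptor, r0$descriptor)
  expect_equal(r1$r.squared, r0$r.squared, tolerance = 1e-9)
  s0 <- setNames(r0$sign, r0$descriptor)
  s1 <- setNames(r1$sign, r1$descriptor)
  expect_equal(s1[["ES_Count_ssO"]], s0[["ES_Count_ssO"]])
  expect_false(s1[["ES_Sum_sssN"]] == s0[["ES_Sum_sssN"]])
})

test_that("adding a constant to Y shifts only the intercepts", {
  sa <- smallAnalogSet()
  a <- sa$set$activities
  a2 <- a; a2$Y <- a2$Y + 10
  r0 <- prioritizeContextEquations(sa$D, a)
  r1 <- prioritizeContextEquations(sa$D, a2)
  idx <- match(r0$descriptor, r1$descriptor)  # near-ties may swap ranks
  expect_equal(r1$beta0[idx], r0$beta0 + 10, tolerance = 1e-8)
  expect_equal(r1$betaES[idx], r0$betaES, tolerance = 1e-8)
  expect_equal(r1$betaFilter[idx], r0$betaFilter, tolerance = 1e-8)
  expect_equal(r1$descriptor[r1$rank <= 3], r0$descriptor[r0$rank <= 3])
})

test_that("monitor table truncates, keeps order, and is deterministic", {
  sa <- smallAnalogSet()
  ranked <- prioritizeContextEquations(sa$D, sa$set$activities)
  expect_equal(nrow(monitorTable(ranked, k = 12)), 12L)
  expect_equal(nrow(monitorTable(ranked, k = 10000)), nrow(ranked))
  expect_identical(monitorTable(ranked),
                   monitorTable(prioritizeContextEquations(
                     sa$D, sa$set$activities)))
  expect_equal(monitorTable(ranked, k = 3)$rank, 1:3)
})

test_that("dependency diagnostics flag pairs, rarity, and sign flips", {
  sa <- smallAnalogSet()
  ranked <- prioritizeContextEquations(sa$D, sa$set$activities)
  dep <- dependencyDiagnostics(sa$D, sa$set$activities, ranked, k = 12)
  prs <- dep$pairs
  sameType <- prs[prs$sameTypePair, ]
  expect_gte(nrow(sameType), 1)
  # rare oxazole moiety planted in exactly 2 compounds
  aaO <- dep$support[grepl("aaO", dep$support$descriptor), ]
  if (nrow(aaO)) {
    expect_true(all(aaO$support == 2))
    expect_true(all(aaO$rare))
  }

  # constructed collinearity forces a sign flip (verified by the oracle)
  set.seed(21)
  n <- 60
  cnt <- sample(0:4, n, replace = TRUE)
  smc <- cnt + rnorm(n, 0, 0.1)         # cor > 0.95 with cnt
  expect_gt(cor(cnt, smc), 0.95)
  y <- 8 * cnt - 5 * smc + rnorm(n, 0, 0.3)
  m <- cbind(Jurs_RNCG = rnorm(n), ES_Count_t = cnt, ES_Sum_t = smc)
  rownames(m) <- sprintf("c%02d", 1:n)
  a <- data.frame(id = rownames(m), Y = y)
  dep2 <- dependencyDiagnostics(dmat(m), a,
                                c("ES_Count_t", "ES_Sum_t"))
  expect_true(any(dep2$combined$signFlip))
  expect_true(dep2$pairs$sameTypePair[1])
  # combined coefficients agree with the normal-equations oracle
  co <- normalEquationsOracle(m[, c("Jurs_RNCG", "ES_Count_t", "ES_Sum_t")], y)
  expect_equal(dep2$combined$beta, unname(co[3:4]), tolerance = 1e-8)
})

test_that("a singular combined design is evidence, not an error", {
  set.seed(22)
  n <- 30
  x <- rnorm(n)
  m <- cbind(Jurs_RNCG = rnorm(n), ES_Count_t = x, ES_Sum_t = 2 * x)
  rownames(m) <- sprintf("c%02d", 1:n)
  a <- data.frame(id = rownames(m), Y = x + rnorm(n, 0, 0.1))
  dep <- dependencyDiagnostics(dmat(m), a, c("ES_Count_t", "ES_Sum_t"))
  expect_true(dep$singular)
})
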