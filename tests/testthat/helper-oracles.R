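# Independent oracles and shared fixtures.
#
# The oracles deliberately avoid the package's computation paths: BFS by
# queue for distances, an explicit double loop over ordered atom pairs for
# E-state perturbations, and the normal equations for least squares.

# Brute-force BFS shortest-path distances over the bond list.
bfsDistanceOracle <- function(g) {
  n <- nrow(atoms(g))
  adj <- vector("list", n)
  b <- bonds(g)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (D[s, w] > D[s, v] + 1) {
        D[s, w] <- D[s, v] + 1
        queue <- c(queue, w)
      }
    }
  }
  D
}

# E-state values by an explicit loop over all ordered pairs.
estateOracle <- function(g) {
  I <- intrinsicStates(g)
  D <- bfsDistanceOracle(g)
  n <- length(I)
  S <- numeric(n)
  for (i in seq_len(n)) {
    s <- I[i]
    for (j in seq_len(n)) if (j != i)
      s <- s + (I[i] - I[j]) / (D[i, j] + 1)^2
    S[i] <- s
  }
  S
}

# OLS coefficients by the normal equations.
normalEquationsOracle <- function(X, y) {
  A <- cbind(1, as.matrix(X))
  solve(t(A) %*% A, t(A) %*% y)[, 1]
}

# A small, chemically diverse SMILES panel reused across tests.
fixtureSmiles <- c(
  ethane = "CC", propane = "CCC", ethanol = "CCO", furan = "c1ccoc1",
  benzene = "c1ccccc1", dimethylether = "COC", trimethylamine = "CN(C)C",
  formaldehyde = "C=O", isobutane = "CC(C)C", neopentane = "CC(C)(C)C",
  chloromethane = "CCl", pyridine = "c1ccncc1", pyrrole = "c1cc[nH]c1",
  oxazole = "c1ocnc1", aceticacid = "CC(=O)O", benzoicacid = "OC(=O)c1ccccc1",
  tzd = "O=C1NC(=O)SC1", toluene = "Cc1ccccc1", cyclohexane = "C1CCCCC1",
  acetonitrile = "CC#N", naphthalene = "c1ccc2ccccc2c1",
  rosiglitazone = "CN(CCOc1ccc(CC2SC(=O)NC2=O)cc1)c1ccccn1")

parseFixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- parseSmilesSet(fixtureSmiles)
    cache
  }
})

# Small synthetic analog set shared by tandem-stage tests (cheap: n = 40).
smallAnalogSet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- analogSetSpec(n = 40, seed = 7)
      set <- generateAnalogSet(spec, seed = 7)
      cache <<- list(set = set, D = buildDescriptorMatrix(set$molecules))
    }
    cache
  }
})

# Multiset signature used by the SMILES round-trip isomorphism check.
graphSignature <- function(g) {
  a <- atoms(g)
  deg <- vapply(seq_len(nrow(a)), function(i) heavyDegree(g, i), 0L)
  sort(paste(a$element, a$nH, deg, a$aromatic, sep = ":"))
}
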