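---
title: "A tandem filter/detector regression screen for ligand SAR series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tandem filter/detector regression screen for ligand SAR series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemro)
```

## The problem and the idea

In a ligand-dependent, receptor-mediated cellular assay the measured
response (here pEC50, $Y = -\log_{10} EC_{50}$ in molar units) mixes two
kinds of signal: a *bulk* component that varies smoothly with gross
physicochemical character across the whole analog series, and a *specific*
component contributed by individual structural modifications that make or
break binding contacts. Compounds carrying such modifications behave as
influential observations — outliers — of any regression built on bulk
properties alone.

This package implements a two-stage ("tandem") screen that mirrors a
tandem separation/detection instrument:

1. **Filter.** Single-descriptor equations $Y = \beta_0 + \beta_{ch}
   X_{ch}$ are fitted for every descriptor in a pool and ranked by $r^2$,
   over many property-ordered subsamples of increasing size. The
   descriptor that dominates these screens as the sample grows is the bulk
   carrier; for charge-driven receptor systems this is the Jurs relative
   negative charge, $RNCG = |q_{\min}| / \sum_{q_i<0} |q_i|$.
2. **Detector.** With the filter held in the model, two-predictor *context
   equations* $Y = \beta_0 + \beta_f \cdot filter + \beta_{ES} \cdot ES$
   are fitted one electrotopological-state (E-state) descriptor at a time
   and ranked by fit $R^2$. Each ES descriptor names one kind of
   structural modification; the sign of $\beta_{ES}$ is the tendency of
   that modification's impact on the cellular response. The top of the
   ranking (a 12-row "monitor table" by convention) is the screen's
   output.

Exactly one ES descriptor enters each context equation. The dependency
diagnostics below show why this restriction is essential.

## E-state descriptors

Every heavy atom receives a bond-pattern type: one prefix letter per bond
to a heavy neighbor (`t` triple, `d` double, `a` aromatic, `s` single,
written in that order), the element, and an `H`/`H2`/`H3` suffix when
hydrogens are attached. An ether oxygen is `ssO`, a tertiary amine
nitrogen `sssN`, an aromatic-ring oxygen `aaO`, a methylene `ssCH2`, a
carbonyl oxygen `dO`.

Each atom also gets an intrinsic state

$$I = \frac{(2/N)^2\,\delta^v + 1}{\delta},$$

with $\delta$ the number of heavy neighbors, $\delta^v = Z^v - n_H -
q_{formal}$ the valence-electron count less attached hydrogens (a formal
charge shifts it by its sign), and $N$ the principal quantum number. The
E-state value perturbs $I$ by every other atom through the topological
distance $d_{ij}$:

$$S_i = I_i + \sum_{j \neq i} \frac{I_i - I_j}{(d_{ij}+1)^2}.$$

The perturbation runs over **all** heavy-atom pairs (no cutoff), and
$r_{ij} = d_{ij}+1$ so bonded neighbors have $r = 2$. Because the
perturbations are pairwise antisymmetric, $\sum_i S_i = \sum_i I_i$
exactly — a conservation law the test suite checks to $10^{-9}$ on a
thousand random molecules. Per molecule, `ES_Count_t` counts the atoms of
type $t$ and `ES_Sum_t` sums their $S$ values; raw (possibly negative)
$S$ values are summed, untruncated.

```{r estate}
ev <- estateValues(parseSmiles("CCC"))
ev[, c("type", "delta", "deltaV", "I", "S")]
```

## Perception model and charges

Chemical parsing is delegated to Open Babel: SMILES/SDF reading, the
valence model and implicit hydrogens, and kekulization. Aromaticity
follows Open Babel's own perception (its MOL2 aromatic-bond flags,
restricted to ring bonds so that delocalized but acyclic groups such as
carboxylates keep their kekulé orders). The aromatic types
`aaO`/`aaN`/`aaCH`/`aaaC` depend on this model, which is why reports stamp
the perception provenance. Hydrogens never appear as graph nodes — E-state
typing reads heavy-atom topology plus H counts.

Partial charges default to Gasteiger–Marsili with hydrogen charges folded
onto their heavy atoms. RNCG needs only a charge-coherent *ordering*, not
any particular charge model, so its role as bulk filter is robust to this
choice; the model name is stamped into every report. Surface-weighted
charged-partial-surface-area descriptors are deliberately out of scope:
RNCG is the only charge descriptor the method uses and it needs no 3D
surface.

Disconnected inputs (salts, mixtures) are rejected by default; a
`largestFragment` switch keeps the dominant component instead.

## The synthetic analog series

Published SAR sets are rarely machine-readable, so the generator builds
one from first principles and is itself first-class, tested code. Every
compound shares a thiazolidinedione-like head (`O=C1NC(=O)SC1Cc1ccc({T})cc1`)
and a tail assembled from moiety units:

| moiety    | unit        | ES signature | default effect $\gamma$ |
|-----------|-------------|--------------|-------------------------|
| ether     | `OC`        | `ssO`        | $-1.5$ per count        |
| amine     | `CN(C)`     | `sssN`       | $+1.0$ per count        |
| methylene | `C`         | `ssCH2`      | $0$ (structural nuisance) |
| oxazole   | `C(c2ocnc2)`| `aaO`        | $+2.0$, planted in exactly 2 compounds |

Activities follow $Y = \beta_0 + \beta_g \cdot RNCG + \sum_k \gamma_k
\cdot count_k + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$, with
defaults $n = 150$, $\sigma = 0.3$, $\beta_0 = 6$ (a typical pEC50) and
$\beta_g = 25$. The bulk coefficient was set so that the RNCG spread of
the series (an SD near 0.06 under Gasteiger charges) moves activity by
roughly 1.5 log units — comparable to a single strong moiety effect,
which is the regime the tandem design assumes. The bulk term uses each
compound's *computed* RNCG, not an independent latent variable, so stage-1
dominance of the filter is a property of the construction, matching the
premise that the filter captures all general effects. Noise is Gaussian on
the log-activity scale, consistent with least-squares regression of pEC50.
EC50 values are emitted as $10^{-Y}$ and round-trip through files at full
precision.

The rare oxazole pair mirrors the classic "analog outlier": a moiety
carried by two potent compounds only, whose descriptor is zero elsewhere.
A self-consistency gate verifies at generation time that one unit of each
moiety changes the count of its declared ES type by exactly one on the
emitted structures.

What the generator does *not* emulate: real series have correlated,
non-additive effects, activity cliffs not expressible as counts,
measurement error that is not i.i.d. Gaussian, and bulk behavior that no
single descriptor carries exactly. Passing recovery tests therefore shows
the machinery is sound under its own model, not that any particular real
system obeys that model.

```{r recover}
set <- suppressMessages(generateAnalogSet(analogSetSpec(n = 60, seed = 4)))
D <- buildDescriptorMatrix(set$molecules)
ranked <- suppressMessages(prioritizeContextEquations(D, set$activities))
monitorTable(ranked, k = 6)
set$truth
```

## Stage-1 subsampling choices

"Property-ordered subsamples" are built by sorting compounds on a pool
descriptor (descending by default; direction is a switch) and taking the
top $n$; ties keep input order. One subsample per ordering descriptor per
size keeps the screen deterministic. Default sizes run 10, 20, … up to ten
below the set size — for other set sizes the size list is a parameter, as
the pattern does not dictate a unique generalization. The tally reports
the modal dominant descriptor per size, the focal descriptor's dominance
count, its family's count, and a near-dominance count (focal rank $\le 4$;
the threshold is an argument).

## Ranking, ties, and degeneracies

"Prioritized by correlation coefficient" is implemented as ranking by fit
$R^2$ — for one predictor this is $r^2$, for two it is the squared
multiple correlation, the only reading consistent across both stages.
Ties break lexicographically by descriptor name for reproducibility.
Constant descriptors are excluded from screens (flagged, logged); ES
columns collinear with the filter are excluded from stage 2 with a logged
reason; a constant response is a hard error. In the dependency
diagnostics a singular combined design is *reported as dependency
evidence*, not raised as a failure.

## Dependency diagnostics

Three failure modes motivate the one-ES-per-equation rule, and
`dependencyDiagnostics()` surfaces each: (1) `Count_t`/`Sum_t` pairs of
one type are near-collinear descriptions of the same modification (their
correlation typically exceeds 0.95 in congeneric series); (2) forcing
correlated ES descriptors into a single fit flips coefficient signs
relative to their single-ES context equations — the diagnostics flag every
such flip; (3) rare-moiety descriptors with support in only a few
compounds are "analog outlier" markers whose signs rest on those few
observations (support $\le 3$ flags them by default; the oxazole pair in
the synthetic series shows support 2).

## Contact verification

The detector's output is a claim about binding contacts, so the package
can check a top-ranked ES type against a crystal structure: select the
ligand atoms of that type in a protein–ligand complex and measure
heavy-atom distances to named protein atoms (hydrogens are invisible to
X-ray crystallography). PDB files carry no bond orders, so ligand bonds
are perceived from the 3D geometry by Open Babel, or supplied as a SMILES
plus an atom-name map. Altloc conformers resolve to the highest occupancy
unless forced. For the published PPARγ worked examples the relevant
entries are 2PRG (rosiglitazone, ligand code BRL) and 1K74 (the
tyrosine-class agonist; the literature also prints the accession as
"1K47", but 1K74 is the real entry and is the one the documentation
refers to). These entries must be fetched from the PDB; the test suite
exercises the same machinery on synthetic complexes built in code, whose
distances are known by construction.

## Problem sizes used by the checks

The conservation and oracle suites use 1,000 and a few dozen random
molecules respectively; the recovery experiment uses the default spec
(n = 150) over 100 seeds; the dominance experiment uses one bulk-only
series (all $\gamma = 0$, $\sigma = 0.2$) with sizes 10–140. These sizes
were chosen to make the statistical statements sharp (resolving a
recovery rate near 95% needs on the order of 100 replicates) while
staying comfortably within a desktop run.

## Known limitations

* Aromaticity, tautomers and charge states are whatever Open Babel
  perceives; descriptor values for borderline heterocycles follow its
  model, and agreement with values from other QSAR engines on
  geometry-optimized structures is not expected to be exact.
* $\delta^v$ applies the principal-quantum-number correction only through
  the $(2/N)^2$ factor, with formal charges shifting $\delta^v$ by their
  sign; heavier-element special cases beyond that are not implemented.
* The stage-1 pool ships with a handful of bulk competitors
  (size, weight, ring bonds, polarity fraction) — an extensible stand-in
  for a full commercial descriptor catalogue, not a reimplementation of
  one.
* Formal influential-observation statistics (Cook's distance and kin) are
  intentionally absent: the method's outlier handling *is* the
  prioritization of context equations.
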