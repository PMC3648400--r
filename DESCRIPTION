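Package: tandemro
Title: Tandem Regression-Outlier Analysis of Ligand Cellular Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage regression screen for structure-activity series of
    receptor ligands. Stage one finds the bulk descriptor that dominates
    single-descriptor fits of cellular activity over property-ordered
    subsamples; stage two holds that filter descriptor fixed and ranks
    two-predictor context equations, one electrotopological-state (E-state)
    descriptor at a time, to expose the key structural modifications and
    the sign of their impact on binding. Includes from-scratch computation
    of Kier-Hall E-state atom types and values and of the Jurs relative
    negative charge (RNCG) descriptor, a planted-truth analog-set
    generator, dependency diagnostics for collinear descriptor pairs, and
    heavy-atom contact measurement in protein-ligand complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
SystemRequirements: OpenBabel (the 'obabel' executable on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
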