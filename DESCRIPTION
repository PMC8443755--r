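Package: acdtol
Title: Site Tolerability Prediction for Acridonylalanine Incorporation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a protein site will tolerate incorporation of the
    bulky fluorescent unnatural amino acid acridon-2-yl-alanine (Acd).
    Structure-derived empirical score terms (heavy-atom contact-count deltas,
    Shrake-Rupley accessible surface area, relative accessibility) and
    bioinformatics features (BLOSUM62 rows, transfer free-energy
    hydrophobicity scales, a melting-temperature-change measure) are combined
    with per-residue Rosetta-style energy-term deltas at the mutation site and
    its 8 Angstrom contact sphere. Balanced binary responses (soluble yield,
    total yield, soluble fraction) are modelled with a classifier zoo tuned by
    stratified five-fold cross-validated grid search over univariate
    ANOVA-selected features, alongside correlation screens and
    backward-selection multiple linear regression. A synthetic-data module
    generates helix structures with bulky planar mutant sidechains, replicate
    score tables with planted energy shifts, and labelled feature matrices
    with known sparse signal, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    class,
    e1071,
    kernlab,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    Biostrings
Config/testthat/edition: 3
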