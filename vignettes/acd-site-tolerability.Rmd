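---
title: "Predicting site tolerability to acridonylalanine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting site tolerability to acridonylalanine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Genetic-code expansion lets a protein carry the fluorescent unnatural amino
acid acridon-2-yl-alanine (Acd), but the incorporation site decides whether
the mutant expresses well: the same substitution that is harmless at one
position can crater soluble yield at another, and neither residue identity
nor simple hydrophobicity predicts which. The working hypothesis behind this
package is that tolerability is a *local structural* property — whether the
environment of the site can desolvate and accommodate a bulky planar
tricyclic sidechain — so features describing local perturbation
(contact-count changes, accessibility, per-residue energy-term changes at
the site and its 8 Å neighbourhood) should predict the phenotype where
global descriptors (total energy change, CαRMSD, substitution matrices
alone) fail.

`acdtol` implements that analysis as a reusable, fully tested pipeline:
structure handling and geometry, two feature families, response labelling
and holdout construction, a tuned classifier zoo, and regression-based
screens, with a synthetic-data module that makes every stage testable
offline.

## Feature model

**Contact deltas (empirical score terms).** Heavy-atom pairs involving the
mutation site with pairwise distance strictly below 4 Å count as contacts,
categorized by polarity (nonpolar iff both atoms are C or S; any pair
containing N or O is polar), pairing (backbone–backbone, backbone–sidechain,
sidechain–sidechain; backbone atoms are exactly N, CA, C, O, OXT) and
locality (intra- vs inter-residue). Pairs separated by one or two covalent
bonds are excluded — bonded geometry is not a contact — using bond templates
for the twenty standard residues and distance-inferred bonds (≤ 1.8 Å) for
nonstandard ones, with the same rule applied across the two peptide
junctions. The feature for a mutation is the fieldwise difference
mutant − WT of the twelve category counts and their three totals. Hydrogens
are excluded throughout: crystal-derived inputs rarely carry them, and a
heavy-atom convention keeps WT/mutant parity.

Three conventions here were genuinely open and are configurable:

* *Strict inequality* at the 4 Å boundary (an atom pair at exactly 4.0 Å is
  not a contact), reading "< 4 Å" literally.
* *Mixed polar/nonpolar pairs count as polar* (default): "nonpolar contact"
  is read as a fully hydrophobic pairing. `mixed_polarity = "nonpolar"` or
  `"drop"` switch the convention.
* Inter-residue contacts are counted once per unordered pair.

**Accessibility.** ASA of the pre-mutation residue is computed on the
wild-type structure with a Shrake–Rupley rolling-probe approximation: probe
radius 1.4 Å (water), Bondi van der Waals radii, and a deterministic
Fibonacci-spiral point set (960 points/atom, giving ~1% error against the
analytic isolated-sphere area; the test suite also checks two overlapping
spheres against an independent Monte-Carlo oracle). RSA divides by the
theoretical per-residue maxima of Tien et al. (2013), so extended
conformations may exceed 1. ASA/RSA are absolute properties of the residue
about to be mutated, not deltas.

**Bioinformatics lookups.** The BLOSUM62 row of the wild-type residue
(including the score for mutation to histidine), three transfer free-energy
scales (cyclohexane→water, vapor→water, octanol→water) and a
melting-temperature-change-vs-glycine measure, all bundled as documented
TSV tables in `inst/extdata`. The ΔTm table is a constructed, clearly
labelled synthetic stand-in (the exact source scale was not available) and
is designed to be swapped file-for-file. Conservation and secondary-structure
descriptors are accepted as user-supplied columns rather than computed:
they need MSAs or DSSP, which are out of scope.

**Energy deltas.** Per-residue, per-term weighted scores in REU are
ingested from a plain-text dialect (`#meta` line, `residue` header, one row
per residue) standing in for a Rosetta per-residue score breakdown; no
weight set is applied because the scores are already weighted, and the
residue total score is treated as just another term. The five replicates per
variant are averaged per cell, and each term becomes two features:
`t_Site`, the averaged delta at the site, and `t_8A`, the *mean* delta over
the contact sphere (residues with Cα–Cα distance ≤ 8 Å from the site,
closed boundary, site excluded). Averaging rather than summing over the
sphere keeps the feature independent of sphere size. An empty sphere yields
zero with a warning. CαRMSD is provided in both superposed (Kabsch) and
fixed-frame modes, since locally relaxed replicate structures may share a
frame; both are exposed and the superposed value is never larger.

## Labelling, splitting and learning

**Labels.** Each response is binarized at its balance cutoff — soluble
yield 520 nM, total yield 1600 nM, soluble fraction 39% — with values
strictly above the cutoff active and ties inactive (matching the convention
that a soluble fraction *equal to or below* 39% is a failure).

**Holdout.** `make_holdout()` reserves `round(0.2 n)` samples (half away
from zero), split as equally as possible across proteins (5 + 5 at the
51-sample 32:19 shape). Within each protein, samples are drawn
proportionally from quartile bins of the *full* response distribution:
binning globally rather than per protein makes the held-out response
distribution — and any cutoff-defined class balance — track the dataset
(the suite checks agreement within one sample over 100 seeds), which
per-protein quantiles do not guarantee. Exact-tie remainders go to a
seeded-random bin so no quartile is systematically favoured. The sampler is
deterministic given its seed, and an explicit-membership mode accepts a
published holdout list verbatim.

**Feature selection and tuning.** Features are scored by one-way ANOVA F
between classes (computed by `stats::anova` per column; constant columns
score 0 with a warning) and the top k kept, ties to the earlier column. The
cap k ≤ 10 guards against overfitting at n ≈ 51. The number of features is
chosen per algorithm by stratified-CV accuracy at default hyperparameters
(ties to the smaller k), then hyperparameters are tuned by exhaustive
Cartesian grid search under stratified 5-fold CV. Two hygiene rules are
enforced and probed by a dedicated leakage test: standardization (or, for
Bernoulli naive Bayes, median binarization) and feature selection are
re-fitted inside each training fold, never on held-out rows; and CV metrics
pool the out-of-fold predictions into a single integer confusion matrix,
matching the way single CV confusion matrices are reported.

The zoo maps to established implementations — ridge-penalized logistic
regression (`glmnet`; a lambda grid stands in for the inverse-C grid of
common toolkits), LDA/QDA (`MASS`), C-, nu- and degree-3 polynomial SVMs
(`e1071`), k-nearest neighbours (`class`), Gaussian naive Bayes (`e1071`),
Bernoulli naive Bayes as median-binarized `naiveBayes`, and a Gaussian
process classifier (`kernlab`). Kernel ridge regression has no R
implementation in the dependency set and is solved directly —
α = (K + λI)⁻¹y on ±1-encoded labels with an RBF kernel — and read out as a
classifier by sign, ties inactive. Grids are deliberately small (1–9
points); they are repo-defined defaults, not a published tuning table, and
are declared per algorithm in `default_model_specs()`.

**Metrics and importance.** Accuracy, precision, recall and F1 follow their
confusion-matrix definitions exactly, with zero-denominator ratios reported
as NaN with a warning, and 3-decimal half-away-from-zero rounding for
reporting. `reconstruct_confusion()` inverts rounded printed metric triples
back to integer confusion matrices by exhaustive enumeration, as an
internal-consistency check on reported tables. The stratified dummy
baseline draws labels from training class frequencies (expected accuracy
p² + (1−p)² at prior p). Feature importance is taken from logistic
coefficients on standardized features, scaled to 100 at the maximum
absolute coefficient.

**Regression screens.** Pearson (continuous) or point-biserial (binary)
correlation ranks features by |R| with stable ties. `fit_mlr()` reports
R = √R², an adjusted R defined as the sign-preserving square root of
adjusted R² floored at zero (the adjusted transform is not standardized in
the field's summary tables; this choice is documented rather than assumed),
the overall F and its upper-tail p-value. Backward selection starts from
the ten most correlated candidates and repeatedly drops the largest-p
coefficient until all p ≤ 0.05.

## The synthetic-data module

The generators define the study conditions the tests run under:

* **Structures.** A 24-residue ideal α-helix (cylindrical parametrization:
  1.5 Å rise and 100° twist per residue, consecutive Cα–Cα ≈ 3.83 Å) with
  backbone N/CA/C/O plus a CB template sidechain, written and re-read as
  standard PDB. The mutant replaces the site sidechain with a planar
  fused-ring dummy of configurable size (default 8 carbon atoms in two
  staggered 1.4 Å rows along the CA→CB direction), mimicking the acridone's
  footprint: big, flat, nonpolar. Clashes are allowed (with a warning) —
  perturbed contacts are precisely what the features measure.
* **Score tables.** WT replicate cells are i.i.d. N(0, σ²); mutant cells
  scatter with fresh noise around the *empirical* WT replicate mean plus
  planted shifts (site δ = 2.0 REU, sphere γ = 0.5 REU, σ = 0.3 REU, 5
  replicates). Centering on the empirical mean makes the WT noise cancel
  from the deltas, so the recovery error is governed by the fresh noise
  alone: sd σ/√5 at the site, and the suite asserts recovery within 4σ/√5
  across 100 seeds.
* **Labelled datasets.** 51 samples × 30 standard-normal features, a sparse
  latent signal (coefficients 3, 2, 1 on features 1–3) plus N(0, 0.593²)
  noise, labels cut at the latent median (balanced within one). The noise
  sd places the Bayes accuracy of the labels at 0.95, from
  P(misclassification) = (π/2 − arctan(s/σ))/π for signal sd s = √14.
  Samples carry two pseudo-protein tags interleaved at 32:19 and
  phenotype-style records derived from the latent response, so holdout
  construction is exercised on the exact dataset shape of the study.

What the generators do *not* emulate: real sidechain chemistry and rotamers,
correlated energy terms, heteroscedastic replicate noise, and
protein-specific feature distributions. Passing tests therefore demonstrate
the pipeline's statistical machinery — selection without leakage, tuning,
recovery of planted effects at realistic n — not that any particular real
protein will be predicted at the same accuracy.

## Numerical choices and degenerate inputs

* Alternate locations resolve to the highest-occupancy conformer, first
  record winning ties; waters and non-amino-acid heteroatoms are dropped
  unless kept explicitly; hydrogens are excluded from contacts and SASA.
* Sulfur is nonpolar (hydrophobicity-oriented contact definition).
* Residue numbering follows the input file; no renumbering.
* Grid-search ties resolve to the first grid point in declared order;
  feature-count ties to the smaller k; KRR and the label rule both treat
  exact ties as inactive.
* All randomness (folds, splits, dummy draws, generators) flows from
  explicit integer seeds, and package functions restore the caller's RNG
  state.
* Reporting rounds half away from zero to 3 decimals; `round_half_away()`
  is exported because base R rounds half to even.

Problem sizes in the test suite were chosen to keep the full run at a few
minutes on one core while leaving the statistical assertions well-powered:
100-seed oracle and recovery loops, 50-seed learning-recovery and
permutation controls at n = 51, 200-seed null-calibration of prob F.

## Known limitations

* Backward elimination with a per-coefficient threshold of 0.05 retains at
  least one spurious feature on pure noise with probability
  ≈ 1 − 0.95^p for p candidates (~40% at p = 10). This is a property of
  the procedure, not of the implementation; on null data expect small
  non-empty models in a sizeable minority of runs. Applications that need
  strict null control should lower `p_threshold` or pre-screen fewer
  candidates.
* The ΔTm-vs-glycine table is a labelled synthetic stand-in; swap in the
  exact source scale for faithful reuse of that feature.
* The per-algorithm hyperparameter grids are small, desk-scale defaults;
  they bound, rather than exhaust, each algorithm's capacity.
* Ten-sample holdouts make single-seed holdout metrics coarse (steps of
  0.1); seed-to-seed variation of ±0.2 around the median is normal and the
  suite asserts medians over seeds, not single draws.
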