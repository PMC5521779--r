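---
title: "Structure-based asparagine deamidation prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based asparagine deamidation prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Asparagine deamidation proceeds through a succinimide intermediate: the
backbone nitrogen of residue *i*+1 attacks the Asn side-chain carbonyl
carbon (CG). `deamidate` treats liability prediction as binary
classification of candidate Asn sites, with one experimentally anchored
descriptor (the penta-peptide deamidation half-life of the local
sequence) and twelve structure-derived descriptors capturing what the
sequence cannot: conformation (φ, ψ, χ₁, χ₂, a 4-level secondary
structure code), flexibility (B-factor z-scores of the C, Cα, Cβ, Cγ
atoms), solvent exposure (PSA, PSSA) and the attack-geometry proxy
(CG···N(*i*+1) distance).

The key assumptions are: (a) a single high-resolution X-ray structure is
an adequate surrogate for the solution ensemble — B-factor z-scores
partially compensate, but the attack distance in particular is a static
snapshot; (b) crystallographic B-factors are comparable across
structures only after z-scoring against each structure's own atom
population; (c) sites whose chemistry the half-life table cannot
describe (Yyy = Q) or whose atoms are missing are excluded rather than
imputed.

## Site enumeration and structure handling

Structures are read from PDB-format text (wwPDB v3.3 fixed columns;
mmCIF is out of scope). Sanitization is deliberately minimal and
deterministic: hydrogens are dropped (all descriptors are defined over
heavy atoms), waters and unmapped hetero residues move to a ligand
store, a small built-in table maps common modified residues (MSE, SEP,
TPO, ...) to their parents, and alternate locations are resolved by
keeping the highest-occupancy conformer with ties broken by the
alphabetically first altloc code — the standard convention where the
original curation tool's behaviour is unpublished. No missing-atom
rebuilding is attempted; a site missing a required atom is reported
with a reason, not fixed.

When no chain is named, the working chain is the one with the most
residues carrying a complete backbone (N, CA, C, O), ties broken by
file order. "Most complete" is our reading of an otherwise undefined
selection rule. C-terminal Asn residues are excluded (no *i*+1 backbone
nitrogen exists to attack), and N-terminal Asn residues are excluded
because φ is undefined; both exclusions are reported.

## Descriptor details and numerical choices

**Half-life lookup.** The table covers 18 Xxx × 17 Yyy measured pairs.
Rules apply in a fixed order: Yyy = P gets a 999-day sentinel (stored
in days, used untransformed); Yyy = Q is not predictable; Yyy = N
shifts the penta-peptide window one residue toward the C-terminus
(re-applying the P/Q rules to the shifted successor, and giving up if
the chain of Asn successors leaves the window undefined); Xxx ∈ {N, Q}
or a missing predecessor substitutes Xxx = G, because the N-terminal
neighbour barely affects the rate. The numeric values are user-supplied
configuration (they are an external experimental data set); the package
ships a coverage-validated template with a placeholder column, and a
clearly labelled synthetic stand-in for testing.

**Dihedrals.** Computed with the atan2 torsion formula under the IUPAC
sign convention (0 = cis, 180 = trans, right-handed looking from atom 2
to atom 3), range (−180, 180]. χ₂ ends at OD1 by the IUPAC rule for
asparagine; the side-chain carbonyl carbon is CG by PDB nomenclature.
Degenerate geometry (coincident or collinear consecutive points) is an
error, not a NaN. Note one property worth stating precisely: the signed
torsion is *invariant* under reversing the four points (the viewing
direction and the handedness flip together) and antisymmetric under
mirror reflection; the test suite asserts both, against an independent
rotation-matrix oracle.

**B-factor z-scores.** μ and σ are taken over all heavy protein atoms
of all chains of the structure, excluding waters, ligands and
hydrogens, with the population (not sample) σ. The source description
("all atoms") does not resolve these choices; ours are documented here
and fixed. A uniform-B structure (σ = 0) yields all-zero z-scores with
a warning.

**Solvent accessibility.** Shrake–Rupley sphere sampling with a 1.4 Å
probe and 960 points per atom, on a deterministic Fibonacci lattice (no
RNG, so extraction is bit-reproducible); doubling the point count moves
PSA by under one percentage point on test fixtures. Radii: C 1.70,
N 1.55, O 1.52, S 1.80 Å. Percentages are relative to the maximal ASA
of Asn in a fully extended Gly-Asn-Gly tripeptide built by the
package's own generator and measured by the same sampling code — a
self-consistent reference in the spirit of published theoretical
maximal-ASA scales, swappable via the `reference` argument. Ratios
above 100 (e.g. a terminal, unusually exposed residue) are clipped with
a warning. The reference tool used for the original percent values is
closed-source, so systematic offsets against it are expected; within
one pipeline the values are consistent.

**Secondary structure.** A simplified Kabsch–Sander assignment: amide
hydrogens are rebuilt 1 Å from N along the preceding C=O direction, the
electrostatic H-bond energy uses the standard 0.084·332 factor with a
−0.5 kcal/mol cutoff, and pairs closer than 3 residues in sequence are
ignored. Runs of two consecutive n-turns (n = 3, 4, 5) make helices
(code 1), Kabsch–Sander bridge patterns make sheet (2), single-H-bond
turns make 4, everything else is coil (3); chains shorter than 3
residues are all coil. This reproduces canonical geometries (ideal
α-helix interiors code 1, extended chains never do) but is not a full
DSSP reimplementation.

## Training protocol

Features are centered and scaled by the training table's per-feature
mean and sample sd; test rows are always transformed with the training
statistics (the suite asserts this leakage contract). Constant features
scale to zero with a warning.

Cross-validation is stratified 10-fold with a required, logged seed
(default 20170721). When the positive class has fewer members than
folds, folds shrink with a warning. Hyperparameters come from a grid
search at a breadth comparable to an automatic-search default: random
forest 500 trees, mtry ∈ {2, 3, 4, 6}; SVM cost ∈ {0.25, …, 4} with an
RBF width from the median heuristic scaled by {0.5, 1, 2}; KNN k ∈ {3,
…, 11}; ANN single hidden layer, size ∈ {3, 5, 7}, decay ∈ {0, 0.01,
0.1}; PLS-DA 1–3 components; naive Bayes has no grid. Ties on CV
accuracy keep the first grid point in declared order, making tuning
deterministic. The reported CV accuracy is the tuned (non-nested)
value; with a 24-point grid it carries a modest optimism bias, which we
accept and document rather than hide behind nested CV.

The original work fit all six families through a generic modelling
framework whose exact grids are unpublished; no equivalent framework is
available here, so each family is implemented in-package behind one
fit/predict-probability interface: the random forest is a compiled CART
ensemble (Gini splitting, bootstrap, leaf-probability averaging,
mean-decrease-in-impurity importances) driven by R's RNG for
reproducibility; the SVM solves the soft-margin dual QP with
`quadprog`, with a logistic (Platt-style) map from decision values to
probabilities; the ANN is trained by BFGS on cross-entropy with L2
decay; PLS-DA is NIPALS PLS1 on the 0/1 label with a logistic link on
the latent score, so the regression algorithm yields calibrated-enough
probabilities and a confusion matrix like the classifiers. KNN
probabilities are neighbour vote fractions with index-order tie
breaking. No resampling or class weighting is applied to the unbalanced
data — only stratified folds — matching the reported protocol.

**RFE.** Iteratively refit the random forest, drop the least important
feature (ties broken by column order), repeat; the ranking is the
elimination order, last survivor first. Reported weights are the
full-model importances rescaled so the top-ranked feature is exactly
100, clipped to [0, 100] and made non-increasing (a running minimum)
so the two definitions — elimination order and importance order —
cannot disagree in the output.

## Evaluation conventions

With 5 positives in 81 sites, degenerate confusion matrices are normal,
so the conventions matter: precision is undefined ("-") when tp + fp =
0, never 0 or 1; MCC is 0 whenever a denominator factor vanishes, so an
all-negative predictor scores like a random one; displayed values are
rounded half-up to 2 decimals while JSON reports keep full precision.
AUC is the trapezoid integral of the threshold-swept ROC (anchored at
(0,0) and (1,1)), which equals the Mann–Whitney statistic with ties
counted one half; the suite proves this equivalence against brute-force
pair counting. The NG-motif baseline predicts positive iff Yyy = G —
deliberately the naive rule, to quantify what structure adds.

## What the synthetic data does and does not establish

The generator has two halves. Peptide structures are grown from
internal coordinates (ideal bond lengths/angles, ω = 180°, the −120°
improper fixing L-chirality, prescribed φ/ψ/χ), so every geometric
descriptor has a known ground truth; a dodecahedral 4 Å carbon shell
provides a reproducible burial construction. PDB text carries 3-decimal
coordinates, which limits torsion round-trips through *text* to about
0.05°; the exact (1e−6) round-trip contract is therefore asserted on
the full-precision in-memory structure, and the text path at format
precision.

Feature tables plant a known signal at the study-like compositions
(194 sites / 28 positive train, 81 / 5 test): a label-correlated
bimodal half-life (fast versus 999-like), moderate shifts (0.45–0.6 ×
`effect` sd) on ψ, χ₂, φ and two B-factor z-scores, and
class-independent noise elsewhere, with secondary structure carrying no
signal — mirroring the qualitative importance structure of real
deamidation data. The label correlation scales with `effect`, so
`effect = 0` is a genuine null table. Default `effect = 2` sd is a
strong, clearly recoverable signal.

A green benchmark test therefore establishes that the pipeline recovers
planted signal, respects its seeds, and beats the majority-class rate
(166/194 ≈ 0.856) — it does **not** establish biological accuracy on
real proteins, which requires the curated training structures and the
measured half-life table that cannot ship with the package. For the
same reason the published cross-validation accuracies, the blind-test
confusion matrix, the ROC curves and the RFE weights are not
desk-reproducible here; what the package does reproduce exactly is the
metric arithmetic of the printed tables, and its `evaluate` command
recomputes metric rows deterministically from any stored prediction
table.

## Known limitations

- Static attack distances ignore dynamics; ensemble (MD-derived)
  distances are an explicit future hook, as is Asp isomerization.
- SASA percentages and secondary-structure codes can differ
  systematically from closed-source tools' values.
- Gln deamidation is out of scope.
- The SVM probability map is fit on training decision values without
  Platt's regularized targets; with few positives it can saturate.
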