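# deamidate

Structure-based prediction of asparagine deamidation liability in
proteins.

## The problem

Asparagine (Asn) residues in protein therapeutics can spontaneously
deamidate: the backbone amide nitrogen of the *following* residue
attacks the Asn side-chain carbonyl carbon (CG), forming a cyclic
succinimide that hydrolyses to aspartate or isoaspartate. In an
antibody CDR this chemical "hotspot" can destroy binding potency, so
liability assessment is a routine step in developability screening. The
common sequence rule — flag every NG motif (Asn followed by Gly) — has
high recall but poor precision, and drives over-engineering.

`deamidate` implements a structure-based alternative: each candidate
Asn site is described by 13 descriptors and classified by machine
learning models trained on experimentally annotated sites.

## The descriptor set

For an Asn at position *i* with neighbours Xxx (*i*−1) and Yyy (*i*+1):

| Descriptor | Meaning | Units |
|---|---|---|
| `half_life` | measured deamidation half-life of the Gly-Xxx-Asn-Yyy-Gly penta-peptide | days |
| `phi`, `psi` | backbone torsions φ, ψ of the Asn | degrees |
| `chi1`, `chi2` | side-chain torsions χ₁ (N-CA-CB-CG), χ₂ (CA-CB-CG-OD1) | degrees |
| `secondary_structure` | helix = 1, sheet = 2, coil = 3, turn = 4 | code |
| `zb_c`, `zb_ca`, `zb_cb`, `zb_cg` | B-factors of C, Cα, Cβ, Cγ, z-scored against all heavy atoms of the structure: z = (B − μ)/σ | — |
| `psa`, `pssa` | percent solvent accessibility of the residue / side chain | % |
| `attack_distance` | CG···N(*i*+1) nucleophilic attack distance | Å |

Substitution rules for the half-life lookup: Yyy = P → 999-day sentinel
(proline cannot attack); Yyy = Q → site not predictable; Yyy = N →
shift the penta-peptide window one residue down; Xxx ∈ {N, Q} or
absent → use Xxx = G.

Six classifier families are available — random forest (compiled CART
ensemble), RBF-kernel SVM (dual QP via `quadprog`), Gaussian naive
Bayes, k-nearest-neighbour, a single-hidden-layer neural network, and
PLS discriminant analysis — all behind one protocol: center/scale
preprocessing, seeded stratified 10-fold cross-validation with grid
search, probability output, and recursive feature elimination (RFE) for
descriptor ranking. Evaluation uses the unbalanced-data metric suite:
confusion matrix, accuracy, recall, specificity, precision (reported
"-" when nothing is predicted positive), MCC (0 on degenerate
denominators), and trapezoid ROC/AUC, plus the NG-motif baseline for
comparison.

Because the experimental penta-peptide half-life table is not
redistributable, it is user-supplied configuration: get the skeleton
with `write_half_life_template()` (or the `template` CLI subcommand),
fill in the measured values, and pass it to `extract_features()`. A
clearly synthetic stand-in (`synthetic_half_life_table()`) supports
testing.

## Worked example

Build a synthetic helical peptide, extract descriptors, then train and
apply a random forest on the planted-signal benchmark:

```r
library(deamidate)

tab <- synthetic_half_life_table(seed = 1)   # stand-in for the measured table
s <- read_structure(build_peptide(peptide_spec(
  "GANGAANG", phi = -60, psi = -45,
  bfactor = function(n) seq(10, 40, length.out = n))))
extract_features(s, tab)
#>   chain resseq icode xxx yyy status half_life phi psi chi1  chi2
#> 1     A      3         A   G     ok      1.82 -60 -45  -65 -20.0
#> 2     A      7         A   G     ok      1.82 -60 -45  -65 -20.1
#>   secondary_structure   zb_c  zb_ca  zb_cb  zb_cg  psa pssa attack_distance
#> 1                   1 -0.805 -0.887 -0.644 -0.564 72.6 71.2            4.03
#> 2                   1  0.967  0.887  1.128  1.208 86.1 94.1            4.03
```

Both Asn-Gly sites sit in a helix (code 1), with the second more
exposed (PSA 86%) and more flexible (positive B-factor z-scores); the
4.03 Å attack distance is the CG···N separation the succinimide must
close.

```r
bm <- build_benchmark(seed = 1)              # 194/28 train, 81/5 test
m <- train_model(bm$train$features, bm$train$labels,
                 model_config("RANDOM_FOREST", seed = 1))
m
#> <deam_model> RANDOM_FOREST trained on 194 sites (28 positive); CV accuracy 0.984
head(predict(m, bm$test$features, sites = data.frame(site = 1:81)), 3)
#>    site probability label
#> 55   55       0.920     1
#> 70   70       0.620     1
#> 37   37       0.612     1
```

Sites are ranked by deamidation probability; on this benchmark the five
planted positives rank on top (test AUC 1.0). The metric suite
reproduces a published blind-test row from its confusion counts:

```r
metrics(confusion_counts(4, 3, 73, 1))
#> accuracy 0.95  recall 0.80  specificity 0.96  precision 0.57  mcc 0.65  auc -
```

## Command line

An executable is installed at `exec/deamidate` under the package
directory (subcommands `extract`, `train`, `predict`, `evaluate`,
`rank-features`, `template`):

```sh
deamidate extract in.pdb --half-life-table hl.csv --out features.csv
deamidate train train.csv --algorithm random-forest --seed 1 --out model/
deamidate predict features.csv --model model/model.json --out ranked.csv
deamidate evaluate eval.csv --baseline ng-motif --out report/
```

Exit codes: 0 success, 2 usage/config error, 3 data error.

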