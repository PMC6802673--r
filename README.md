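# fetalbone

Classification of fetal and maternal bone development from serum bone-turnover
biomarkers.

## The problem

Studies of maternal nutrition restriction in pregnant ruminants measure a small
number of animals under a 2×2×2 factorial design — animal type (fetus/mother),
treatment (control/restricted feeding), gestation period (middle/late) — and
record six serum bone-turnover proteins (PTH, BALP, BGLAP/osteocalcin, TRAP,
INTP/NTx, CTX-I/CTx) together with six bone phenotypes (femur and humerus
weight, length, diameter). `fetalbone` is a tested, reusable implementation of
the modelling procedure for such data: can a classifier tell low from high bone
measurements using the biomarkers, and which encoding of the experimental
conditions makes that possible?

## The method

Each bone output is robust-scaled within animal type, `(x − median)/IQR`, and
split at the median into binary classes. The key input encoding is the
*experiment-centered* (group-mean-centered) feature

```
MA_ij = mean_i(x_j) − x_ij
```

the mean of biomarker *j* over all records in condition group *i* minus the
record's own value, computed either within the joint animal×treat×period
grouping (`MAmix`, 6 features) or per single axis (`MAi`, 18 features). These
compete against the raw concentrations (`Metab`), one-hot condition indicators
(`OneHot`), and empirical condition probabilities (`ProbECs`, `ProbMix`).
Twelve block combinations × six outputs give 72 datasets, each evaluated with
seven pinned classifier families (KNN, linear-kernel SVM, RBF-kernel SVM,
logistic regression, decision tree, random forest, gradient-boosted trees)
under leave-one-out cross-validation — 504 models — inside a pipeline whose
robust scaler is fit on training rows only. Removal-based importance
(score-without-feature minus pool score) and single-feature models characterise
each best model, and a synthetic-data generator with planted
biomarker-to-bone links makes every stage verifiable without animal data.

## Worked example

```r
library(fetalbone)

rec <- generate_synthetic_study(synthetic_config(seed = 2024))

head(summarize_groups(rec, c("animal", "treat"), c("PTH", "TRAP")), 4)
#>   animal      treat variable      mean       sem  n
#> 1  fetus    control      PTH 809.63002 87.391593 14
#> 2  fetus    control     TRAP  51.49829  4.531153 14
#> 3  fetus restricted      PTH 799.07087 79.500624 14
#> 4  fetus restricted     TRAP  51.45318  3.941627 14

ds <- assemble_dataset(rec, list(id = "Hw:MAmix", output = "Hw", blocks = "MAmix"))
loocv_accuracy(ds, make_classifier("SVM linear"))
#> <eval Hw:MAmix | SVM linear | LOOCV: score 0.804 (56 records, 6 features)>

imp <- importance_by_removal(rec, list(id = "Hw:MAmix", output = "Hw",
                                       blocks = "MAmix"),
                             make_classifier("SVM linear"))
head(imp, 3)
#>   output          feature new_score       delta
#> 1     Hw  MA-TRAP-experim 0.5714286 -0.23214286
#> 2     Hw MA-CTX-I-experim 0.7857143 -0.01785714
#> 3     Hw   MA-PTH-experim 0.8035714  0.00000000
```

The generator planted a TRAP→Hw link (signal/noise 3) in this table, so the
linear SVM on the six centered biomarkers predicts low/high humerus weight at
LOOCV accuracy 0.804, and removing `MA-TRAP-experim` — and only it — collapses
the score (delta −0.232): the removal-importance analysis recovers the planted
driver. `run_all(rec, out_dir = "report")` runs the whole procedure (group
summaries, 504-model grid, best models, ablations, one-feature models, one-hot
versus centered comparison) and writes each table as CSV.

A thin command-line wrapper with subcommands (`integrate`, `encode`,
`list-datasets`, `grid`, `best`, `importance`, `onefeature`, `simulate`,
`report`) is installed at `inst/cli/fetalbone.R`.

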