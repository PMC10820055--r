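# scaffqsar

Scaffold-aware QSAR modelling of ion-channel modulator bioactivity in R.

Medicinal chemists screening modulators of a drug target — the motivating
case is the TRPV1 nociceptor channel, whose agonists and antagonists are
candidate non-opioid analgesics — need models that predict a compound's
potency (pK\_i, pIC\_50 or pEC\_50, the negative log10 of the molar
activity) from its structure alone, and that generalize to *new
chemotypes* rather than interpolating within a series. `scaffqsar`
implements that workflow end to end:

1. **Curation** — raw activity tables (SMILES, endpoint, value, unit) are
   screened, converted to molar and log-transformed, salt/metal ions are
   stripped to the largest organic fragment, and replicate measurements
   are merged when their p-activities span ≤ 1 log unit (discarded
   otherwise).
2. **Descriptors** — four families per compound: MACCS keys (166 bits),
   a path-based hashed fingerprint of 1–7-bond linear paths (2048 bits,
   the classic Daylight dialect), Morgan/ECFP4 circular fingerprints
   (radius 2, 1024 bits), and 110 electrotopological-state (E-state)
   descriptors. The ECFP4 and path fingerprints are computed in-package on
   an annotated molecular graph so every bit can be mapped back to the
   atoms that produced it.
3. **Carbon-scaffold splitting** — each molecule is reduced to its cyclic
   skeleton (Murcko framework, heteroatoms → C, all bonds single).
   Scaffolds with < 5 members send one random member to the training set
   and the rest to the test set; scaffolds with ≥ 5 members send 80% to
   training.
4. **Feature selection** — recursive feature elimination driven by
   random-forest impurity importance (RFE-RF), selecting the subset with
   the lowest cross-validated RMSE.
5. **Modelling** — SVR (RBF kernel; C ∈ {0.01…1000} × γ ∈ {1e-4, 1e-3,
   1e-2}), bagged regression trees, GBDT and XGBoost (100–1000 trees,
   step 50), tuned by grid search on CV RMSE.
6. **Validation** — five-fold cross-validation (Q², RMSE\_CV, MAE\_CV as
   mean ± sd over folds, with Q² = 1 − SS\_res/SS\_tot), external-test
   metrics (R², RMSE\_T, MAE\_T), and Y-randomization (refitting on
   permuted activities to rule out chance correlation).
7. **Interpretation** — normalized forest importances (summing to 1),
   mapping of top fingerprint bits to substructures, and activity-shift
   histograms comparing feature-bearing and feature-free compounds.

Because public bioactivity extracts are not redistributable, the package
ships a first-class **synthetic library generator**: scaffold templates ×
R-group decorations with *planted* substructure–activity effects plus
Gaussian noise, so every stage of the pipeline is testable against known
ground truth.

## Worked example

```r
library(scaffqsar)

cfg <- study_config(
  "Ki",
  families   = c("ECFP4", "ESTATE"),
  algorithms = c("svr_rbf", "xgb"),
  generator  = generator_config("Ki", n_compounds = 150, seed = 42),
  rfe_step = 64L, rfe_num_trees = 150L, rfe_min_features = 8L,
  grids = list(svr_rbf = expand.grid(C = c(1, 10), gamma = c(0.001, 0.01)),
               xgb     = data.frame(n_estimators = c(100, 200))),
  yrand_repetitions = 20L, seed = 7)

st <- run_endpoint_study(cfg)
st
#> <qsar_study> Ki: 4 model cells (121 train / 29 test)
#>   optimum: svr_rbf x ECFP4 (Q2 0.481, R2 0.605, 36 features)
```

The printed optimum says: of the 4 algorithm × descriptor cells, the
RBF-kernel SVR on the 36 RFE-selected ECFP4 bits cross-validated best
(mean fold Q² = 0.481 at this small n and reduced grid) and reached
R² = 0.605 on the scaffold-held-out test set — i.e. the model explains
~60% of the activity variance on chemotypes it never saw during
training. `tidy(st)` returns the
full per-cell metric grid, `st$yrand` the Y-randomization result,
`st$importance` the normalized importance ranking, and
`autoplot(st$yrand)` / `autoplot(st$shift)` the standard figures.

Individual stages compose with the pipe just as well:

```r
lib <- generate_library(generator_config("Ki", n_compounds = 400, seed = 1))
X   <- featurize(lib, "ECFP4", smiles_col = "smiles")
sel <- rfe_rf(unclass(X), lib$p_activity, step = 32, seed = 1)
autoplot(sel)   # RMSE_CV vs number of features, selected point marked
```

A thin CLI over the same functions lives at `inst/cli/scaffqsar`
(subcommands `simulate`, `curate`, `split`, `featurize`, `select`,
`train`, `validate`, `yrand`, `interpret`, `study`).

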