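---
title: "Methods: scaffold-aware QSAR regression in scaffqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaffold-aware QSAR regression in scaffqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the parameters that matter, what the synthetic
data generator does and does not emulate, the numerical choices made where
the design was genuinely open, and the known limitations.

## The problem and the model

A QSAR (quantitative structure–activity relationship) regression maps a
molecular structure, encoded as a fixed-length numeric descriptor vector,
to a bioactivity value. Activities here are potencies of ion-channel
modulators expressed on the p-scale: pK~i~, pIC~50~ or pEC~50~, the
negative base-10 logarithm of the molar measurement, so one unit is one
order of magnitude in potency. The pipeline makes the usual QSAR
assumptions: activities on the p-scale are comparable across sources once
units are normalized; structure determines activity up to measurement
noise; and additive fingerprint presence/absence carries enough signal
for tree ensembles and kernel machines to exploit.

### Curation

Four rules, applied in order: (1) records without a recognized endpoint,
a positive numeric value, or a unit convertible to molar (nM, µM, M) are
dropped and counted per reason; (2) values are converted to molar and
p-transformed; (3) salts and metal counter-ions are removed by keeping
the *largest organic fragment* — the fragment with the most heavy atoms
containing at least one carbon, ties broken toward the lexicographically
smallest canonical SMILES so the result is deterministic; (4) replicate
measurements of one `(canonical SMILES, endpoint)` are merged to their
arithmetic mean when their p-activity spread is ≤ 1 (inclusive), and the
compound is discarded otherwise. The de-duplication key is the canonical
SMILES *after* salt stripping: structure identity is the only defensible
merge key when no database accession is available. Merging happens after
unit conversion; because the rule operates on the p-scale, the order does
not change its outcome. Unconvertible units are dropped, never guessed.

### Descriptors

Four families with fixed lengths:

| family | length | values | computed by |
|---|---|---|---|
| MACCS keys | 166 | binary | OpenBabel backend |
| path-based ("Daylight" dialect) | 2048 | binary | in-package |
| ECFP4 (Morgan, radius 2) | 1024 | binary | in-package |
| E-state | 110 | real | in-package |

The path fingerprint enumerates all simple linear paths of 1–7 bonds
(the conventional default), labels each by its element/bond-order
sequence read in the canonical (lexicographically smaller) direction,
hashes, and folds to 2048 bits. ECFP4 is the Morgan algorithm: initial
atom invariants from (element, degree, implicit hydrogens, charge, ring
membership, bond-order sum), two update rounds, one feature per (atom,
radius) with duplicate atom environments removed, folded to 1024 bits.
Both are computed on the package's own molecular graph so a set bit can
be traced to a central atom plus radius-≤2 environment (ECFP4) or a
linear atom path (path fingerprint) — the basis of the interpretation
stage. Folding collisions are accepted as-is, matching standard
practice. Fingerprints are computed after canonicalization, which makes
them invariant to how the input SMILES was written; the graph is
kekulized, so "aromatic" environments are represented through alternating
bond orders rather than an aromatic flag.

E-state descriptors assign each atom an intrinsic state
$I = ((2/N)^2\,\delta_v + 1)/\delta$ ($N$ the principal quantum number,
$\delta_v$ valence electrons minus hydrogens, $\delta$ the heavy-atom
degree, with $\delta$ floored at 1 so lone heavy atoms stay finite),
perturbed by all other atoms via $\sum_j (I_i - I_j)/r_{ij}^2$ with
$r_{ij}$ = topological distance + 1. Atoms are binned into a fixed list
of 55 types keyed by element, hydrogen count and ring-annotated bond
pattern; the 110 features are the per-type sums of the E-state values
plus the per-type counts. No canonical 110-membership list is published
for the toolchain being emulated, so the package ships its own documented
default covering common drug-like chemistry; atoms outside the list
contribute to no feature, and the length is fixed by the list.

### Carbon scaffolds and the split

The carbon scaffold (cyclic skeleton) is computed by iteratively pruning
terminal side-chain atoms until only ring systems and their connecting
linkers remain, then replacing every heavy atom by carbon and every bond
by a single bond, and canonicalizing. Keeping the core *strictly* to
rings + linkers makes the operation idempotent —
`carbon_scaffold(carbon_scaffold(x)) == carbon_scaffold(x)` — which we
treat as a defining algebraic property; the alternative convention of
retaining exocyclic double-bonded atoms (carbonyl oxygens on linkers)
loses idempotence once bond orders collapse to single, so it was not
adopted. Acyclic molecules map to a sentinel pseudo-scaffold and are
subject to the same split rules as any other group.

The split: scaffolds with fewer than 5 members put exactly one random
member in training and the rest in test; scaffolds with ≥ 5 members put
`round(0.8 n)` members in training. Rounding is half-up (deterministic;
the convention is otherwise unstated). The rare-scaffold direction is
implemented literally — one molecule *to the training set* — even though
it inflates the test share of rare chemotypes; because the literal
reading is debatable, `rare_to_train = FALSE` switches to the reversed
reading (one to test, rest to train). Identical seeds give identical
splits, and per-scaffold train/test counts are seed-independent.

### Feature selection (RFE-RF)

From the full feature set, each iteration records the k-fold
cross-validated RMSE of a random-forest regressor on the current
features, ranks features by impurity importance (variance reduction for
regression; the field often calls this the "Gini index" by analogy with
classification forests), and removes the `step` least important. The
selected subset is the argmin of RMSE_CV along the trace, ties broken
toward fewer features. Design choices: the fold partition is *frozen*
across elimination steps, so the trace compares subsets rather than fold
draws (re-randomizing folds each step would add resampling noise to the
argmin); the selector forest defaults to 500 trees; `step = 1` is the
literal procedure and larger steps are a documented approximation for
2048-bit inputs; zero-variance columns are excluded up front (a forest
cannot split on them) and reported. Perfectly collinear duplicates of an
informative feature are genuinely interchangeable: the procedure
guarantees that at least one member of such a group survives, not all.

### Learners and tuning

Four regressors behind one adapter interface: RBF-kernel SVR (e1071),
bagged regression trees (in-package bootstrap aggregation of fully grown
rpart trees — the bootstrap op also exposes the ~36.8% out-of-bag
identity), classic gradient-boosted trees and regularized extreme
gradient boosting (both on the xgboost library: the GBDT configuration
uses learning rate 0.1, depth 3 and no regularization, the XGBoost
configuration the library's regularized defaults). Grid search scores
every point by k-fold CV RMSE with a frozen partition and refits the
winner on all training data; the default grids are C ∈ {0.01, 0.1, 1,
10, 100, 1000} × γ ∈ {1e-4, 1e-3, 1e-2} for SVR (18 points) and 100–1000
trees in steps of 50 for the tree methods (19 points). The grid-search
objective metric is CV RMSE, consistent with the selection stage.
Non-listed hyperparameters stay at library defaults. All stochastic
learners take explicit seeds; every stage derives its own seed stream
from the study master seed, recorded in the run manifest.

### Validation

Q² (CV) and R² (test) are both $1 - SS_{res}/SS_{tot}$ with the total
sum of squares around the observed mean; RMSE and MAE are standard.
Five-fold CV validates each sample exactly once and reports mean ± sd
across folds; the ± values in the study report are fold standard
deviations (fold-vs-repeat provenance is otherwise unstated, and fold sd
is the quantity the procedure actually produces). Per-fold Q² requires
at least two observations per fold, so leave-one-out-like settings are
rejected with a message.

Y-randomization permutes the response uniformly (preserving its
distribution exactly), refits the already-tuned learner on the already-
selected features, and records the CV Q² of each of the configured
repetitions (default 1000). Re-running selection per permutation is
available in principle but not the default: the reference procedure
re-models the disrupted data with the optimal algorithm and fingerprints,
and freezing them keeps the computation tractable. A "paired" t-test
against a single original value is not well-defined, so the package
reports a one-sample t-test of the randomized Q² sample against the
original Q² *and* the empirical percentile of the original within the
randomized sample.

### Interpretation

Importances come from a random forest refit on the final selected
features — not from the possibly non-tree optimal model (an RBF-SVR has
no native importances) — normalized to sum to exactly 1 and sorted. The
activity-shift analysis partitions compounds by presence of the listed
bits (`all` by default, matching "compounds containing the top k
features"; `any` available) and reports group sizes, means, the shift,
and histograms over shared edges with a 0.5 p-unit bin width (chosen to
resemble the customary presentation granularity). Degenerate partitions
(all or none bearing) are flagged rather than reported as a shift.

## The synthetic generator

`generate_library()` assembles compounds as scaffold template ×
R-group decorations and assigns
$p = \text{baseline} + \sum_k \beta_k\,\text{present}_k + \varepsilon$,
$\varepsilon \sim N(0, \sigma)$, clipped to the endpoint's activity
range. Defaults are fixed to the study conditions being emulated:
library sizes 661 (K~i~), 1894 (IC~50~), 367 (EC~50~); p-activity ranges
[5.76, 10.00], [4.04, 9.40], [3.95, 8.72]; noise σ = 0.3 p-units (a
realistic inter-assay reproducibility figure); two planted effects of
+1.0 (an aryl methylsulfonamide head, the size of shift reported for
top-feature-bearing compounds) and +0.3 (a trifluoroacetamide tail) with
sampling probabilities chosen so roughly half the library bears the
strong fragment. Common templates are sampled with Zipf-like weights
(exponent 1.2) and a reserved block of rare templates is spread at ≤ 4
members each, so the scaffold census mixes common (≥ 5) and rare (< 5)
groups like a real census. Structures are unique by construction
(collision-resampled), substructure flags are computed by SMARTS matching
on the emitted structures (so incidental occurrences count as present),
and everything is reproducible from the config seed.

What the generator does *not* emulate: realistic medicinal-chemistry
decoration statistics, activity cliffs, assay-specific censoring,
correlated noise between related analogs, or tautomer/stereochemistry
effects. Clipping to the activity range slightly biases effect sizes near
the boundaries (documented trade-off: it keeps effects interpretable
versus resampling). Passing tests on this generator therefore
demonstrates that the pipeline's machinery — curation algebra, split
contract, selection, validation, interpretation — behaves correctly on
data with known ground truth; it does not certify predictive performance
on any real chemotype distribution.

## Numerical choices and degenerate inputs

* Hashing for both fingerprints is a polynomial hash mod 2^31 computed in
  exact double arithmetic, platform-independent by construction.
* `r_squared` refuses constant observed vectors (zero denominator), CV
  refuses folds smaller than 2, RFE refuses constant responses, PCA
  refuses all-constant matrices, and `activity_shift` flags one-sided
  partitions instead of emitting NaN shifts.
* Metal-only inputs to salt stripping return `NA` (removed, counted);
  unparseable SMILES raise errors carrying the offending string.
* OpenBabel aborts a SMILES stream at the first bad record;
  canonicalization therefore runs in passes so one bad record cannot
  corrupt the mapping for the rest of a batch.
* Study optima are chosen by highest mean Q², ties broken by higher test
  R², then fewer selected features.

## Problem sizes used by the test and acceptance runs

The shipped tests and the acceptance script run the full pipeline at
desk scale as the package's own standard verification sizes: planted-
signal studies at n = 400 with RFE `step` 32 and 200-tree selector
forests, Y-randomization at 100 repetitions, determinism checks at
n = 120 with reduced grids, and the endpoint presets at their full sizes
(661/1894/367) for generation-level checks. The defaults of
`study_config()` remain the full protocol (4 × 4 model grid, full
hyperparameter grids, 1000 repetitions).

## Known limitations

* MACCS keys come from the OpenBabel pattern set, which differs in a few
  keys from other toolkits' MACCS implementations; bit *indices* are
  stable within the package but not comparable across toolkits. The same
  caveat applies to any hashed fingerprint: bit numbering is
  implementation-specific.
* The kekulized graph representation means aromatic systems contribute
  alternating single/double patterns to atom types and path labels;
  within-package comparisons are consistent, cross-toolkit bit-level
  comparisons are not meaningful.
* The E-state type list is a package default, not a published standard;
  exotic atom environments fall outside it and contribute no signal.
* Bagged trees and both boosting variants share the xgboost/rpart
  implementations' handling of ties and thresholds; exact numeric
  reproducibility is guaranteed under a fixed seed on a fixed platform,
  not across BLAS/compiler variations.
* The pipeline models a single endpoint at a time; no multi-task
  borrowing, no applicability-domain estimate, no conformal intervals.
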