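---
title: "Classification SAR modelling of estrogen receptor subtype selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification SAR modelling of estrogen receptor subtype selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erqsar)
library(dplyr)
```

## The modelling problem

The estrogen receptor exists as two subtypes, ERα and ERβ, with different
tissue distributions and partly opposing physiology; compounds that hit one
subtype selectively are of direct pharmacological interest. `erqsar`
implements a classification structure–activity relationship (CSAR) workflow
that learns, from curated IC50 data, to call a structure *active* or
*inactive* against each subtype and to combine the two calls into a
selectivity verdict (`alpha_selective`, `beta_selective`, `dual_active`,
`dual_inactive`).

The workflow is deliberately conventional, which is the point: every stage
is a documented, testable contract.

1. **Standardization** (`standardize_molecules()`): SMILES are validated by
   a lexical pre-check (so malformed input fails loudly, with a token
   position, instead of being silently "repaired"), salts are stripped to
   the largest organic fragment, and structures are normalized to Open
   Babel canonical SMILES. The rule set is recorded in every model artifact
   as `openbabel-canonical/1` so that prediction-time featurization is
   guaranteed to replay training-time featurization.
2. **Curation** (`curate_activity()`): IC50 values are converted to
   pIC50 = −log10(molar concentration). Compounds with IC50 < 1 µM
   (pIC50 > 6) are labelled active, IC50 > 10 µM (pIC50 < 5) inactive, and
   the window in between — including the boundary values exactly — is
   *intermediate* and excluded. Replicate measurements of the same
   canonical structure are aggregated by median pIC50; compounds whose
   replicates straddle both class regions are dropped outright, because any
   averaging rule would fabricate a label for a compound the assays
   disagree about.
3. **Fingerprints** (`compute_fingerprints()`): ordered dictionaries of
   substructure rules, in presence (0/1) or occurrence-count mode, with
   embedding counts deduplicated over automorphic matches.
4. **Filtering and splitting**: near-constant bits (sample SD < 0.1) are
   removed (`variance_filter()`); the Kennard–Stone maximin algorithm
   (`kennard_stone_split()`) places 80% of compounds in the internal
   (training) set and the remaining 20% in the external (test) set.
5. **Modelling** (`tune_and_train()`): a random forest tuned over a grid of
   `ntree` (100–1,000 by 100) and `mtry` (5–30 by 5) by mean five-fold
   cross-validated MCC, evaluated by accuracy, sensitivity, specificity and
   the Matthews correlation coefficient, and interpreted by mean decrease
   of the Gini index (`rank_features()`).
6. **Applicability domain** (`fit_domain()`, `in_domain()`): a PCA
   bounding box fitted on the internal set flags predictions that
   extrapolate outside the model's chemical space.

## Design decisions worth knowing about

**Salt stripping rule.** The retained fragment is the one with the most
heavy atoms, preferring carbon-containing fragments; ties break by
molecular weight, then lexicographic canonical SMILES. This makes
standardization a pure function of the input string.

**Tautomer canon.** Standardization relies on Open Babel's canonical
SMILES normalization and nothing more. Stronger tautomer canonicalization
schemes exist; whichever is in force is stamped into the model artifact,
and predictions always reuse the training-time scheme. Exact parity with
other toolkits' tautomer handling is not claimed.

**Strict thresholds.** pIC50 exactly 5 or 6 is intermediate. The cost is
dropping a handful of boundary compounds; the benefit is that "active" and
"inactive" always mean strictly-inside-the-class-region.

**Variance filter before splitting.** The SD filter is fitted on the full
curated set, before the train/test split. This mirrors the production
protocol this package reproduces, and is a (mild, documented) leakage
source: the filter sees the test compounds' bit variances, though never
their labels. The filter record flags this.

**Kennard–Stone determinism.** Distance is Euclidean on the filtered
fingerprint block (on binary bits this is the square root of the Hamming
distance). All ties break on the lowest row index, so the split is a pure
function of the ordered matrix — there is no random state anywhere in the
split. The internal-set size is `ceiling(fraction * n)`.

**Tuning objective.** The grid is scored by mean cross-validated MCC with
a fixed, seeded, stratified fold assignment shared by all grid points;
ties prefer the smaller `ntree`, then the smaller `mtry`. MCC is preferred
to accuracy because the curated classes are rarely balanced. Whether a
"training" metric means resubstitution or out-of-bag is ambiguous in much
of the QSAR literature, so both are emitted, labelled `training` and
`training_oob`.

**MCC convention.** When any factor of the MCC denominator is zero
(degenerate confusion matrices), MCC is defined as 0.

**Applicability domain.** Two mean-centred, unscaled principal components
by default (binary bits share a scale, so unit-variance scaling would
inflate rare bits). Membership is a closed-interval box test per
component, so every internal compound is in-domain by construction, and a
query exactly on the boundary is *inside*. Out-of-domain queries still
receive predictions, but flagged — the flag is a reliability statement,
not a refusal.

**Mann–Whitney comparisons.** The chemical-space analysis
(`class_comparison()`) compares Ro5 descriptor distributions between
classes with a Mann–Whitney U test: exact two-sided p by full enumeration
of rank splits (mid-rank ties) when the pooled sample is small
(`n ≤ 12`), normal approximation with tie and continuity correction
otherwise; the two-sided exact p is `2·min(tail, 1−tail)` capped at 1.
Box-plot dispersions are reported as the sample SD and labelled as such.
No multiple-testing correction is applied across the four descriptors.

## The fingerprint dictionaries

Dictionaries are ordered lists of bit rules in three kinds:
`smarts_presence`, `smarts_count_at_least`, and `feature_count_at_least`
(element counts, H counts, ring counts). Bit order is contractual: bit
*i* is always column *i+1* of a computed matrix, and model artifacts store
the full dictionary.

Four built-in families mirror the cardinalities and structural mix of the
classic interpretable fingerprint sets — 881 PubChem-style bits (count
rules plus SMARTS sections), 307 substructure bits (presence and count
usable), 166 MACCS-style bits, 4,860 Klekota–Roth-style bits. **Their
definitions are synthetic stand-ins**: generated deterministically from a
constrained SMARTS grammar plus a curated functional-group list, because
the original per-bit definition lists are not redistributed with this
package. The family names carry a `_synthetic` suffix to make this
impossible to miss. Bit-for-bit parity with other fingerprint toolkits is
therefore out of scope by construction (it was never achievable anyway
across aromaticity models); the cardinalities, the ordering contract, the
rule kinds, and the engine that evaluates them are the tested surface.
User-supplied dictionaries in the documented TSV format are first-class
citizens and go through the same validation (contiguous indices, compiling
patterns, thresholds ≥ 1).

A compact 24-bit `demo24` family covers the synthetic benchmark's grammar
and keeps examples and end-to-end tests fast.

## What the synthetic benchmark emulates — and what it does not

`generate_benchmark()` emits a ChEMBL-export-like activity table with a
planted, fully known signal. Active compounds are built on a
para-hydroxybenzyl scaffold so that a 4-methylphenol substructure
(SMARTS `[OX2H]c1ccc(C)cc1` — a free phenol para to a carbon substituent,
echoing a feature class repeatedly flagged as important in
estrogen-receptor SAR) embeds in every one of them; inactive compounds are
decorated aromatic scaffolds containing no free phenol (anisoles and
aliphatic alcohols are allowed, deliberately, so that generic
oxygen-containing bits do *not* separate the classes — only the
phenol-specific bits do). Class pIC50 values are drawn from N(7.0, 0.4)
and N(4.0, 0.4), resampled to stay strictly above 6 / below 5, so that at
zero label noise the thresholds are unambiguous. Values are back-converted
to IC50 in nM (every third row in µM) to exercise unit handling.
`label_noise` draws a compound's structure from the other class's grammar
while keeping its measured activity, degrading the structure–label
association in a controlled way. `inject_duplicates_and_salts()` adds
replicate rows in swapped units with counter-ions to exercise curation.

What passing tests on this benchmark demonstrate: the pipeline recovers a
planted substructure signal end-to-end (external-test MCC, top-5 Gini rank
of the planted bit), featurization identity between train and predict
time, and containment of the Kennard–Stone external set in the internal
set's PCA box. What they do **not** demonstrate: performance on real
estrogen-receptor data. The real SAR landscape has correlated,
many-to-many structure–activity relations, assay heterogeneity, and class
imbalance that this generator does not emulate; published headline numbers
on ChEMBL-derived ER sets are not reproducible without those sets and are
not claimed here.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script run the benchmark at
150 + 150 compounds per class over ten seeds, with a reduced tuning grid
(`ntree` ∈ {100, 200}, `mtry` ∈ {4, 8}) against the 24-bit demo family —
sizes chosen so the planted signal is comfortably learnable and the whole
suite stays desk-scale. The full default grid (60 pairs) is exercised for
its bookkeeping (candidate counting, skipping, tie-breaking) on small
matrices. Quartiles use the linear-interpolation convention
(`stats::quantile(type = 7)`), the common box-plot default. Fingerprint
computation memoizes per (dictionary, mode, canonical SMILES); fingerprints
are pure functions of the canonical structure, so memoization is
observationally transparent.

Degenerate inputs are rejected rather than patched: empty tables, single
class labels, all-identical feature rows, dictionaries with gaps or
duplicate indices, fractions outside (0, 1], non-positive IC50 values.

## A worked run

```{r workflow, eval = FALSE}
bm_alpha <- generate_benchmark(benchmark_spec(seed = 1))
bm_beta <- generate_benchmark(benchmark_spec(seed = 2))

pipeline <- train_pipeline(
  bm_alpha$activity, bm_beta$activity,
  dictionary = "demo24",
  config = model_config(ntree_grid = c(100, 200), mtry_grid = c(4, 8), seed = 1)
)
glance(pipeline)

predict_selectivity(pipeline, c("Oc1ccc(C)cc1", "CCc1ccc(CC)cc1"))

autoplot(pipeline$alpha$domain)
autoplot(pipeline$alpha$model, top_k = 10)
```

## Known limitations

- The built-in dictionaries are synthetic renditions of the classic
  families, suitable for method development, benchmarking and as format
  examples — not for comparing against published per-bit analyses.
- Open Babel's aromaticity perception governs all matching; patterns
  written for other toolkits' models may match differently.
- ALogP comes from Open Babel's atom-additive (Wildman–Crippen-type)
  scheme; other implementations differ in atom typing and will not agree
  to the second decimal.
- Only IC50 endpoints are supported; Ki/EC50/percent-inhibition curation
  is out of scope.
- The selectivity call is a pure function of the two binary labels; no
  probability-margin thresholding is applied, and the per-target
  probabilities are reported raw for users who want their own margins.
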