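---
title: "Automated QSRR model building for retention-time prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated QSRR model building for retention-time prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsrrflow)
```

## The problem

Identifying metabolites and lipids by mass spectrometry is ambiguous:
isomeric and isobaric compounds share an *m/z*, and MS/MS libraries do not
cover everything. Chromatographic retention time (RT) is the standard
orthogonal evidence, but RT depends on the column, eluents and gradient, so
a model trained in one lab rarely transfers to another. Quantitative
structure–retention relationship (QSRR) modelling solves this locally: run
50–200 standards on *your* method, describe each compound numerically from
its structure, and fit a regression from those molecular descriptors to RT.
The catch is that building such a model — descriptor hygiene, feature
selection, learner choice, hyperparameter tuning, honest validation — is a
bioinformatician's afternoon, per column, per method. `qsrrflow` automates
that afternoon.

## The pipeline

Given a CSV of `name, smiles, rt_minutes`:

1. **Descriptors.** 2-D descriptors are computed from SMILES via OpenBabel
   (ChemmineR/ChemmineOB): Wildman–Crippen SLogP, molar refractivity,
   molecular weight, TPSA, H-bond donor/acceptor counts, element counts,
   ring and aromatic-ring counts, functional-group counts, and a few
   derived constitutional quantities. Only 2-D descriptors are used — no
   conformer generation — because retention on both reverse-phase and HILIC
   columns is dominated by hydrophobicity and polarity, which these
   capture. Users can supply their own descriptor columns in the same CSV;
   they take precedence over computed columns of the same name. The set is
   deliberately compact compared to full descriptor suites (which produce
   on the order of a thousand); nothing downstream depends on the count.

2. **Filters.** Three hygiene filters, each with an inclusive threshold:
   drop a descriptor when ≥ 75% of compounds are missing it; when its modal
   value covers ≥ 90% of compounds (near-constant); and when its absolute
   Pearson correlation with an already-kept descriptor is ≥ 0.9. The
   correlation scan is greedy in input column order, keeping the earlier
   column of an offending pair, on pairwise-complete observations (at
   least 3 shared points). Missing and constant columns are removed first
   so the correlation pass sees the most informative columns. The stack is
   idempotent, row-order invariant, and residual missing cells are filled
   with training-column medians.

3. **Randomization, scaling.** The compound order is randomized with the
   run seed, and features are standardized (zero mean, unit variance);
   constant features in a training subset are dropped at scaling time so
   every scaled feature has positive variance.

4. **Feature selection.** Recursive feature elimination driven by
   random-forest impurity importance (500 trees): each round drops the
   least-important 10% of remaining features (single-feature steps are
   impractical at descriptor-matrix widths). The subset size is chosen by
   5-fold cross-validation minimizing held-out mean absolute error, with
   ties resolved toward the smaller subset. A forced feature count (e.g.,
   6, 9 or 12) replaces the size search with elimination to exactly that
   count.

5. **Model search.** Candidates: multiple linear regression, a 500-tree
   random forest, and RBF-kernel support vector regression over a 7 × 7
   log-spaced grid of C and γ spanning [0.001, 1000]. Every candidate is
   scored by 5-fold inner cross-validation; the winner maximizes mean
   held-out r², ties broken by lower mean absolute error, then by
   simplicity (linear < SVR < random forest). Inner-CV model scores use
   the coefficient of determination (1 − SS~res~/SS~tot~); the final
   evaluation statistics report squared Pearson correlation, the
   convention used for best-fit summaries.

6. **Outer validation and final fit.** A 5-fold outer cross-validation
   refits the *entire* pipeline (imputation, scaling, selection, search)
   inside each fold — no statistic is ever computed from held-out rows —
   and reports per-fold and aggregate r² and absolute error so users can
   judge whether the method suits their data before accepting a model. The
   final model is then refit on all rows and packaged with its complete
   preprocessing state, the training RT range, seed and configuration, so
   a saved bundle predicts standalone and bit-identically after reload.

## Prediction and evaluation

`predict()` replays impute → scale → restrict-to-selected-features →
learner, and flags predictions outside the training RT range: a statistical
model extrapolating beyond the retention times it saw is unreliable. When
*measured* values are available, `exclude_extrapolated()` applies the
observed-time rule instead (observed RT outside the training range is
discarded, boundary kept). `evaluate_predictions()` reports the least-squares
best-fit line of predicted (y) on measured (x) — the orientation under which
an ideal model gives y = x — squared-Pearson r², median signed error, median
signed percent error, and the fraction of predictions within 1 and 2 minutes.
`filter_relative_error()` implements the validity convention of dropping any
prediction whose relative error exceeds 35% of the observed RT (strictly
greater; denominators are observed times, which must be positive).

## The study protocol

`run_protocol()` reproduces the replicated-split experiment design: 5
independent randomized splits, 75% train / 25% test (or an absolute training
size: with 60 of 240 compounds training, the other 180 all become test
compounds), 3 models per split differing only in seed-derived randomness.
Descriptor filters are refit per training set. Feature usage is aggregated
across all 15 models: descriptors present in most or all models are the
chemically meaningful core (SLogP reliably among them), while descriptors
appearing once or twice are quirks of the random splits. Per-split and
per-replicate seeds derive deterministically from the base seed
(`base + 1000·split + replicate`), so the whole study is reproducible from
one integer.

## Synthetic benchmarks

Two seeded generators stand in for LC-MS data:

* `gen_matrix()` builds a compounds × descriptors matrix of i.i.d. standard
  normal noise with a planted informative subset (default 3 features,
  coefficients ±2, so the signal spans several minutes), optional affine
  duplicate blocks, near-constant columns (modal value covering 95% of
  rows) and high-missing columns (80% missing) that must cross the default
  filter thresholds. RT is linear in the informative features, or a smooth
  sinusoidal response for testing the nonlinear-learner path, plus Gaussian
  noise of 0.1 min — the middle of the replicate RT standard deviations
  (0.005–0.2 min) observed on real columns. The baseline RT is 16 min so
  simulated times stay positive and within realistic elution ranges.
* `gen_series()` builds real, parseable SMILES for homologous series
  (n-alkanols, n-fatty acids) with RT linear in chain length — the
  idealized reverse-phase behaviour of a lipid family sharing a backbone,
  where hydrophobicity is the monotone driver.

What these generators deliberately do **not** emulate: the heavy-tailed
descriptor distributions and block correlation structure of real descriptor
suites, HILIC's phosphate-compound RT spread (0.4–1 min replicate sd), and
chemical diversity outside a training family. Green tests therefore
demonstrate the machinery — recovery of planted signal, leak-free
validation, boundary conventions, reproducibility — not field accuracy on
any particular column.

## Numerical choices and edge cases

* Fold assignment is contiguous blocks over the randomized order; ties in
  the learner ranking are resolved deterministically (simplicity order), so
  (data, config, seed) fully determines every result. All random-forest
  fits run single-threaded with a fixed seed.
* Degenerate inputs fail loudly with classed errors: constant RT targets,
  fewer than 10 training rows, zero surviving descriptors, imputer columns
  never seen at fit time, bundles with a newer format version.
* Training sizes in the test-suite and acceptance benchmarks (e.g., 200
  rows × ~53 descriptors for recovery runs, 240 × 23 for the protocol
  series, 40-compound series end-to-end) were chosen as the smallest sizes
  at which the statistical structure of interest — recovery of planted
  features, the training-set-size effect, sub-0.3-min series MAE — is
  stably expressed.

## Known limitations

Descriptor coverage is narrower than a full Mordred-style suite, which
matters most for chemistries whose retention is driven by descriptors we do
not compute (e.g., detailed electronic-state descriptors). Extrapolation
flagging is a range check on RT, not a domain-of-applicability analysis in
descriptor space. The grid for C and γ is discrete (7 points per axis);
retention differences below the grid's resolution of roughly a factor of 10
in hyperparameter space are absorbed by the inner CV's tolerance.
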