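---
title: "Modeling post-resuscitation decisions and neurologic outcomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling post-resuscitation decisions and neurologic outcomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modeling problem

After an out-of-hospital cardiac arrest (OHCA), patients who regain
spontaneous circulation (ROSC) and survive to hospital admission face a
sequence of hospital decisions. One of the most consequential is whether
to perform coronary angiography (CA). `postrosc` models two linked
binary classification tasks on registry data whose inputs are
*exclusively categorical*:

1. **Decision task** — will this hospital perform CA on this patient?
   (23 categorical inputs: demographics, arrest circumstances,
   prehospital care.)
2. **Survival task** — will the patient leave with a functional
   neurologic outcome? The Cerebral Performance Category (CPC) score is
   binarized: Class 0 = CPC 1/2 (functional), Class 1 = CPC 3/4/5. The
   survival model sees the same 23 inputs *plus the CA decision* — the
   only new information between the two stages.

Because hospitals differ both in how often they provide CA and in their
outcome quality, the package's headline analysis stratifies hospitals
into outcome tertiles, adapts the models to the best tertile, and
counterfactually audits the other tertiles: which of their no-CA
patients would the best tertile's decision policy have flipped to CA,
and what does the survival model predict would have happened to them?

Registries of real post-arrest care are access-restricted, so the
package ships a synthetic registry generator that reproduces the
statistical structure the analysis needs. Everything downstream —
encodings, networks, leaderboard, cohort audit — is tested against that
generator and its known ground truth.

## The embedded fully convolutional network (EFCN)

A patient record is treated as a sequence of length $F$ (one position
per categorical feature). The network is:

* **Embedding layer.** Each feature $f$ with $L_f$ levels owns an
  $L_f \times d_f$ embedding table with
  $d_f = \min(16, \lceil (L_f + 1)/2 \rceil)$ — small vocabularies get
  small embeddings. Tables are initialized $N(0, 0.05)$. Features whose
  $d_f$ is below the widest embedding are zero-padded in the channel
  dimension so positions align.
* **Convolution stack.** Three same-padded 1-D convolution blocks with
  32, 64 and 32 filters and kernel widths 8, 5 and 3, each followed by
  batch normalization ($\epsilon = 10^{-5}$, running-statistic momentum
  0.9) and a rectifier. Weights use He-scaled normal initialization.
  The canonical fully-convolutional classifier this family descends
  from uses 128/256/128 filters; at registry scale (a few thousand
  rows, ~24 positions) that width is heavily over-parameterised and
  slow on a single CPU, so the default here is the same shape at a
  quarter width. Filter counts, kernels, and the embedding rule are all
  arguments of `efcn_architecture()`.
* **Head.** Global average pooling over the $F$ positions, optional
  inverted dropout (default 0), and a single logistic output.

Training (`train_efcn()`) minimizes mean binary cross-entropy with
mini-batch Adam (learning rate $10^{-3}$, batch 64, $\beta = (0.9,
0.999)$), scoring the validation set after every epoch and returning
the weights of the best validation-AUROC epoch (patience 20, maximum
200 epochs by default). Predicted probabilities are clamped to
$[10^{-12}, 1 - 10^{-12}]$ inside the loss. All randomness (weight
initialization, batch shuffling) flows through seeded R RNG, so runs
are bit-reproducible under single-threaded execution.

The implementation is plain R: convolution is materialized by an
im2col expansion over contiguous row blocks and executed as one
BLAS-level matrix product per layer, with analytically derived
backpropagation (verified against numerical gradients in the test
suite).

### Sequential training and embedding transfer

The decision network is trained first. `transfer_embeddings()` then
builds the survival network and copies every shared feature's embedding
table verbatim; the CA embedding — the one input the survival task adds
— and the convolution stack are freshly initialized. A transfer
manifest records the provenance of every table.

A fully literal reading of the protocol this mirrors ("the only
randomly initialized weights ... is the embedding vector for the CA
input") would imply the convolution weights were transferred as well.
The package defaults to embeddings-only transfer, which is the part the
architecture diagrams highlight, and exposes `transfer_all = TRUE` for
the literal reading. Training the survival model never mutates the
stored decision model (value semantics, asserted in tests).

## The synthetic registry generator

`default_config()` builds a calibrated generator emulating the study
conditions of a large urban EMS system:

* **Size and structure.** 2,398 admitted patients by default; 33
  receiving hospitals with fixed volume weights under which roughly 15
  hospitals exceed 75 expected patients — the eligibility threshold the
  cohort analysis uses.
* **Covariates.** The 23 decision inputs are sampled independently from
  per-feature marginals drawn once from the configuration seed.
  Independence is a deliberate simplification: it keeps the
  Bayes-optimal AUROC computable in closed form from the sidecar and
  the generator auditable. A `covariate_sampler` hook accepts a joint
  sampler when dependence matters.
* **Decision model.** CA $\sim$ Bernoulli(logistic(intercept + feature
  effects + hospital policy offset)). Feature level effects are drawn
  $N(0, 0.45)$ and centered; hospital policy offsets are
  anti-correlated with quality offsets (better hospitals provide more
  CA), which is what makes a cross-tertile decision audit informative
  rather than vacuous.
* **Outcome model.** Class 1 (non-functional) $\sim$
  Bernoulli(logistic(intercept + feature effects + $\beta_{CA}
  \cdot$ CA + hospital quality offset)) with $\beta_{CA} = -0.8$ by
  default: CA improves outcomes, consistent with the clinical
  literature motivating the decision model. Hospital quality offsets
  are $N(0, 0.6)$, centered.
* **Calibration.** `calibrate_intercepts()` root-finds both intercepts
  against Monte-Carlo marginal estimates (100,000 profiles) so the
  simulated CA rate is 21.5% and the functional-outcome rate 20.8% —
  the study's reported marginals. The coefficient scale 0.45 was chosen
  so the latent signal yields a Bayes AUROC ceiling near 0.85–0.87,
  the regime the published models operate in.
* **Sidecar.** `generate_registry()` retains, per patient, the exact CA
  propensity and the Class-1 probability under both CA = 0 and CA = 1.
  `bayes_auroc()` scores these true probabilities against the realized
  labels: the ceiling no model can beat in expectation, used as the
  reference for recovery tests.

What the generator does **not** emulate: covariate dependence, temporal
drift, missing data, and the real registry's demographic composition
(not public). Passing recovery tests therefore demonstrates that the
pipeline's machinery is correct and well-calibrated on data with the
assumed structure — not that the models would attain the published
real-data AUROCs.

## Splits

`split_data()` assigns records to train / validation / test /
cohort-analysis subsets (40/10/25/25 by default) by simple random
assignment — no stratification by outcome or hospital, matching the
source protocol's plain random split; stratification would change the
cohort-analysis counts. Subset sizes use largest-remainder rounding:
for 2,398 records this gives 959/240/600/599, whereas the published
study reports 957/241/600/600 — a discrepancy that exact 40/10/25/25
arithmetic cannot produce, so the package documents it rather than
hard-coding the published sizes.

## Classical comparison harness

All classical families consume full one-hot encodings (no reference
level dropped — collinearity is irrelevant for these model families and
full blocks keep the encoding symmetric with the worked three-level
example `[0,1,0]`). Level order is schema order, never frequency order,
so encodings are stable across datasets — a precondition for embedding
transfer to be meaningful.

`grid_search()` is exhaustive over modest default grids, selects by
validation AUROC with first-in-grid tie-breaking, and
`run_leaderboard()` assembles 8 classical families plus the EFCN on
identical splits for both tasks. R has no lightgbm, so both boosting
rows are backed by xgboost under two documented regimes (deeper trees
vs. shallow-shrinkage). The published grid table is not public; the
defaults here are declared stand-ins and user grids are accepted.

## Metrics

* **AUROC** is the exact Mann–Whitney rank statistic (ties counted
  one-half); the test suite checks it against a brute-force all-pairs
  oracle to $10^{-12}$.
* **AUPRC** uses the step-wise precision envelope over distinct-score
  thresholds, starting from the first threshold's precision at its
  recall (no extrapolated recall-0 point).
* Thresholded metrics (accuracy, F1, MCC, confusion) use threshold 0.5
  with scores *at* the threshold classified positive; both choices are
  configurable and documented because the source protocol states
  neither. MCC is defined 0 when any confusion marginal is empty.
* **Brier score** is the mean squared probability error; a propriety
  test checks the generator's true probabilities beat distorted copies.
* **Attributions** are permutation-sampling Shapley values at
  whole-feature granularity (a categorical feature toggles as one
  unit). Each sampled permutation telescopes exactly, so local accuracy
  (base value + contributions = score) holds by construction; the
  estimator is checked against exact coalition enumeration on small
  models. Means are reported per predicted class.

## Cohort analysis and the counterfactual audit

Hospitals qualify with at least 75 study-period records (eligibility is
judged on the full registry; pass `volume_records` explicitly when
calling `assign_cohorts()` on a subset). Qualifying hospitals are
ranked by their CPC 1/2 rate computed on train + validation rows only,
ties broken by larger volume then lexical id, and grouped 5-5-5 into
tertiles.

`retrain_on_cohort()` warm-starts both networks from the full-data
weights and fine-tunes on the best cohort's train/validation rows; zero
epochs is the identity, and the source bundle is never modified.

`counterfactual_audit()` then applies the best cohort's decision model
to a target cohort's *held-out cohort-analysis rows*: patients without
an initial CA whose decision score reaches 0.5 are flipped; flipped
patients are scored by the survival model under CA = 0 and CA = 1 and
classified at the same threshold (1 → 0 is a positive change). Three
design decisions are deliberate and logged:

* the *fine-tuned* survival model does the re-scoring (the full-data
  model is available behind a flag);
* the audit is one-directional — patients who received CA are never
  counterfactually denied it;
* rendered percentages use half-up rounding (R's `round()` is
  half-even, which would change printed values like 18.85 vs 18.86 at
  the second decimal).

Uncertainty uses the percentile bootstrap with patient-level resampling
(1,000 replicates by default) — the interval method behind the original
abstract's confidence bounds is unstated, so this one is declared
rather than claimed identical. Degenerate resamples (no CA = 0
patients) are skipped and counted.

## Problem sizes used by the automated checks

Chosen as the package's own test conditions: generator calibration at
n = 50,000 (±1 percentage point); model-recovery against the Bayes
ceiling at 20,000 fitting / 5,000 held-out rows (within 0.05 AUROC,
plus a permutation-null band of [0.4, 0.6] at n = 2,000); hospital
quality-ranking recovery with 15 hospitals × 600 patients whose quality
offsets are evenly spaced on $[-1.5, 1.5]$ — spacing chosen so adjacent
hospitals differ by at least one standard error of an empirical rate at
that volume; bootstrap coverage for a proportion at n = 300 over 500
simulations of 400 replicates; and bitwise pipeline reproducibility at
n = 900. The study-scale acceptance run uses the full n = 2,398 with
60-epoch training budgets.

## Known limitations

* The audit is predictive re-scoring, not causal inference: no
  propensity adjustment or instrumental analysis is attempted, and a
  "positive change" is a model prediction, not an estimated treatment
  effect.
* The generator's independence and additive-logistic assumptions make
  the Bayes ceiling attainable by boosted trees; interaction-heavy real
  data would separate the model families more than the synthetic
  leaderboard does.
* The EFCN determinism contract assumes single-threaded BLAS; thread
  count does not change correctness, only bitwise reproducibility.
* CPC is binarized; no multi-class CPC modeling is offered.
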