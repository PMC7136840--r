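---
title: "Modelling mortality from longitudinal EHR encounters: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mortality from longitudinal EHR encounters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clout)
```

## The prediction problem

Hospitalised and critically ill patients accumulate longitudinal electronic
health records: a sequence of encounters, each documenting a set of diagnosis
(ICD) codes, medications, and laboratory components with normal/abnormal
flags. The task is to predict a binary outcome — here, patient mortality —
from the encounter sequence, and to do so in a way whose *risk factors* can
be inspected and judged by clinicians.

The modelling premise of this package is that the three clinical feature
families ("views") of an encounter are not independent: diagnoses drive
prescriptions, both drive and reflect laboratory abnormalities. A
representation that captures this shared structure should carry more signal
per dimension than the raw indicators.

## From events to model inputs

Cohort construction applies three rules:

1. **Two or more encounters per patient.** The final encounter is removed
   before prediction (its contents would not be available when the prediction
   is needed), so at least one informative encounter must remain.
2. **Abnormal labs only** (default). Lab components enter the feature space
   only when flagged abnormal; a binary normal/abnormal coding outperforms
   using all lab components, so the all-labs mode is kept behind
   `build_cohort(abnormal_only = FALSE)` purely for comparison.
3. **Chronological ordering** with ties on identical timestamps broken by
   encounter id, so cohorts are reproducible regardless of file row order.

Each encounter becomes three multi-hot indicator vectors $v_d, v_m, v_l$ over
per-view vocabularies built from the **training split only**; codes first
seen at validation/test time are skipped and counted (out-of-vocabulary),
never errors. Vocabulary indices are assigned lexicographically (1-based, the
R convention).

Splitting uses floor(0.7 N) / floor(0.1 N) / remainder — the only integer
convention that partitions 7537 patients into (5275, 753, 1509). Nothing in
the split is outcome-stratified. After hyperparameter selection on the
validation split, the final model can be retrained on the merged
train+validation set (`clout_config(retrain_on_merged = TRUE)`).

## The shared latent space

The correlational network (`train_corrnet`) is a three-view autoencoder with
sigmoid encoders into a shared latent space and linear decoders:

$$ l = \sigma\!\left(\textstyle\sum_{v \in \text{active}} W_v^\top x_v + b\right). $$

Its objective sums twelve mean-squared reconstruction terms — the all-views
encoding decoded to each view, plus each single-view encoding decoded to all
three views — minus $\lambda$ times the sum over the three view pairs of the
mean per-latent-dimension Pearson correlation between single-view encodings.
Minimising it therefore both reconstructs each view and *aligns* what each
view alone says about the encounter; at $\lambda = 0$ it is exactly a
multi-view autoencoder, which the tests assert. Reconstruction is
mean-squared error by default (the inputs are 0/1 indicators); a logistic
cross-entropy decoder sits behind `corrnet_config(decoder = "logistic")`.

Design choices worth stating:

* correlations are computed per minibatch with a variance floor of $10^{-8}$;
  a latent dimension that is constant within a batch contributes correlation
  0 (and zero gradient) rather than NaN;
* the network is trained unsupervised on training-split encounters and then
  **frozen**; the classifier only projects through it. End-to-end fine-tuning
  is deliberately out of scope;
* at prediction time the projection uses all three views jointly
  (`active = all`), not a sum of single-view encodings;
* defaults: latent dimension 64, $\lambda = 1$, Adam at $10^{-3}$, 50 epochs,
  batch 128. The comparison plain autoencoder (`train_autoencoder`) uses one
  sigmoid hidden layer $f$ and one linear output layer $g$ with a hidden
  dimension strictly smaller than the input (compression), 64 by default.

## Encounter vectors and the classifier

The simple-concatenation vector is
$e_c = \mathrm{relu}(\,[E_d^\top v_d + b_d;\; E_m^\top v_m + b_m;\;
E_l^\top v_l + b_l]\,)$ with per-view linear embeddings of default dimensions
(64, 64, 32). Five variants of the final encounter vector are available,
mirroring an ablation ladder over representations:

| variant | encounter vector $e$ |
|---|---|
| `simple_concat` | $e_c$ |
| `ae_only` | autoencoder hidden vector $f$ |
| `latent_only` | latent projection $l$ |
| `ae_concat` | $[f; e_c]$ |
| `latent_concat` | $[l; e_c]$ (the best-performing fusion) |

An optional elapsed-time feature (days since first or previous encounter,
divided by 365) is appended as one scalar; unscaled day counts would dwarf
the other activations. The autoencoder and latent components are frozen;
embeddings train jointly with the classifier.

The classifier is a single-layer unidirectional LSTM (hidden size 128) over
$e_1 \dots e_n$, pooled by additive attention,

$$ s_i = u^\top \tanh(W h_i + b), \qquad a = \mathrm{softmax}(s), \qquad
   H = \textstyle\sum_i a_i h_i, $$

with padding positions masked out of the softmax, followed by a linear layer
and sigmoid giving the death probability. Training minimises mean
(unweighted) binary cross-entropy with Adam — at ~38% prevalence class
weighting is unnecessary — with early stopping on validation AUROC
(patience 5, max 100 epochs). All forward/backward passes are hand-derived
matrix algebra; the test suite checks every gradient against central finite
differences and the full forward pass against an independent scalar-loop
oracle.

The logistic baseline cannot use temporal structure, so each patient is
collapsed to the elementwise OR of their encounters' indicators and fitted
with ridge-penalised logistic regression (glmnet).

## Risk factors by zero-out ablation

The attribution weight of a feature for a patient is
$p(\text{original}) - p(\text{feature zeroed in every encounter})$; a feature
the patient never documents has weight exactly 0 without recomputation, and
weights may be negative (protective features). Ablation is across all
encounters by default because a feature's "contribution" is a property of the
patient record; per-encounter ablation is available via the `encounters`
argument.

Population-level weights average patient weights over the patients who
document the feature (the `support`). The mean-over-support normalisation
keeps rare and common features comparable; since support is reported,
alternative aggregations can be recomputed from the output. Attribution runs
over the test split by default — it interprets the deployed model.
Restricting attribution to correctly predicted patients is possible upstream
by filtering the cohort, and was deliberately not made the default.

For expert review, features are drawn by stratified sampling from rank bins
1–20 / 21–50 / 51+ (rank 20 belongs to the first bin): 4 per bin from one
patient's ranking (12 features), then 2 per bin from each per-view population
ranking (18 features), excluding features already drawn so the review set is
maximised, and finally shuffled under the same seed for blind presentation.
The provenance (scope, bin, rank) travels in a sidecar, never in the blinded
list.

Agreement between raters and models uses pairwise Pearson correlations over
the feature scores, per-entity mean (SD) against the human raters, a gold
standard defined as the per-feature arithmetic mean of rater scores, and a
Welch two-sided t test for comparing collections of correlations (raw $r$
values, matching the arithmetic used in this literature; a Fisher-z analysis
can be applied externally to the returned matrix). Leave-one-rater-out
re-analysis is built in.

## The synthetic cohort generator

Real credentialed ICU data cannot ship with a package, so `generate_cohort`
produces cohorts with the statistical structure the method assumes, plus a
known ground truth for recovery tests:

* each patient carries a latent health state $z_t \in \mathbb{R}^k$
  following a stationary AR(1) process $z_t = \rho z_{t-1} + \varepsilon_t$,
  $\varepsilon_t \sim N(0, (1-\rho^2) I)$, $z_1 \sim N(0, I)$ — the simplest
  process with within-patient temporal dependence, kept at unit marginal
  variance so effect sizes are interpretable;
* every code's documentation probability is
  $\sigma(w_c^\top z_t + \beta_{0,c} + \delta_c y)$: the shared $z_t$ induces
  the cross-view correlation the latent space is meant to exploit, per-code
  baselines $\beta_{0,c}$ are jittered around rates giving roughly 8
  diagnoses, 10 medications and 8 abnormal labs per encounter, and
  $\delta_c$ is `marker_effect` (default 2) for the planted marker codes
  and 0 otherwise;
* mortality is $\mathrm{Bernoulli}(\sigma(\beta^\top z_n + \gamma))$ drawn
  *before* the codes, so the marker shift conditions on the eventual label
  and the attribution ground truth is unambiguous;
* $\gamma$ is calibrated by bisection to a target prevalence of 0.38 at a
  Monte-Carlo size of 20&nbsp;000 (`prevalence_calibrate`);
* lab codes are additionally "measured normal" at rate 0.1 independent of
  the latent state, exercising the abnormal-only filter;
* defaults: 2000 patients, 2–8 encounters, vocabularies (200, 150, 100),
  latent dimension 8, $\rho = 0.7$, $\beta = (0.3, \dots)$, 40 markers per
  view. Forty markers per view (27% of all codes) reflects that in ICU
  populations a sizeable minority of documented codes genuinely associate
  with mortality, and leaves the rank-correlation recovery statistic enough
  ceiling to be informative.

What the generator does **not** emulate: realistic ICD frequency or
comorbidity structure, demographics, coding noise and missingness, informative
encounter timing, or vital signs. Passing recovery tests therefore show the
pipeline recovers the kind of structure it assumes, at desk scale — not
clinical-grade performance on real records. The planted signal is strong
enough that held-out discrimination approaches 1.0, far above what real EHR
data yields; the recovery tests are about correctness of the machinery, not
about reproducing any particular real-data operating point.

## Numerical and reproducibility choices

* All randomness flows from per-stage seeds derived from one master seed by
  hashing the stage name (`derive_seed`); identical seeds give byte-identical
  cohorts, traces and parameters.
* LSTM forget-gate bias initialised at 1 (standard remedy for early gradient
  vanishing); other weights are scaled Gaussian $N(0, 1/\sqrt{\text{fan-in}})$.
* Attention and loss computations clamp probabilities at $10^{-12}$ inside
  logs; the softmax subtracts the row maximum.
* Ranking ties are broken by (view, code) lexicographic order; metric
  zero-denominators (e.g. precision with no positive predictions) are defined
  as 0 with a warning; AUROC ties count 1/2 (Mann–Whitney convention).
* Macro (unweighted) averaging is the default for the per-class
  precision/recall/F1 table; micro-averaging is a switch.
* The test suite runs its heavier checks at the generator defaults
  (2000 patients) once per seed and shares the fitted artifacts across
  checks; unit tests use cohorts of 40–300 patients with vocabularies of
  10–30 codes per view, which keeps the full suite in the single-digit
  minutes on one CPU.

## Known limitations

* Ablation attribution inherits confounding: a medication prescribed in
  palliative care will carry a large weight because of the care context, not
  a causal effect. No causal adjustment is attempted.
* The correlational objective is optimised per minibatch; very small batches
  make the correlation estimate noisy (batches of fewer than 2 encounters are
  rejected outright).
* Gradient-based attributions (saliency, integrated gradients) and deeper /
  bidirectional recurrent stacks are out of scope.
* The logistic baseline's ridge penalty is fixed per run, not tuned; it is a
  reference point, not a tuned competitor.
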