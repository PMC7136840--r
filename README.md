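# clout

Mortality prediction from longitudinal EHR encounter sequences, with
interpretable risk-factor attribution.

Each hospital encounter documents three correlated families of discrete
clinical features ("views"): diagnosis (ICD) codes, medications, and abnormal
laboratory components. `clout` implements a family of sequence classifiers
built on the idea that a *shared latent representation* of the three views
carries more signal than their raw indicators:

1. **Multi-hot encoding.** Encounter *t* becomes indicator vectors
   *v_d, v_m, v_l* over per-view vocabularies built from the training split.
2. **Shared latent space.** A three-view correlational network — a multi-view
   autoencoder whose objective adds a reward for Pearson correlation between
   the latent encodings computed from each single view — is trained
   unsupervised and frozen; it projects each encounter to
   *l = σ(Σ_v W_vᵀ v_v + b)*.
3. **Encounter vector.** Five variants: embedded-views concatenation
   *e_c = relu([E_dᵀv_d; E_mᵀv_m; E_lᵀv_l])*, a plain autoencoder hidden
   vector *f*, the latent projection *l* alone, or the fusions *[f; e_c]* and
   *[l; e_c]* (the best performer). An optional elapsed-time scalar
   (days/365) can be appended.
4. **Attention-pooled LSTM.** Hidden states *h_1 … h_n* are pooled by
   additive attention, *H = Σ a_i h_i* with *a = softmax(uᵀ tanh(W h_i + b))*,
   then a linear layer and sigmoid give the death probability. A
   ridge-penalised logistic regression on OR-aggregated patient vectors is
   the non-temporal baseline.
5. **Ablation attribution.** A feature's risk weight for a patient is the
   drop in predicted probability when its indicator is zeroed in every
   encounter; population weights average over the patients documenting the
   feature. Rankings feed a stratified, seeded, blinded review sample
   (bins 1–20 / 21–50 / 51+), and rater agreement is analysed with pairwise
   Pearson correlations against an averaged gold standard.

Cohort rules follow the standard protocol for this task: patients need two or
more encounters because the final encounter is removed before prediction;
abnormal-only lab coding is the default; splits are 70/10/20 by
floor/floor/remainder (7537 patients → 5275/753/1509, merged train+validation
6028) with a recorded seed.

All networks (correlational autoencoder, embeddings, LSTM, attention) are
implemented in base R matrix algebra with hand-derived analytic gradients and
Adam; the test suite verifies every gradient against finite differences and
the forward passes against independent scalar-loop oracles.

## Worked example

Because the method is developed against credentialed ICU data that cannot be
redistributed, the package ships a synthetic-cohort generator with the same
statistical skeleton: a latent AR(1) patient state drives three correlated
views and mortality, and known "marker" codes get a planted logit shift in
patients who die — an unambiguous attribution ground truth.

```r
library(clout)

sim <- generate_cohort(generator_config(n_patients = 600, seed = 42))
sim$cohort
#> <ehr_cohort> 600 patients, 2984 encounters, mortality 37.3%, 0 excluded (<2 encounters)

splits <- split_cohort(names(sim$cohort), ratios = c(0.7, 0.1, 0.2), seed = 42)

prepared <- lapply(sim$cohort, prepare_model_input)   # drop last encounters
train_cohort <- structure(prepared[splits$train], class = "ehr_cohort")
vocabs <- build_vocabularies(train_cohort)

cn  <- train_corrnet(train_cohort, vocabs, corrnet_config(epochs = 30, seed = 42))
fit <- train_clout(sim$cohort, splits, encoder_config("latent_concat"),
                   clout_config(seed = 42), corrnet = cn, vocabs = vocabs)

test_tl <- prepared[splits$test]
p <- predict_cohort(fit$model, test_tl)
y <- vapply(test_tl, `[[`, integer(1), "mortality")
auroc(p, y)
#> 0.999
```

The planted signal makes the synthetic task almost perfectly separable by
rank; note that early stopping selects on AUROC, so the 0.5 probability
threshold is not calibrated and threshold-based metrics lag the ranking
metric. Risk factors, per patient and across the population:

```r
head(patient_risk_factors(fit$model, test_tl[[1]]), 3)
#>         view  code      weight rank
#> 1 medication M0006 0.009996891    1
#> 2 medication M0128 0.005029446    2
#> 3 medication M0117 0.004795152    3

pop <- population_risk_factors(fit$model, test_tl)
head(pop$pooled, 3)
#>         view  code      weight support rank
#> 1 medication M0128 0.004758518      56    1
#> 2 medication M0131 0.004514282      76    2
#> 3 medication M0073 0.004348012      60    3

eff <- ground_truth_effects(sim$truth)
m <- merge(pop$pooled, eff, by = c("view", "code"))
cor(m$weight, m$effect, method = "spearman")
#> 0.55
```

The positive rank correlation says the ablation ranking recovers the planted
mortality markers. `stratified_sample_features()` then draws the blinded
review set, and `agreement_analysis()` scores rater/model agreement.

An end-to-end experiment (simulate → split → pretrain → train variants →
evaluate → attribute → sample for review) runs from one YAML config through
`run_experiment()` or the thin CLI:

```sh
exec/clout all --config run.yaml --out runs/demo
```

## Scope

The package deliberately excludes raw EHR table extraction, ICD code
grooming, vital signs, gradient-based attribution, and causal adjustment of
risk factors (ablation weights inherit confounding — a palliative-care
medication will score high because of its context). See the methods vignette
(`vignettes/clout-methods.Rmd`) for the full design rationale and
limitations.
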