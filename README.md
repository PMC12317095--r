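# duetmil

Dual-modality multiple-instance learning for whole-slide biomarker
prediction, with screening trade-off analysis, attention explainability and
claims-derived survival stratification.

## What this package is for

Predictive immunotherapy biomarkers — microsatellite instability (MSI) /
mismatch-repair deficiency in colorectal cancer, PD-L1 combined positive
score (CPS) in breast cancer — are normally called from sequencing or from
pathologist-scored immunohistochemistry (IHC). `duetmil` implements a
weakly supervised alternative: a transformer aggregator over bags of tile
embeddings that predicts a binary biomarker status from the H&E and IHC
whole-slide images of a case, *together or alone*. It is aimed at
computational-pathology researchers who want a desk-scale, fully
reproducible implementation of the dual-modality approach: every stage —
synthetic cohort generation, tissue segmentation and tessellation, tile
encoding, cross-validated training, evaluation, heatmaps, and survival
analysis — runs on a laptop with no downloads.

## The model

A slide is a bag of 224 x 224-pixel tiles at x10 magnification, each tile
encoded to a 768-dimensional embedding. One *parameter-shared* transformer
trunk (linear projection, learned class token, two pre-norm multi-head
self-attention blocks, no positional encodings) maps each modality's bag to
its final class-token state `h_HE, h_IHC ∈ R^m`. The head scores the pair

    logit = MLP([h_HE ; h_IHC]),    P(positive) = sigmoid(logit),

and during training one branch is dropped with probability 0.3 per step
(its block zero-filled), so the head tolerates a missing stain and the same
trained weights serve `DUET`, `HE_ONLY` and `IHC_ONLY` inference. Training
is batch-size-one AdamW under 6:2:2 five-fold cross-validation with
validation-AUROC model selection and a 500-tile sampling cap; test-time
inference uses all tiles. Per-tile explanations come from attention rollout
(recursive multiplication of head-averaged attention matrices), single-tile
classification scores, and their product (contribution maps). Predicted
labels feed Kaplan-Meier / log-rank / Cox analyses of time-on-treatment and
overall survival derived from claims-style tables (100-day presumed-death
rule, 21-day exclusion).

Forward, backward and optimizer are plain base-R matrix algebra, verified
against finite differences in the test suite.

## Worked example

Generate a synthetic paired-modality cohort with planted complementary
signal, train the dual-branch model under five-fold cross-validation, and
evaluate all three inference modes:

```r
library(duetmil)

cohort <- generate_cohort(synth_config(seed = 101))
cohort
#> Synthetic paired-modality cohort: 300 cases (91 positive, 30.3%), assay MSI_LOCI

cv <- duonet_cv(cohort,
                duonet_config(model_dim = 64, n_heads = 4, mlp_hidden = 64),
                train_config(learning_rate = 1e-3, epochs = 10,
                             eval_every = 200, seed = 101),
                keep_fits = TRUE)
summary(cv)
#>       mode n_folds mean_auroc  ci_lower  ci_upper
#> 1     DUET       5  0.9595279 0.9251694 0.9938864
#> 2  HE_ONLY       5  0.8593673 0.7624046 0.9563299
#> 3 IHC_ONLY       5  0.8699357 0.8200490 0.9198224
```

The duet model (mean test AUROC 0.96, t-based 95% CI across the five
folds) beats both single-stain modes (0.86, 0.87) because each modality of
a positive case expresses its signal only 70% of the time — exactly the
complementarity the dual-modality design exploits. Screening trade-off at
a 2% admissible false-negative percentage:

```r
curve <- tradeoff_curve(cv$records[cv$records$mode == "DUET", ])
pick_operating_point(curve, target_fn_pct = 2)
#>       threshold fn_pct   tn_pct sensitivity
#> 158 0.002489676      2 50.33333   0.9340659
```

i.e. accepting 2% false negatives, the model rules out 50% of all cases
while keeping sensitivity at 93%. Survival stratification by predicted
status (pooled cross-fold test predictions, threshold 0.5):

```r
sv <- survival_by_status(cohort,
                         predictions = cv$records[cv$records$mode == "DUET", ])
sv$cox[c("hr", "ci", "p")]
#> $hr
#> [1] 0.6951807
#>
#> $ci
#> [1] 0.5198601 0.9296276
#>
#> $p
#> [1] 0.01420249
```

Patients the model calls biomarker-positive stay on treatment and survive
significantly longer (hazard ratio 0.70, 95% CI 0.52-0.93, log-scale Wald
p = 0.014) — the predicted labels carry the prognostic signal planted with
the true ones. Heatmaps for one case of the first fold:

```r
maps <- explain_case(cv$fits[[1]], cohort$cases[[cv$splits[[1]]$test_ids[1]]])
render_heatmap(maps$HE, slide_dims = c(1344, 1344), "contribution.png")
```

A thin command-line driver (`inst/cli/duetmil.R`) exposes
`simulate | train | evaluate | explain | survival | all` over a YAML run
configuration; see `run_pipeline()`.

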