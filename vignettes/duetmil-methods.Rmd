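---
title: "Dual-modality multiple-instance learning for whole-slide biomarker prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality multiple-instance learning for whole-slide biomarker prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(duetmil)
```

## The problem

Predictive biomarkers for immunotherapy — microsatellite instability (MSI)
and mismatch-repair deficiency (MMRd) in colorectal cancer, PD-L1 combined
positive score (CPS) in breast cancer — are routinely called from
sequencing or from pathologist-scored immunohistochemistry (IHC). Both
routes are slow, costly and partly subjective. `duetmil` implements a
weakly supervised image-analysis pipeline that predicts a binary biomarker
status directly from whole-slide images (WSIs), using the routine H&E
morphology stain and a single IHC stain *together*, and then asks two
follow-up questions a clinical team would ask: which tissue regions drove
the prediction (attention and contribution heatmaps), and do the model's
predicted labels stratify patient outcomes (time-on-treatment and overall
survival) the way laboratory-confirmed labels do?

Because paired H&E/IHC slide archives with linked molecular calls and
claims data are private, the package is built to be exercised end-to-end on
synthetic cohorts whose structure mirrors the real setting. The synthetic
generator is first-class, tested code; every statistic the package reports
can be recomputed from scratch on a laptop.

## The model

Each slide is reduced to a *bag* of tile embeddings: the slide is
segmented, tessellated into 224 x 224-pixel tiles at x10 magnification
(about 1 micron per pixel), and each tile is mapped to a 768-dimensional
feature vector by a pluggable encoder. The aggregator is a transformer
over the bag:

* a linear projection from the embedding width to `model_dim`;
* a learned class token prepended to the tile tokens;
* two pre-norm transformer blocks (multi-head self-attention followed by a
  GELU feed-forward), with no positional encodings, so the model is
  permutation-invariant over tiles as multiple-instance learning requires;
* the final class-token state is the slide representation.

The same trunk — identical parameters — processes the H&E bag and the IHC
bag ("parameter sharing"). The two class-token states are concatenated
(H&E block first) and an MLP head produces one logit; the logistic link
gives the slide-pair probability. During training, with probability
`p_branch_dropout = 0.3` per step one of the two branches is *dropped*:
its feature block is replaced by zeros. The head therefore learns to
tolerate a missing modality, which is what makes single-stain inference
(`HE_ONLY`, `IHC_ONLY`) possible with the same trained weights.

Forward pass, backpropagation and the AdamW optimizer are written directly
in base-R matrix algebra, and the analytic gradients are checked against
finite differences in the test suite.

### Design choices the description left open

* **Block structure.** Pre-norm blocks, GELU activations, a learned class
  token, and a final layer norm — the standard small-ViT arrangement used
  by transformer MIL aggregators.
* **Dropped/missing branch filling.** Zeros, before concatenation. This
  keeps the head input width fixed and makes branch dropout and missing
  modalities the same mechanism.
* **Branch-dropout semantics.** `p` is the per-step probability that *some*
  branch is dropped, with the victim chosen uniformly; a lone available
  branch is never dropped.
* **Loss.** Binary cross-entropy on the single logit. No class
  re-weighting is applied by default.
* **Model selection.** Validation AUROC every `eval_every` iterations and
  at the end of training; the earliest best checkpoint wins ties.
* **Feed-forward width.** Twice `model_dim` (the head's hidden width is a
  separate `mlp_hidden`).

## Training and evaluation protocol

Cross-validation follows a 6:2:2 design: five outer folds partition the
cohort into test sets; within each fold the remaining 80% splits 3:1 into
training and validation. Folds are stratified by label so every split
retains both classes at desk-scale cohort sizes. Training iterates slides
singly (batch size one) with AdamW; at most 500 tiles per slide are
randomly sampled during training and validation, while test-time inference
always uses all tiles (enforced by a mode flag, not caller discipline).
Default hyperparameters mirror the published recipe (learning rate 1e-5,
weight decay 5e-4, 10 epochs, evaluation every 500 iterations).

The primary metric is AUROC, reported per fold and aggregated as a mean
with a Student-t 95% confidence interval across the five folds. Stratified
AUROC by scanner and specimen site audits covariate robustness; strata
with a single class are reported as undefined rather than dropped. The
screening trade-off analysis sweeps every distinct predicted probability
as a threshold (positive iff probability >= threshold) and reports the
false-negative percentage (FN/total x 100), true-negative percentage and
sensitivity; `pick_operating_point()` returns the point ruling out the
most cases subject to an FN% bound.

## Explainability

Attention rollout averages each layer's heads into one row-stochastic
matrix and multiplies the layer matrices in order; the class-token row,
restricted to tile columns and renormalised, attributes the slide score to
tiles. Per-head class-token attention maps are also exported. The per-tile
*classification* score is the model probability when the tile is presented
alone; the *contribution* map is the elementwise product
attention x classification. For display each channel is min-max normalised
to [0, 1] after clipping at the 1st/99th percentiles; a constant channel
maps to zero and is flagged rather than producing NaN. Degenerate identity
attention (all mass retained by the class token) falls back to uniform
scores with a warning. The plain product rollout is the default; a
residual-corrected variant is deliberately not applied.

## Claims-derived endpoints and survival

Time-on-treatment (TOT) is the day interval between the first and last
drug administrations in the claims stream. Overall survival uses a
recorded death date when present; otherwise a claims gap of *more than*
100 days before the data refresh is presumed death — imputed at the last
claim day, the latest evidence of being alive — and contact within 100
days of the refresh is censoring. Cases with TOT below 21 days are
excluded from survival analyses as poor-quality data. Kaplan-Meier
estimation, the log-rank test and the Cox proportional-hazards model (the
biomarker-negative group as reference, Breslow ties by default, Efron
behind a flag) are delegated to the `survival` package; a monotone
likelihood is an explicit error, never a silent estimate. Stratification
by *predicted* status thresholds the pooled cross-fold test probabilities
at 0.5 by default, with the screening operating point available as an
alternative.

## The synthetic cohort generator

`synth_config()` defines the study conditions. Each case carries a latent
binary status drawn at the configured prevalence. Embedding bags are
isotropic Gaussian noise; in positive cases a fraction of tiles is
mean-shifted inside a small modality-specific coordinate block (H&E and
IHC blocks are disjoint, so each stain carries its own signal). Assay
measurements are drawn conditionally on status — over-dispersed
negative-binomial locus counts for the MSI arm, Poisson cell-count pairs
for the CPS arm — with rejection so the *rule-derived* label (locus
thresholds 116/113-115/112, or CPS >= 10) always equals the latent status.
Scanner and specimen site are assigned per case and applied as small
constant offset vectors in a nuisance subspace disjoint from both signal
blocks, the smallest mechanism that lets stratified evaluation detect
covariate shift. Linked claims-style outcome tables draw
status-conditional exponential death and treatment-stop times with a
configurable true log hazard ratio, independent dropout, administrative
censoring at the claims refresh, and a configurable fraction of deaths
that go unrecorded so the 100-day rule has work to do.

What the generator does *not* emulate: real histology texture statistics,
stain variation, spatial correlation between neighbouring tiles, encoder
geometry of real pretrained models, and informative censoring. Passing
tests therefore demonstrate that the machinery is correct and that the
architecture behaves as designed under known conditions — not that any
particular AUROC would transfer to real slides.

### Study conditions

Two synthetic regimes are used by the package's own experiments, chosen to
probe different properties of the method:

* **Classification study (default `synth_config()`).** n = 300 cases,
  prevalence 0.3, 10-40 tiles per slide, 30% of tiles shifted by 2.0 in a
  16-dimensional block per modality, and *complementary* expression: each
  modality of a positive case expresses its signal independently with
  probability 0.7 (at least one always does). Single-stain information is
  thus deliberately incomplete (a single-modality model faces ~30% of
  positives with no visible signal) while the pair is nearly complete —
  the regime in which dual-modality fusion should, and does, beat either
  stain alone. Prevalence is enriched relative to a real screening cohort
  so that every desk-scale fold holds enough positives for stable training
  and fold-level AUROC.
* **Explainability study (sparse-witness conditions).** Same cohort shape,
  but only 10% of tiles carry signal, shifted by 3.0 in an 8-dimensional
  block. Here the bag mean is a weak classifier and the model must
  *select* witness tiles, which is precisely the regime in which attention
  rollout is expected to localise. Under dense signal the classifier
  saturates early and weight decay then pulls the unneeded attention
  logits toward uniform, so localisation is not a meaningful property
  there; this behaviour is intrinsic to attention-MIL training, and the
  package documents it rather than hiding it.

The desk-scale training harness uses `model_dim = 64`, 4 heads,
`mlp_hidden = 64` and learning rate 1e-3 (10 epochs, evaluation every 200
iterations). The published defaults (512-dim model, 8 heads, learning rate
1e-5) remain the package defaults but are sized for GPU-scale cohorts; at
~2,000 batch-one steps on a 300-case cohort they leave a freshly
initialised model undertrained, while 1e-3 trains to convergence and 2e-3
is already unstable.

## Numerical details

* Layer norm uses eps = 1e-5; GELU is exact (`x * pnorm(x)`).
* Softmax rows are shifted by the matrix maximum before exponentiation.
* AdamW decays weight matrices only (not biases, layer-norm parameters,
  or the class token).
* Binary cross-entropy is computed in the numerically stable logit form.
* The trade-off curve includes an `Inf`-threshold row for the all-negative
  operating point.
* All randomness flows from one master seed through `derive_seed()`
  (stage-name hashing), so stages are independently reproducible and any
  fold schedule can run in parallel without changing results.
* A probability of exactly 1 falls in the closed last histogram bin;
  survival times of zero days are nudged to half a day so the
  product-limit estimator is defined.

## Known limitations

* The toy tile encoder is a deterministic statistics-projection stand-in
  honouring the encoder contract; it separates synthetic textures but is
  not a learned histopathology representation. Any external encoder with
  the same `tiles -> N x width` contract can be plugged in.
* The tissue segmenter is a saturation/Otsu stand-in for a trained pixel
  classifier; the control-region detector is replaced by an explicit
  exclusion-geometry interface.
* Embedding bags are serialized as RDS (with a CSV export); no HDF5
  binding is used.
* Single binary endpoint; no multi-class heads, no multivariable Cox
  adjustment, no proportional-hazards diagnostics, no DeLong variance or
  calibration analysis.
* Exact tile-multiplicity invariance does not hold with a class token in
  the softmax denominator; deviations are tiny (< 1e-4 is asserted) but
  structurally present.
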