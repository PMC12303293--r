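---
title: "dermastack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dermastack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dermastack classifies smartphone photographs of skin lesions into six
diagnostic classes — actinic keratosis (ACK), basal cell carcinoma (BCC),
melanoma (MEL), nevus (NEV), squamous cell carcinoma (SCC) and seborrheic
keratosis (SEK) — by combining an image branch and a clinical-metadata branch
through a stacking ensemble. This vignette explains the model, the
conventions the implementation fixes, the design decisions that were
genuinely open, and what the synthetic test bed does and does not show.

## The pipeline

Each photograph is resized to 224 x 224 x 3 and expanded into a triplet:

1. the **original** image;
2. its **Black-Hat transform** `T_BH(I) = (I . B) - I`, the morphological
   closing of the grayscale image minus the image itself, which isolates
   dark structures smaller than the structuring element `B` (hairs,
   pigmented spots, lesion borders) against lighter skin;
3. its **adaptive Gaussian binarisation**, where a pixel is white iff its
   intensity strictly exceeds the Gaussian-weighted mean of its local window
   minus a constant `C` — a per-pixel threshold robust to uneven
   illumination.

The three members are each passed through a patch-based transformer
feature extractor (ViT-B/16 geometry: 16-pixel patches, 196 tokens,
768-dimensional embeddings) producing 14 x 14 x 768 feature maps
`F_original`, `F_blackhat`, `F_adaptive`. Fusion is multiplicative then
concatenative:

    M_bh = F_original * F_blackhat        (element-wise)
    M_ad = F_original * F_adaptive        (element-wise)
    F    = concat_x(F_original, M_bh, M_ad)   # 14 x 42 x 768

Global average pooling reduces `F` to a 768-vector, and a single dense
layer with softmax yields the image-branch probabilities. Because the
concatenation runs along the spatial width axis, the pooled vector is
exactly the arithmetic mean of the three branch GAPs; the test suite
asserts this collapse to 1e-12, which pins the fusion geometry.

Clinical metadata (the 26-attribute PAD-UFES-20 schema) feeds a
gradient-boosted tree ensemble (xgboost). The two branches' 6-class
probability vectors are concatenated, image half first, into a 12-long
stacked vector; a ridge multinomial logistic regression (the meta-model)
produces the final prediction.

## Imaging conventions

All of these are fixed and documented so that independent per-pixel oracles
reproduce the operators bit-exactly:

* **Grayscale**: ITU-R BT.601 luma weights (0.299, 0.587, 0.114), rounded
  half-up. Subsequent filters keep fractional precision.
* **Borders**: reflect-101 (reflection about the edge pixel) for
  morphology, blur and thresholding alike.
* **Gaussian blur**: separable kernel truncated at `ceiling(3 * sigma)`
  samples per side, normalised to unit sum.
* **Resize**: exact area averaging when an axis shrinks, bilinear with
  half-pixel-aligned centres when it grows; resizing to the same target is
  idempotent.
* **Threshold comparison** is strict (`>`): ties go to black.
* **Black-Hat kernel**: elliptical 9 x 9 by default, sized to the dark
  features of interest (hair shafts, pigment clumps); configurable.

### The threshold window

The local window must act as an estimator of the *surrounding skin*, not of
the lesion interior: a window much smaller than the lesion sees only
lesion, its local mean equals the interior intensity, and the interior
thresholds white. A window of side `w` can only reach `(w - 1) / 2` pixels,
so a 21-pixel window cannot segment any lesion larger than ~10 px radius
regardless of the weighting. The package therefore defaults to `window =
61` on 224-pixel images (roughly a quarter of the frame) with weight scale
`weight_sigma = (window - 1) / 2`, i.e. the window spans one standard
deviation per side — broad and gently centre-weighted. `C = 5` intensity
levels suppresses noise-induced black speckle (post-blur noise is ~1
level), and the pre-threshold blur uses `sigma = 1`. All four parameters
are configurable per call and on the command line.

## The backbone contract

The feature extractor is a *contract*: image in, 14 x 14 x 768 map out,
deterministic for fixed weights. Two weight sources implement it:

* **seeded-test** (default): a randomly initialised encoder with the same
  input/output geometry but configurable depth (default 2 blocks, 4 heads,
  768-wide MLP). All weights are N(0, 0.02^2) draws from one seed, so every
  downstream stage is testable on one CPU with no downloads and byte-level
  reproducibility. Random untrained features are a standard, surprisingly
  strong baseline for linear probes, which is what the dense head is.
* **pretrained**: an adapter accepting a user-supplied weight list with the
  full 12-block ViT-B/16 geometry (converted from a released checkpoint).
  No checkpoint is bundled. The backbone is frozen in either case; features
  are precomputed once. Fine-tuning is out of scope.

Inputs are scaled to 0..1 and standardised per channel with the
conventional ImageNet statistics, identically for all three triplet
members. Tokens map to the spatial grid row-major; no class token is used,
so the 196 tokens and the 14 x 14 grid correspond one-to-one.

## Image-branch head, focal loss, class weights

The head is one dense layer 768 -> 6 with softmax (the architecture is
deliberately minimal: one fully connected layer). It is trained by
full-batch gradient descent with momentum (default 300 epochs, learning
rate 0.5 on column-standardised features, momentum 0.9) on the
class-weighted **categorical focal loss**

    L = -alpha * w_y * (1 - p_y)^gamma * log(p_y),   gamma = 2, alpha = 0.25

with balanced class weights `w_c = N / (K * n_c)`. At `gamma = 0`,
`alpha = 1` the loss reduces exactly to class-weighted cross-entropy, and
the analytic gradient is verified against finite differences in the tests.
The focal literature's sigmoid formulation does not compose with a softmax
output; the focal modulation is therefore applied to the softmax
probability of the true class (categorical focal loss). Probabilities are
clipped at 1e-12 inside the loss. All randomness (initialisation, the
optional stratified validation carve-out for early stopping) flows from one
seed in `head_config()`.

## Clinical branch

`clean_metadata()` drops the three identifiers, the diagnostic label and
the anatomical region (kept out so the model is not anchored to body
location), encodes booleans as 0/1 and categoricals as ordinal integer
codes — boosted trees are insensitive to the ordering, and a level map is
stored so new data encodes consistently — and **never imputes**: every
missing cell stays `NA` and is routed natively by xgboost's default
directions. Defaults: 300 trees, depth 6, learning rate 0.1, multiclass
softmax objective, single-threaded for determinism.

`biopsied` is retained as a predictor. It plausibly leaks diagnostic
certainty (biopsies are ordered for suspicious lesions); users comparing
against clinical practice should consider dropping it.

## Stacking protocol

* The 80/20 train/test split is made first (test size =
  round-half-up(0.2 n), which reproduces 1838/460 from 2298 samples);
  cross-validation operates inside the 80%.
* `make_fold_plan()` builds stratified K-folds (default K = 10) by dealing
  shuffled class members one at a time to the currently smallest fold:
  per-fold class counts stay within 1 of proportional *and* fold totals
  stay within 1 of each other for arbitrary label multisets.
* `make_oof_stack()` trains both base models K times; each sample's stacked
  vector comes from base models that never saw its fold. The tests assert
  the leakage guard directly: perturbing a sample's fold-mates never
  changes its own out-of-fold vector.
* The meta-model is trained on the out-of-fold vectors; the base models are
  then refit on the full training split for deployment. Ridge multinomial
  regression (glmnet, `alpha = 0`, `lambda = 0.01`) keeps the 12 collinear
  probability inputs stable.
* Argmax ties break toward the lowest class code.

## Evaluation arithmetic

Per class, one-vs-rest: PPV = TP/(TP+FP), recall = TP/(TP+FN), F1 = their
harmonic mean, NPV = TN/(TN+FN) with TN computed against the total
evaluated count, which is threaded explicitly. Overall metrics are **macro
(unweighted) averages** — this aggregation rule is confirmed by exact
arithmetic: macro-averaging the published per-class table reproduces the
published overall PPV/recall/F1 to all six printed decimals, and
`recover_confusion_counts()` recovers the integer confusion counts behind
printed ratios (e.g. PPV 0.840909 and recall 0.948718 at n = 460 are
exactly 37/44 and 37/39), which in turn reproduce the printed NPVs.
Undefined ratios (zero denominators) are flagged `NA` with a warning and
excluded loudly — never silently zeroed.

## The synthetic test bed

`synth_config()` defines the study conditions used throughout the tests:
600 paired samples, class mix qualitatively mirroring the real imbalance
(ACK 32%, BCC 35%, MEL 4%, NEV 11%, SCC 8%, SEK 10% — MEL rare but still
>= 10 per class inside the training split, as 10-fold stratified CV
requires), ~35% missingness on the lifestyle/demographic metadata columns,
and `signal = 1` ("strong signal").

Images emulate: a skin-toned background varying across captures, a linear
illumination gradient, Gaussian sensor noise, one darker elliptical blob
with class-dependent contrast (55–95 levels), radius (14–30 px), boundary
irregularity and chromatic tint (melanoma dark and neutral, BCC
pearly-pink, keratoses erythematous or waxy-brown), mild internal
reticular texture, and 0–2 dark hair strokes that give the Black-Hat
branch structure to respond to. Metadata rows follow the field's risk
factors: malignant classes older, fairer Fitzpatrick types, more frequent
skin-cancer history, growth/change/bleeding symptoms, larger diameters.
At `signal = 0` every class-conditional distribution collapses to the
common mean (verified by a two-sample test in the suite).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: photorealistic lesion morphology and texture,
close-up framing where the lesion fills most of the frame, camera-specific
artifacts (compression, white balance, focus), co-occurring distractors
(rulers, ink marks), label noise, and patient-level correlation between
lesions. Accuracy on the synthetic bed measures *recovery of a planted
signal*, not clinical performance; the published headline numbers require
the real dataset and a pretrained, fine-tuned backbone, both outside this
package's scope.

Problem sizes in the test suite were chosen to keep a full run on one CPU
comfortable: oracle equivalence on 16 x 16 / 32 x 32 rasters, protocol
checks at n ~ 100, the end-to-end study at n = 600 with the depth-2 seeded
backbone.

## Numerical and degenerate-input choices

* All RNG use is local: every public function that draws randomness takes a
  seed, saves and restores the caller's RNG state, and the pipeline fans a
  single global seed out through `derive_seed(seed, offset)`.
* `compute_class_weights()` and the model fitters error on absent classes
  and single-class inputs rather than returning degenerate fits.
* `stack_probs()` validates both halves sum to 1 within 1e-6.
* Softmax is computed with the max-shift; adding a constant to all logits
  leaves probabilities unchanged within 1e-9.
* Byte-level determinism is asserted for image generation, metadata CSVs,
  backbone features (a frozen golden check) and full pipeline reruns.

## Known limitations

* The seeded-test backbone is untrained; its features are a linear-probe
  baseline, not learned representations. Plug in pretrained weights via the
  adapter for real use.
* The dense head and meta-model are deliberately small; there is no
  hyperparameter search anywhere.
* `region` is dropped by design even though anatomical site is clinically
  informative; `biopsied` is kept even though it may leak (see above).
* Morphology is implemented with dense shift-and-compare operations: exact
  and fast at 224 x 224, but not optimised for megapixel inputs (resize
  first, as the pipeline does).
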