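---
title: "Auditing image datasets for shortcut-learning hazards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing image datasets for shortcut-learning hazards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`otobias` audits binary medical-image datasets for properties that let a
classifier cheat: acquisition artifacts correlated with the label,
near-duplicate images leaking across the train/test boundary, and
dataset-level style differences aligned with the diagnosis. This vignette
explains the models and procedures, the parameters that matter, what the
synthetic validation data does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The data contract

A dataset is a *manifest* — a CSV binding image files to binary labels
(0 = normal, 1 = abnormal), optional subtype and patient metadata, and a
split tag (`train` / `internal_val` / `unassigned`) — plus 8-bit RGB
rasters (PNG natively; JPEG via EBImage when installed). Analysis is
image-level by default, mirroring common practice in public otoscopy
collections; `stratified_split(by_patient = TRUE)` moves whole patients
together, which is the partitioning we actually recommend whenever patient
identifiers exist, precisely because image-level splitting is one of the
leakage mechanisms the redundancy audit detects.

The stratified split assigns, per class, `max(1, round(fraction * class
size))` shuffled records to internal validation. The `max(1, ·)` floor is a
deliberate choice: it guarantees both classes appear in validation even for
degenerate class sizes, at the cost of slightly exceeding the nominal
fraction there. The assignment is a pure function of (manifest order,
fraction, seed).

## Counterfactual occlusion

`apply_eclipse(img, extent)` blacks out the pixels whose centers satisfy

$$\left(\frac{x - c_x}{e\,W/2}\right)^2 + \left(\frac{y - c_y}{e\,H/2}\right)^2 \le 1,$$

with $c_x = (W-1)/2$, $c_y = (H-1)/2$ and $e$ the *extent*. The boundary is
inclusive and evaluated at pixel centers, which makes masks bit-exactly
reproducible; masked sets are nested in $e$, and the masked-area fraction
converges to $(\pi/4)e^2$ (within 0.5% at 512×512). The ellipse is centered
on the image rather than on a localized anatomical region: otoscope framing
places the tympanic membrane centrally, and no localization procedure is
assumed. Extent 1 is the inscribed ellipse — the corners stay visible, which
is exactly the point: anything a classifier still reads at extent 1 lives in
the border, not the anatomy.

In the pipeline sweep (`run_experiment1`), evaluation sets are masked at the
same extent as training. Masking only the training side would conflate the
audit signal with a train/test distribution shift; masking both isolates the
question "is there label signal outside the clinical region?".

## The color-statistic audit

Each image is summarized by six statistics of the hexcone HSV transform:
hue mean and std (degrees, linear statistics), saturation and value mean and
std (8-bit scale, population standard deviations). Choices worth stating:

* **Scale.** H in degrees [0, 360), S and V in [0, 255]. Odds ratios are
  per-unit and therefore scale-dependent; any comparison across toolchains
  must fix the scale first.
* **Hue linearity.** Linear hue statistics are the default; they are wrong
  near the 0/360 wrap (a red image with hues {1°, 359°} gets mean 180°). A
  circular option (`circular_hue = TRUE`) exists, but the default is linear
  because reddish otoscopy hues rarely straddle the wrap and linear moments
  are what plain logistic pipelines consume.
* **Pixel set.** All pixels by default, including black borders and eclipse
  masks; `fov_mask()` (value > 10) is available to exclude them. Auditing
  the full frame is the conservative choice — borders are acquisition
  artifacts too.
* **Population vs sample std.** Population, the image-statistics convention;
  at image pixel counts the difference is negligible.

The audit model is unpenalized logistic regression fitted by IRLS (tolerance
1e-8 on the coefficient change, 100 iterations maximum), raw features, no
selection, no standardization — deliberately naive, because the point is
that *even this* classifies biased data. The covariance is the inverse
observed Fisher information; per-feature odds ratios are $e^\beta$ with Wald
CIs $e^{\beta \pm z\,\mathrm{SE}}$. Complete separation (diverging
coefficients; the working threshold is $|\beta| > 30$, far beyond any
plausible per-unit color effect) flags the model as non-converged, and
`odds_ratios()` refuses it — Wald inference is meaningless there, while the
ranking the scores induce is still usable for AUC. Strongly planted
synthetic confounds do separate completely; real clinical datasets at
realistic effect sizes typically do not.

## ROC machinery

AUC is the Mann-Whitney statistic with ties counted ½ — synthetic audits
produce genuinely tied scores (a nearest-neighbor classifier emits 0/1), so
the tie rule is load-bearing. The DeLong variance comes from per-positive
and per-negative placement values computed via midranks in O(n log n);
a brute-force O(mn) structural-components oracle validates it in tests. CIs
are normal-approximation, truncated to [0, 1]; perfect separation yields a
zero-variance point CI with a warning rather than an error, because the
audits legitimately produce AUC 1. The unpaired comparison uses
$z = (\hat A_1 - \hat A_2)/\sqrt{v_1 + v_2}$ against the standard normal
(one-sided for the leakage hypothesis, oriented AUC(leaked) >
AUC(clean)); the paired variant subtracts placement values before taking
variances, capturing their covariance. Monte Carlo calibration at desk
scale: 95% CI coverage ≈ 0.93–0.94 at n = 50/50 and true AUC 0.8 (the
mild undercoverage of the normal approximation at these sizes), and
one-sided type-I error within ±0.015 of nominal 0.05 over 2000 null
replicates.

## Embeddings, duplicates, styles

The default embedding is deliberately not learned: per-channel 32-bin
intensity histograms (96 dims) concatenated with a 16×16 bilinear
downsampled luminance grid (256 dims), L2-normalized. It is deterministic,
fast, and sensitive to exactly the properties the audit needs — global
color distribution and coarse framing geometry. `crossfold_embeddings`
reproduces the protocol of averaging embeddings from k fold-trained models
(5 stratified folds by default); with the non-trainable default it
provably reduces to single-pass embedding, and a trained embedder can be
plugged in via the factory argument.

Grouping is single-linkage: components of the graph with an edge wherever
cosine distance ≤ α. Single linkage is the only linkage for which the
grouping is *monotone* in α (every set at a smaller threshold is contained
in one set at a larger threshold) — a property the tests exploit and users
can reason with. All pairwise distances are computed exactly; at the
dataset sizes in scope (≲ 20k images) the O(n²) cost is acceptable and
deterministic.

Two thresholds, both calibrated on the generator and fixed:

* `alpha_dup = 2e-4` for near-duplicates. Exact copies sit at distance
  ~1e-15; distinct generated images never fall below ~9e-4 across seeds
  and sizes. Recovery of planted duplicate sets is exact
  (precision = recall = 1) when copies are unperturbed; once copies are
  jittered (pixel shifts + noise), their distances (~0.02 at 1-pixel
  jitter) overlap the distinct-image scale and a single global threshold
  can no longer be perfect — the redundancy report still finds such sets at
  a looser α, but with possible false merges.
* `alpha_style = 0.05` for styles: same-style pairs lie below ~0.015,
  cross-style pairs above ~0.12, so 0.05 cleanly separates framing
  regimes.

The redundancy report counts duplicate sets, their sizes, and `Σ(size − 1)`
redundant images, and partitions internal-validation images by whether they
share a set with a training image. Style clusters (≥ `min_size` members at
`alpha_style`) are reported with label composition; association with the
label uses Fisher's exact test — an implementation choice for a calibrated
small-sample test — and purity ≥ 0.9 flags a candidate style bias.

## The synthetic generator

`generate_dataset` renders otoscope-like images: a dark chroma-textured
border (every channel < 20), a bright circular field of view, a shaded
"canal" annulus, and an inner "membrane" disk, with per-image color jitter.
Two framing styles emulate acquisition regimes: Style I (full field,
radius 0.48·min(H, W), centered) and Style II (zoomed, radius
0.34·min(H, W), center offset by (0.10 W, 0.06 H)). The planted biases:

* **Clinical signal**: a blob of `clinical_contrast` added to the green
  channel strictly inside the membrane disk (within 0.4 of its radius, blob
  radius 0.3·r_membrane). Because the membrane sits inside the central
  ellipse, an eclipse of extent ≥ 0.7 provably removes the signal — this
  turns the causal claim "the model reads artifacts" into a testable
  property. Green is used because membrane colors leave headroom there, so
  a contrast-80 blob survives without clipping.
* **Saturation-variability confound**: abnormal images have the spread of
  their saturation channel around its mean multiplied by
  `1 + saturation_bias` (a variability effect, not a mean shift, because
  saturation *std* is the discriminative feature being emulated). It is
  applied image-wide — including the dark border — so the confound, like
  real lighting artifacts, survives full occlusion.
* **Style bias**: with probability `style_bias_prob` the framing style is
  determined by the class (normal → I, abnormal → II), else uniform.
* **Near-duplicates**: `round(fraction · n)` source images get 1–3 copies
  (uniform), shifted by ≤ `jitter` pixels with edge replication plus
  Gaussian noise of sd `jitter`; copies inherit the label, and with
  `leak_across_split` the first copy lands in the opposite split.

One master seed feeds named substreams (style, render, signal, bias, split,
duplication), so toggling one bias leaves the draws of the others
untouched; output is byte-identical across runs.

Default condition sizes: 200 images per class for the color audit (a 20%
stratified validation split then holds 40 per class), 150 per class for the
occlusion sweep and duplicate audits, 64×64 pixels. Effect sizes for planted
biases were chosen by simulation to guarantee separation — a
`saturation_bias` of 1.0 (doubled spread) separates classes essentially
perfectly, which validates recovery but is far stronger than what real
datasets show; weaker settings (≈ 0.15) produce realistic AUCs around 0.85.

**Measurement of null conditions.** With all biases at zero, a single
stratified validation draw of 40/40 has a null-AUC standard deviation of
about 0.065, so a single dataset cannot certify "AUC ≈ 0.5" tightly. Null
internal AUC is therefore measured as the mean over 3 independently seeded
replicate datasets (sd ≈ 0.03), which is what the acceptance checks assert
against the [0.40, 0.60] band.

**What passing these tests does not show.** The generator's artifacts are
planted, separable and stationary; real confounds are weaker, entangled
with anatomy, and drift over time. Perfect duplicate recovery here reflects
exact copies under a deterministic embedding, not the fuzzier
near-duplicates of clinical archives. The audits' *mechanics* are validated
(geometry, statistics, recovery, calibration); their sensitivity on real
data depends on embedder quality and threshold tuning that this package
cannot certify in advance.

## Desk-scale classifiers

Full-scale deep training is out of scope; the pipeline ships two
deterministic stand-ins behind a pluggable fit/score contract (any
classifier honoring it can be substituted, and the dataflow guarantees the
fit never sees evaluation records — asserted in tests with an instrumented
classifier):

* `logistic_on_embedding` — ridge logistic regression (glmnet, fixed
  λ = 0.05, standardized internally) on the 352-dimensional default
  embedding. The ridge penalty is a numerical necessity in the p > n
  regime, not a tuned hyperparameter.
* `nearest_neighbor` — 1-NN on the embedding, scoring with the nearest
  training label. It exists to *demonstrate* memorization: with leaked
  exact duplicates its AUC on the leaked subset is 1 by construction.

## Known limitations

Linear hue statistics near the wrap; a single global duplicate threshold
(no per-pair adaptive criterion); no perceptual hashing; image-level
protocol by default; binary labels only; the default embedding is
translation-sensitive, so heavily shifted duplicates need looser thresholds
than the calibrated default.
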