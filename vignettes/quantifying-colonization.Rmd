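---
title: "Quantifying arbuscular mycorrhizal root colonization from stained micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying arbuscular mycorrhizal root colonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootquant)
```

## The measurement problem

Arbuscular mycorrhizal (AM) fungi colonize the root cortex of most plant
species, and nearly every study of the symbiosis needs a per-sample estimate
of *how much* of the root is colonized. The standard laboratory readout is a
brightfield micrograph of a cleared, blue-stained root segment: fungal cell
walls retain the stain and appear dark blue, plant tissue stays translucent
or light blue, and the slide background is near white. The classical
quantification is visual — an operator assigns each segment to one of six
intensity classes (1 none, 2 few traces, 3 under 10%, 4 10–50%, 5 50–90%,
6 over 90%) — which is slow and operator-dependent.

`rootquant` implements two semi-automated, image-based estimators of the
colonized area fraction, plus the statistical layer used to evaluate them
against visual scoring:

* **t-index** (thresholding). After grayscale conversion, the root section
  is isolated from the background and every pixel strictly darker than a
  global brightness cutoff inside the root is counted as stained:
  \[ t = 100 \cdot \frac{\text{mycorrhized area}}{\text{total root area}}. \]
* **ml-index** (pixel classification). Each pixel is described by a
  25-channel filter-bank vector and classified as *colonized*,
  *root tissue* or *background* by a random forest trained on annotated
  pixels:
  \[ ml = 100 \cdot \frac{\text{colonized}}{\text{colonized} + \text{non-colonized}}. \]

Both indices live on \([0, 100]\) and are scale-free area ratios, so pixel
calibration (µm/px) is irrelevant to them.

## The thresholding engine

`measure_threshold()` mirrors an ImageJ-macro workflow:

1. **Grayscale conversion** (`to_grayscale()`): BT.601 luminance
   (\(0.299R + 0.587G + 0.114B\), rounded half-up) by default. The red
   channel is offered as an alternative because a blue stain absorbs red
   light most strongly and therefore gives the best fungal contrast; both
   are recorded in the output.
2. **Root isolation** (`extract_root_mask()`): pixels darker than
   `bg_cutoff` (default 240 on a near-white background) are candidate
   tissue; the mask is hole-filled and cleaned by keeping 8-connected
   components covering at least 0.1% of the frame, which removes dust and
   debris without eroding the root band.
3. **Selection** (`threshold_select()`): pixels *strictly below* the
   threshold (default 100) inside the root mask. The strict inequality is
   deliberate and documented so macro ports agree at the boundary: a
   uniform frame at exactly the threshold value selects nothing.

The threshold is a global, *ex ante* setting: nothing is adapted per image.
This is the method's central weakness on real data (brightness varies
between slides, dyes and optics) and its central virtue as a baseline
(fully reproducible and monotone: raising the cutoff can only grow the
selection, a property the test suite asserts).

## The 25-channel feature bank

`compute_feature_stack()` describes each pixel by 25 filter responses:

| channels | filter | parameters (defaults) |
|---|---|---|
| 1–5 | Gaussian blur | σ = 1, 2, 4, 8, 16 px |
| 6–10 | Sobel gradient magnitude of Gaussian blur | σ = 1, 2, 4, 8, 16 px |
| 11–22 | Gabor magnitude | f = 0.05, 0.12, 0.25 cycles/px × θ = 0, π/4, π/2, 3π/4 |
| 23–25 | Hessian at σ = 2 | larger eigenvalue, smaller eigenvalue, determinant |

Design choices, made once and recorded with every trained model:

* **Scales** are octave-spaced and span the width range of the structures
  of interest at low magnification — hyphae a few pixels wide up to
  arbuscule patches tens of pixels across. Gabor wavelengths (1/f = 4, 8.3,
  20 px) cover the same range.
* **Gabor responses are quadrature-pair magnitudes** (even kernel
  zero-meaned), giving invariance to local phase and brightness offset —
  standard texture-analysis practice. Four orientations on a π/2 grid make
  the bank equivariant under 90° rotations (asserted as a property test).
* **The Hessian triple is (λ₁, λ₂, det)**: the eigenvalues are the natural
  ridge/blob detectors for curvilinear hyphae versus compact vesicles, and
  the determinant separates blob-like from saddle-like neighbourhoods.
* **All convolutions use reflective boundary padding**, so a flat field is
  a fixed point of the smoothing channels and derivative channels vanish on
  it exactly; smoothing preserves the global mean of arbitrary images to
  within 0.1% relative.

The 5 + 5 + 12 + 3 partition is pinned by a validation check; a
configuration that does not yield exactly 25 channels is rejected.

## The pixel classifier

Training data are sparse pixel annotations (scribbles): each annotated
pixel carries one of the three classes. `build_training_set()` turns them
into a feature matrix via the bank above; `train_pixel_model()` fits a
random forest (default 100 trees, unlimited depth, fixed seed — the learner
is swappable in principle but a forest is a robust default for 25-D texture
features and small training sets). Training is deterministic given the
seed, models serialize with their feature configuration, and prediction
refuses a feature stack computed under a different configuration (hash
check) rather than silently mixing incompatible descriptors.

Two interpretation decisions deserve emphasis:

* **Three classes, not two.** The ml-index formula names only colonized and
  non-colonized areas; with an explicit background class the denominator
  can be restricted to root tissue (the default), which is what an area
  *of the root* means. `measure_ml(include_background = TRUE)` switches to
  the whole-frame denominator for comparison.
* **Ties** in the forest vote break toward the class listed first in the
  model's class list, making label maps reproducible bit for bit.

`export_training_folder()` / `import_training_folder()` write and read a
shareable reference-training layout (`images/`, `labels/`, `config.yaml`),
so a laboratory can publish the exact annotations behind its model; the
round trip reproduces the training matrix exactly.

## The synthetic scene generator

`generate_scene()` produces micrograph-like images with known ground truth,
which is what makes both engines testable without any image download. A
scene is assembled from:

* a smooth root band (fraction `root_width_fraction` = 0.55 of the frame
  height, sinusoidally modulated edges);
* dark fungal structures placed inside the root: curvilinear **hyphae**
  (smoothed random-walk strokes ~3 px wide), **arbuscules** (dense
  dendritic blobs clipped to cell-sized elliptical patches), and
  **vesicles** (filled ellipses); optionally extraradical hyphae outside
  the root, which are rendered but never counted as colonization;
* intensity levels `background_level` (250) > `root_level` (230) >
  `fungus_level` (80), each mapped to a bluish RGB triple with that
  luminance. The background/tissue pair is placed symmetrically around the
  documented background cutoff (240), so root isolation has a well-defined
  ideal operating point, and the tissue/fungus midpoint (155) plays the
  same role for the colonization threshold;
* a light Gaussian edge blur (σ = 0.7, the anti-aliasing), then an optional
  linear illumination ramp and additive Gaussian sensor noise
  (`noise_sd`, default 0) — difficulty knobs that are off by default so
  tests can separate algorithm error from scene ambiguity.

Structures are added one at a time, centred on not-yet-colonized root
pixels, until the colonized fraction is within 0.02 of
`target_colonization` (exact area targeting is ill-posed under discrete
stencils, so the tolerance is declared, not silent). An in-principle
unsatisfiable request — a positive target with no structure types enabled —
raises a placement error; running out of placement budget instead reports
the achieved fraction with a flag. Scenes are bit-reproducible from their
seed. `generate_dataset()` draws per-class target fractions from the
six canonical class ranges (`trouvelot_target_ranges()`, top class capped
at 0.95) and writes images, masks and a manifest CSV.

What the generator does **not** emulate: stain-intensity variability within
a structure, out-of-focus blur, bacteria/algae/debris that confound real
thresholding, vignetting beyond a linear ramp, and any µm calibration
(scenes are in pixel units; the indices are ratios, so this is benign).
Passing the recovery tests therefore shows the engines are correct on
well-posed input, not that they are robust to every field sample.

## Evaluation statistics

The evaluation layer compares per-image indices against visual class
scores the way method-comparison studies in this field do:

* `descriptives()` — per-class n, mean, sample SD (n−1), range, plus a
  pooled row.
* `anova_raw()` — classical one-way ANOVA via `stats::aov`.
* `anova_from_summaries()` — the same table rebuilt from `(n, mean, sd)`
  alone, which is the tool for re-analysing *published* summary tables
  without raw data. On summaries computed from raw values the two routes
  agree to 1e−9 relative (a core oracle test).
* `bonferroni_pairwise()` — pooled-variance t statistics on the
  within-group df, p-values multiplied by the number of pairs (capped
  at 1). With zero within-group variance, nonzero differences are flagged
  significant at p = 0 rather than crashing.
* `fit_polynomial()` — OLS fits of visual score on index, degrees 1–3,
  with R² about the mean of y (R² ≡ 0 for constant y by convention);
  R² is non-decreasing in degree, asserted as a nesting property.
* `model_report()` — the four-row side-by-side comparison (R² linear /
  quadratic / cubic, significant pairs out of 15).

The package bundles the published per-class summaries of a 180-image
stained-root benchmark (`reference_class_summaries()`), and the acceptance
script reconstructs the benchmark's ANOVA tables, grand means and post hoc
pattern from those summaries alone.

## Numerical and scale choices

* Working bit depth is 8 (16-bit inputs are integer-divided down); filter
  outputs are real-valued.
* Grayscale luminance rounds half away from zero (ImageJ-style), not
  banker's rounding.
* The acceptance experiments run at the generator's default 180 × 240 px
  geometry; the heavier in-suite classifier recovery test runs at
  132 × 176 px, a scale at which hyphae are still several pixels wide and
  all structure classes render faithfully. Training uses 10 scenes with
  150 annotated pixels per class per scene; evaluation spans a 12-scene
  gradient of true fractions 0–0.6 at sensor noise SD 4.
* Trouvelot class edges are half-open intervals at 10/50/90 so the map is
  total and monotone; the class 2/3 boundary ("few traces") is the
  configurable `trace_cutoff`, default 1%, because the visual criterion is
  not numeric.

## Known limitations

* A fixed global threshold cannot cope with between-image brightness
  drift; that failure mode is by design (it is the baseline being
  evaluated), and the classifier is the intended remedy.
* The classifier distinguishes colonized from uncolonized tissue only;
  per-structure classes (arbuscule vs vesicle vs hypha) are left open by
  the type system but not implemented.
* Whole-root-system extrapolated indices (F%, M%, a%, …) of the classical
  visual protocol are out of scope; only per-image class assignment is
  provided.
* Annotation masks are raster scribbles; there is no polygon/vector
  annotation format.
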