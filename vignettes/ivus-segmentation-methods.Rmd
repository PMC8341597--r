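---
title: "Methods: synthetic IVUS phantoms, U-Net segmentation, and clinical vessel assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic IVUS phantoms, U-Net segmentation, and clinical vessel assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intravascular ultrasound (IVUS) images a coronary artery from the inside:
each frame is a grayscale cross-section in which the blood-filled lumen
appears dark, the vessel wall with its atheromatous plaque appears as a
mid-gray annulus, calcium deposits appear as saturated arcs that cast
acoustic shadows, and implanted stent struts appear as small bright points
on the vessel circumference. Two frame-level judgments drive treatment
decisions: whether the lumen is significantly narrowed (cross-sectional
area strictly below 4 mm², the threshold associated with elevated risk of
major adverse cardiac events), and whether calcification is severe (an arc
occupying more than two of the four quadrants around the vessel center).

`ivusseg` implements the full development loop for a semantic-segmentation
approach to these judgments: every pixel of a frame is assigned one of five
classes — background, lumen, media+plaque, calcification, stent — by a
U-Net, and the clinical quantities are derived from the predicted mask.
Because clinical IVUS images with expert annotations are rarely shareable,
the package includes a phantom simulator that produces B-mode-like frames
with exact ground truth, so every stage is testable end to end.

## The phantom model

A synthetic patient is a pullback: an ordered sequence of frames at 0.5-mm
spacing whose geometry evolves smoothly, so nearby frames are strongly
correlated — exactly the correlation that makes frame-level random splits
leak information and motivates patient-level splitting.

Per frame the geometry is parametric: an elliptical lumen (semi-axes in mm,
rotation, slightly off-center), an outer vessel border (lumen plus a wall
thickness of 0.6–1.3 mm), optional calcification arcs carved into the
annulus, an optional strut ring hugging the lumen border, and an optional
bright wire-artifact ray. Parameters follow bounded random walks with
clipped steps; the construction guarantees a per-frame lumen semi-axis
change of at most 0.25 mm, and lesions occupy contiguous frame runs:

* **Stenosis.** A contiguous run of frames whose lumen area dips below
  4 mm² along a smooth profile. Areas inside a run stay at or below
  3.8 mm² and areas outside at or above 4.3 mm², with 4-frame entry/exit
  ramps; the 0.5 mm² guard band around the threshold keeps the analytic
  narrowed flag unambiguous under rasterization while the smallest
  minimum areas reach 1.8 mm².
* **Calcification.** One solid arc per run. Severe runs draw extents in
  185–300° (an arc wider than 180° always touches at least three
  quadrants); non-severe runs draw 15–88° (never more than two). Arc
  endpoints are kept at least 4° away from quadrant boundaries so that
  rasterized pixels cannot spill across a boundary and flip the
  ground-truth quadrant count. The arc sits 0.03–0.10 mm outside the lumen
  border with a thickness of 0.25–0.40 mm, clipped to stay inside the wall.
* **Stent.** A ring of 7–10 struts (0.09-mm radius blobs at the lumen
  border) with per-strut angular jitter and slow drift across the run.

Lesion run lengths are drawn per patient as Binomial(frames, fraction), so
the dataset-level fraction of frames showing each lesion follows the
configured probability with plain binomial sampling error even though
frames are correlated within patients. The defaults — 59.1% of frames with
calcification, 12.3% with a stent, 28.7% of calcified runs severe —
reproduce the composition of a single-center complex-lesion cohort; the
narrowed-lumen fraction defaults to 0.35, a plausible value for pullbacks
through culprit lesions, and is freely configurable.

Rendering builds a deterministic echogenicity map (lumen 0.06, media+plaque
0.45, background 0.18 with a bright adventitia rim outside the vessel
border, calcification 0.95, struts 1.0), attenuates everything radially
outward of a calcification or strut within its angular sector to a
configurable residual (default 0.15), draws the catheter ringdown at the
image center, and multiplies in Rayleigh-distributed speckle smoothed by a
3×3 binomial kernel. With `speckle_scale = 0` the rendered frame equals
the deterministic map exactly, which the tests exploit.

Two deliberate conventions:

* **The catheter is labeled lumen.** The bright ringdown circle exists only
  in the B-mode rendering; in the mask its pixels carry the lumen class,
  because they lie inside the luminal border — the same convention expert
  annotators use. This also keeps the pixel-count lumen area an unbiased
  estimator of the analytic ellipse area π·a·b, which the recovery tests
  check to 2%.
* **Pixel spacing is an assumption.** Clinical export resolution is rarely
  recorded alongside images; the default of 0.02 mm/px on 256×256 frames
  (a ~5 mm field of view, plausible for a 60-MHz catheter) is configurable,
  and all areas scale with its square. Scaled-down runs use 64×64 frames at
  0.08 mm/px, preserving the field of view.

What the phantoms deliberately do **not** emulate: polar-domain acquisition
physics and ring-down artifacts beyond a schematic catheter, bifurcations,
thrombus, dissection, side branches, and the full texture statistics of
tissue. Passing tests therefore demonstrate that the pipeline's machinery
is correct and that the network can learn this class of appearance; they do
not certify clinical performance.

## The mask convention

Masks travel as 8-bit RGB PNGs with one flat color per class: black
background, green lumen, red media+plaque, orange (255,165,0)
calcification, blue stent. Decoding assigns each pixel the nearest palette
color under the max-channel distance with a tolerance of 10 (forgiving
slight antialiasing in third-party masks), and refuses pixels farther than
that from every palette color, listing their coordinates. Write-then-read
is bit-exact, which the tests assert on random masks.

## The network and its training recipe

The segmenter is a U-Net: `depth` encoder levels of two 3×3 stride-1
convolutions (ReLU, dropout 0.1 after each) with 2×2 max-pooling between
levels and filter counts doubling per level; a symmetric decoder with 2×2
nearest-neighbour upsampling and skip concatenation from the matching
encoder level; and a 1×1 convolution to a per-pixel 5-way softmax. Padding
is "same", so predictions align with the input grid; argmax ties break
toward the lower class index. Training uses categorical cross-entropy,
Adam at learning rate 0.001, batch size 2, horizontal/vertical flips and
rotations for augmentation, and 20% of training frames for validation.

Choices this package had to make explicit:

* **Feature widths** default to 16 doubling per level; both depth and base
  width are configuration.
* **Rotations** are restricted to 90° multiples, applied identically to
  frame and mask with no interpolation, so augmented masks remain exact
  label grids and per-class pixel counts are preserved. Free-angle rotation
  would require label resampling and is not needed on rotation-symmetric
  anatomy.
* **Epoch budget and early stopping** (patience on validation loss, best
  weights checkpointed) are explicit `train_config` fields. The scaled
  study runs in this package use 6 epochs, past the point where the
  validation loss of the 64-px phantom task flattens.
* **Class weighting** is off by default, matching the plain
  cross-entropy recipe, but a per-class weight vector exists in
  `train_config` because pixel imbalance (tiny strut blobs against a
  dominant background) is the known failure mode of the stent class.

The convolutions, pooling, upsampling, dropout, softmax cross-entropy and
the full backward pass are implemented natively in C++ (RcppArmadillo) via
im2col matrix multiplication; Adam runs in R over the flat parameter list.
The analytic gradients are verified against central finite differences in
the test suite. One numerical subtlety: with zero-initialized biases a dead
ReLU channel can place pre-activations exactly on the kink, where a central
difference legitimately disagrees with the subgradient convention
relu′(0) = 0; the gradient test jitters parameters off that set. Dropout
uses a dedicated xorshift stream seeded per gradient call from R's RNG, so
training is bit-reproducible under `set.seed()`.

## Splitting

`make_split` holds out whole patients for the test set — never frames —
and then draws `round(0.2 · n_train)` validation frames from the training
patients only. With correlated pullback frames, a frame-level test split
would overestimate generalization; the held-out-patient design is the
honest one and is what the scaled learning check uses.

## Clinical quantities from a mask

* **Lumen area** is the lumen pixel count times spacing²; the narrowed
  flag is strict (`area < 4.0`), so exactly 4.00 mm² is not narrowed.
* **Calcification arc** bins the angles of calcification pixels about the
  lumen centroid into 1° bins; the arc is the number of occupied bins, so
  disjoint deposits sum their occupied angle rather than spanning a convex
  hull. Quadrants are the four fixed 90° sectors from the image +x axis;
  severe means more than two occupied quadrants. Quadrant anchoring is a
  modeling choice — an alternative arc>180° rule sits behind
  `rule = "arc180"`. If calcification exists with no lumen the function
  raises a reference error; `center_fallback = TRUE` substitutes the image
  center. The 1°-bin definition needs adequate sampling: a band at radius
  r px crosses ~r·π/180 px of arc per bin, so bins can only go empty when
  the band sits closer than ~25 px to the centroid; recovery checks
  therefore measure at ≥ 30 px.
* **Struts** are 8-connected components of the stent class with at least
  3 pixels (suppressing single-pixel noise), reported by centroid.
* **Strut recall** matches predicted to true centroids one-to-one within a
  5-px tolerance and divides by the number of true struts. The matching is
  the maximum-cardinality assignment (exact bitmask dynamic program up to
  14 struts on the smaller side, greedy beyond), with ties broken by total
  distance; a greedy nearest-pair rule can strand matchable pairs, and an
  exhaustive-assignment oracle in the tests pins the exact semantics.
  Frames with no true struts score 1 by convention and are excluded from
  stent-frame aggregates.

## Evaluation

Per-class pixel confusion counts are one-vs-rest; IoU = TP/(TP+FP+FN),
Dice = 2TP/(2TP+FP+FN), with a class absent from both masks scoring 1 and
classes absent from every truth mask excluded from means. Because a mean
IoU depends strongly on how per-class values are aggregated, the report
always carries an explicit mode tag and both modes are available: `pooled`
(confusion counts summed over frames first) and `macro_per_image`
(per-frame per-class scores averaged over the frames whose truth contains
the class). The two modes genuinely differ whenever class sizes vary across
frames, and published mean IoUs often cannot be reproduced without knowing
which was used; this package refuses to leave that ambiguous.

Image-level classification (narrowed lumen; severe calcification) applies
the same mask-to-flag rule to truth and prediction and reports
accuracy/recall/precision from the frame-level 2×2 table, with recall and
precision defined as 1 on an empty denominator. Lumen-area agreement uses
Spearman's rank correlation (exact null distribution for n ≤ 10 without
ties, t-approximation beyond) plus the squared Pearson correlation as R².

## Problem sizes and reproducibility

The package's own study conditions are desk-scale: 20 patients × 30 frames
at 64×64 px for learning checks (2 held-out patients, two seeds), 200
phantoms at 256 px for geometry recovery, 100 random mask pairs for the
metric oracle. A single global seed fans out to per-stage seeds (hash of
stage name and seed), each stage writes a manifest with the configuration
hash, and identical configuration plus seed reproduces every artifact
bit-for-bit. On these phantoms the scaled U-Net separates lumen and
media+plaque cleanly while the stent class — thin, rare, and visually
similar to calcification — lags far behind, the same ordering reported for
clinical IVUS segmentation.

## Known limitations

Phantom realism is schematic by design; no GPU path exists (the native
implementation targets correctness and desk-scale sizes, roughly 0.1 s per
64-px training step on one core); free-angle augmentation, alternative
architectures, and stent-expansion indices are out of scope. The simulator
emits single-vessel cross-sections only.
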