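---
title: "Label-free virtual staining of plant cells: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free virtual staining of plant cells: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative plant cell biology leans on fluorescence microscopy —
membrane dyes to segment cells, organelle markers to track motion,
viability stains to count dead cells — yet fluorescence imaging brings
phototoxicity, photobleaching and dye-invasion artifacts, particularly
during time-lapse work. *Virtual staining* sidesteps this: a
convolutional network is trained on paired bright-field/fluorescence
images and then predicts the fluorescence channel from bright-field
alone, so the downstream quantification (segmentation, morphometrics,
tracking, classification) runs label-free.

**vstain** implements this workflow end to end in R, together with a
seeded synthetic microscopy-scene generator that provides exact ground
truth, so that every stage — network, colocalization score,
morphometrics, tracking and texture classification — can be validated
without external data.

## The regression network

The staining model is a UNet whose convolution blocks are replaced by
residual channel attention (RCA) blocks. One block computes

    x -> conv3x3 -> ReLU -> conv3x3 -> channel-attention gate -> (+ x)

where the gate pools each channel to its spatial mean, passes the
pooled vector through a bottleneck of width `C / r` (ReLU) and a
sigmoid, and rescales each channel by the result; the block input is
added back (through a 1x1 projection when the channel counts differ).
The encoder has `depth` levels (block, then 2x2 max pooling, channels
doubling per level), a bottleneck block, and a symmetric decoder with
nearest-neighbour upsampling and skip concatenation, closed by a linear
1x1 single-channel head. The head is zero-initialized so an untrained
model predicts a flat zero image and the first gradient steps are well
scaled.

Training minimizes mean squared error (mean absolute error selectable)
with Adam at `1e-3` and no schedule — a deliberate, documented choice:
virtual-staining studies of this kind often train inside commercial
tools whose exact hyperparameters are not public, so this package uses
the standard image-regression recipe and documents it fully. Patches are sampled
uniformly at random each epoch with optional 8-fold dihedral
augmentation. Inputs and targets are normalized to the pooled 1–99
intensity percentiles of the training set; the bounds travel with the
model and are reapplied at prediction time. Predictions are reported in
normalized target units: every consumer in this package (rank-based
colocalization, watershed segmentation, min–max-quantized texture
features) is invariant to the absolute intensity scale.

### Tiled inference and the attention gates

The channel-attention gates are *global* statistics, so naive tiled
prediction would make the output depend on the tiling. `predict_stain()`
instead resolves the gates sequentially: for each attention layer, all
tiles are run with the earlier gates fixed, the layer's pre-gate
features are pooled over each tile's owned (partition) region, and the
gate is computed once from the combined global mean. A final pass
stitches the owned regions. With tile overlap exceeding the receptive
field, tiled and whole-image predictions agree to floating-point
rounding — the consistency is by construction, not by feathered
approximation.

### Determinism

All randomness (weight init, patch sampling, augmentation) derives from
the model seed through a save/restore RNG wrapper; no function touches
the global RNG state. Under the single-threaded BLAS this package is
developed against, training and prediction are bit-reproducible. A
multi-threaded BLAS may reorder reductions and introduce float-level
jitter; that is the only residual nondeterminism.

## Threshold overlap score

Colocalization between a prediction and a reference channel is scored
by the threshold overlap score (TOS) at the top intensity percentile
(default t = 1). Selection is *rank-exact*: exactly `ceiling(t/100 * N)`
pixels are selected, ties broken by intensity then row-major index —
so the score is invariant under monotone intensity transforms, which
matters because virtual stains live in arbitrary units. With selected
counts `n1`, `n2`, co-selection `n12`, expected overlap `E = n1 n2 / N`,
maximum `M = min(n1, n2)` and minimum `m = max(0, n1 + n2 - N)`, the
log-rescaled score is

    ln(n12 / E) / ln(M / E)            if n12 >= E
    ln(max(n12, 1/2) / E) / ln(E / max(m, 1/2))   otherwise

clipped to [-1, 1]: -1 at complete anticolocalization, 0 at
independence, +1 at complete colocalization, with a half-pixel floor
keeping the score defined when the minimum overlap is zero.

One property worth knowing: the independence null is exactly 0 only
asymptotically. When the expected overlap `E` is small (a 200x200 image
at t = 1 gives E = 4 px), the anticolocalization branch is normalized
by the much smaller log-range `ln(E/0.5)` than the colocalization
branch's `ln(M/E)`, so downward fluctuations of `n12` weigh more and
the mean over independent noise pairs is biased negative (about -0.11
at that size; about -0.013 at 384x384 where E is 15; negligible by
E of 25 or so). The package computes the score exactly as defined and
reports whatever the data give; analyses that want a near-zero
independence reference should use images (or percentiles) with E of
roughly 15 or more.

## Segmentation and morphometrics

Bright structures are binarized with Otsu's method (256-bin histogram,
exact maximization of between-class variance, ties to the lowest cut).
Membrane-stain images are segmented with a tolerance watershed:
optionally a morphological gradient first (for step-edge images), then
flooding of the inverted intensity with catchment basins merged when
their dynamic falls below `tolerance` — the h-extrema rule. The
tolerance is a free parameter by design, conventionally adjusted per
image set; on a [0,1] prediction scale the pipeline default is 0.2
(13100 in 16-bit units, inside the 1200–14,000 range such tools are
tuned over for membrane images). The output labels partition the image;
`gradient_radius_px = 0` is the right setting for fluorescence
membranes, where the stain itself is the ridge.

Per-cell metrics follow fixed raster conventions, validated against
closed forms:

* **Area** `S` is pixel count times squared pixel size.
* **Perimeter** `L` is the length of the marching-squares contour of
  the label mask (pixel centres at integer coordinates, 0.5 iso-level)
  smoothed with a 3-point circular moving average. The smoothing
  removes the raster staircase: a digitized disk of radius 100 px
  measures circularity `4*pi*S/L^2 = 0.979`, a square measures
  `pi/4 + 0.019`, against raw-contour values of 0.894 and 0.795.
* **Solidity** is the contour-polygon area over its convex hull area,
  computed on a 7-point-smoothed copy of the same contour. Using one
  polygon for both numerator and denominator makes convex rasters
  measure exactly 1 (an axis-aligned rectangle gives 1.0, a disk
  0.999); the stronger smoothing is needed because the residual zigzag
  of the 3-point contour reads as ~2% spurious concavity on oblique
  edges — a pure measurement artifact the area *ratio* should not see.
* **Aspect ratio** is the fitted-ellipse definition: the square-rooted
  eigenvalue ratio of the second central moments (with the 1/12 pixel
  correction), not a bounding-box ratio.
* Coordinates put pixel centres at integer positions, origin top-left,
  x along columns; outputs are in micrometres.

Agreement between two measurement sources is the ordinary
least-squares coefficient of determination over cells matched by
mutual best overlap.

## Tracking

Objects are detected per frame by Otsu binarization, 8-connected
labeling (with a minimum area), and intensity-weighted centroids.
Frame-to-frame linking is greedy in ascending distance with a hard
gate (`max_disp_px`, default 15): pairs are accepted closest-first,
each end at most once; unmatched detections open tracks, unmatched
tracks close. Hungarian assignment would slot behind the same
interface, but at chloroplast densities the greedy rule is already
exact whenever spacing exceeds twice the per-frame displacement (a
property the tests check exhaustively). Speeds are Euclidean centroid
displacements converted through the pixel size and the frame interval
(0.28 um/px and 0.5 s in the chloroplast experiments), in um/s.
Single-point track stubs carry no speeds and drop out of statistics.

## Texture classification

Live/dead classification uses gray-level co-occurrence matrices —
per-crop min–max quantization to 64 levels (a 1–99-percentile variant
is available), distance 1, angles 0/45/90/135 degrees, symmetrized and
normalized — and the 13 classical Haralick statistics averaged over
angles. The classifier is a random forest with the randomForest
package's documented defaults (500 trees, sqrt(p) candidate features
per split, unlimited depth). Evaluation keeps the train/test split
fixed and re-seeds only the forest, once per seed, reporting per-seed
accuracies, their mean and SD, and the first seed's confusion matrix.
Re-seeding only the forest (rather than re-splitting the data) isolates
the classifier's own variance, which is what a multi-seed accuracy
summary is meant to measure. Crops are analyzed unmasked, matching a
manual-cropping workflow.

## The synthetic-scene generator

The generator is the package's stand-in for raw microscopy and defines
the study conditions; all of its randomness is seeded per call.

* **Pavement fields** are lobed Voronoi tessellations: pixels join the
  seed minimising distance plus a per-seed sinusoidal term in polar
  angle, bending walls into puzzle-piece lobes of amplitude
  `lobe_amplitude` px (0 gives convex cells). Seed points keep a
  minimum spacing of `0.62 * sqrt(W*H/n)` so fields have even-sized
  cells, as real epidermis does.
* **Cell files** are rows of abutting superellipses with a
  length-to-width ratio `elongation` (default 2.5), the BY-2-like
  geometry used for the aspect-ratio contrasts.
* **Chloroplast fields** scatter non-overlapping disks whose radii
  follow the ~5 um organelle diameter through the pixel size
  (0.28 um/px gives ~9 px radii).
* **Bright-field rendering**: interior transmittance 0.85 vs 0.92
  background, a thin dark wall line, and a signed
  difference-of-Gaussians halo at `defocus_sigma_px` emulating the
  slightly defocused contrast that makes walls learnable; organelles
  shift transmittance (nuclei darker, vacuoles brighter, chloroplasts
  strongly darker); additive Gaussian read noise, clipped to [0,1].
  The fluorescence channels are *deterministic functions of the scene
  geometry* (membrane: blurred wall indicator, sigma 0.9 px; nucleus:
  soft blobs; vacuole: eroded interiors; chloroplast: shaded disks), so
  a regression model can in principle recover them exactly — the
  generator deliberately omits stochastic staining heterogeneity,
  which no bright-field-conditioned model could predict.
* **Time-lapses** move chloroplasts by a correlated random walk
  (persistence-mixed directions, truncated-normal speeds) with
  reflecting walls and excluded-volume collisions (blocked steps
  reverse; doubly blocked steps stall at zero displacement). Truth
  speeds are recorded from the *realised* displacements, so they are
  exact by construction at any parameter setting.
* **Viability crops** share one wall geometry across classes — death
  does not remove the wall. Living cells contain a nucleus,
  transvacuolar strands and granules (coherent internal bright-field
  contours); their membrane channel is a smooth ring lining the wall.
  Dead cells have a retracted, wavy protoplast whose membrane channel
  is a filled collapse mass with speckled debris; in bright-field the
  retraction is a faint coherent contour plus slightly stronger
  speckle. Per-crop acquisition nuisances (focus blur 0–0.8 px,
  background debris blobs, read-noise level 0.4–1.3x nominal) emulate
  real acquisition variability. This construction gives the texture
  classifier a genuinely hard bright-field problem — co-occurrence
  statistics cannot parse *which kind* of internal contour they see —
  while the staining network, which can, produces images whose texture
  separates the classes; that asymmetry, not any intensity shortcut,
  is what the classification experiment measures.

What passing tests on these scenes do **not** show: robustness to
optical physics the generator omits (phase effects, shading, uneven
illumination at field scale, 3-D defocus), to real staining
heterogeneity, or to morphologies outside the implemented shape
models. The generator validates the machinery, not the biology.

## Experiment scales

The figure-analog experiments default to desk scale, chosen once:

* Staining/colocalization: 200 training and 20 held-out 64x64 pavement
  scenes (~4 cells each), depth-2 RCA-UNet with 8 base channels,
  attention reduction 4, 10 epochs, batch 8.
* Morphometrics: 20 scenes of 192x192 px with 12 cells (~31 um cells
  at 0.56 um/px — comparable relative resolution to real fields; cells
  much smaller than ~25 um would be dominated by raster error), lobe
  amplitudes cycling 0/4/8 px, watershed tolerance 0.2.
* Tracking: 30 chloroplasts on 320x320 px at 0.28 um/px, 10 frames at
  0.5 s, speeds 2 +/- 0.5 um/s, persistence 0.8; the staining model
  trains on 120 two-chloroplast scenes for 14 epochs.
* Classification: the full-scale defaults use 1200 crops per class
  with a 900 train / 300 test split and ten forest seeds — the standard
  scale for this assay; the acceptance tests run a 400/300 reduction.
  The staining model trains on 200 crop pairs for 24 epochs (batch 4);
  a 64 px crop carries roughly 1/250 the pixels of a full micrograph,
  so a corpus of a few hundred crops matches the information content of
  the ~150 full-size training pairs such models are typically given.

## Known limitations

* 2-D only; no 3-D reconstruction or z-aware staining.
* The pure-R network engine is sized for desk-scale experiments, not
  GPU-scale corpora.
* The TOS independence null is negatively biased at small expected
  overlap (see above); this is a property of the statistic, reported
  as computed.
* Watershed tolerance remains a per-dataset calibration, exactly as in
  the interactive tools this pipeline mirrors.
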