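# vstain — label-free virtual staining and quantification for plant cell microscopy

Fluorescence labels make plant cells measurable — membrane dyes outline
cells for morphometrics, chlorophyll autofluorescence tracks chloroplast
movement, viability stains separate living from dead cells — but they
bring phototoxicity, bleaching and dye artifacts, especially in
time-lapse work. **vstain** implements the label-free alternative in R:
an image-to-image regression network (a UNet built from residual channel
attention blocks, "RCA-UNet") is trained on paired bright-field /
fluorescence images and then predicts synthetic fluorescence from
bright-field alone, feeding the same quantification a real stain would:

* **Colocalization** — threshold overlap score (TOS) at the top
  intensity percentile with logarithmic rescaling: −1 complete
  anticolocalization, 0 independence, +1 complete colocalization.
  Selection is rank-exact, so the score ignores intensity units.
* **Morphometrics** — Otsu thresholding, tolerance-based (h-extrema)
  watershed of membrane stains, and per-cell area *S*, perimeter *L*,
  circularity 4π*S*/*L*², solidity (area over convex-hull area) and
  fitted-ellipse aspect ratio, with R² agreement reports.
* **Motion** — per-frame centroid extraction, gated nearest-neighbour
  linking, per-interval speeds in µm/s (e.g. 0.28 µm/px at 0.5 s
  frame intervals for chloroplast work).
* **Viability** — gray-level co-occurrence (Haralick) texture features
  and a random-forest live/dead classifier evaluated over multiple
  seeds with confusion matrices.

Everything runs against a seeded synthetic microscopy-scene generator
(pavement-cell fields, BY-2-like cell files, chloroplast fields,
live/dead crops) that provides exact ground truth, so the whole
pipeline is testable end to end without external data. For the model,
conventions and design rationale see the methods vignette in
`vignettes/virtual-staining-methods.Rmd`.

## Worked example

Train a membrane-staining model on synthetic pavement scenes, stain a
held-out field, and measure the cells label-free:

```r
library(vstain)

t1 <- run_stain_specificity(seed = 1)   # trains membrane + nucleus models
round(t1$tos, 3)
#>          membrane nucleus vacuole
#> membrane    0.702  -1.000      -1
#> nucleus    -1.000   0.898      -1
t1$untrained_tos
#> [1] -0.571
```

The TOS cross-matrix reads like a staining-specificity panel: each
model colocalizes with its own target structure (diagonal, 0.70 and
0.90) and not with the others (off-diagonal, −1), and training lifts
the membrane model far above its untrained baseline (−0.57).

```r
morph <- run_morph_analog(t1$models$membrane, seed = 1)
round(morph$r_squared, 3)
#>    area_um2 circularity    solidity
#>       0.997       0.955       0.964
```

Cells segmented from the *virtual* membrane stain by tolerance
watershed agree with the ground-truth masks at R² ≥ 0.95 for area,
circularity and solidity — the morphometrics no longer need the dye.

```r
motion <- run_motion_analog(seed = 1)      # chloroplast time-lapse
round(motion$r_squared, 3)
#> [1] 0.998
```

Speeds recovered by centroid tracking match the generator's true
speeds almost perfectly; with tracking run on virtually stained frames
instead of the autofluorescence channel the agreement stays above 0.95.

```r
via <- run_viability_analog(seed = 1, n_per_class = 400,
                            n_train_per_class = 300, seeds = 1:10)
c(brightfield = via$eval_bf$mean, virtual = via$eval_vs$mean)
#> brightfield     virtual
#>       0.771       0.915
```

The same Haralick-feature random forest classifies live/dead cells
substantially better on the virtual stain than on raw bright-field —
the virtual stain normalizes acquisition nuisances away and renders
the collapse of dead protoplasts as explicit texture.

The numbered scripts under `analysis/` run these experiments at full
scale and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_scenes.R --seed 1
Rscript analysis/02_train_virtual_stains.R --seed 1
Rscript analysis/03_morphometric_agreement.R --seed 1
Rscript analysis/04_chloroplast_speeds.R --seed 1 --with-model
Rscript analysis/05_viability_classification.R --seed 1
```

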