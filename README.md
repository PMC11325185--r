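# quadmosaic

Enhancement and cell detection for **non-confocal quadrant-detection AOSLO**
images of the photoreceptor mosaic.

Split-detection adaptive optics scanning light ophthalmoscopy resolves
photoreceptor inner segments by dividing multiply-scattered light between
two off-axis detectors and forming the normalised difference
`S = (A − B)/(A + B)` per pixel. Its contrast is directional — every cell
appears as opposed bright and dark semicircles — and sits on a
low-spatial-frequency background scattered back by the retinal pigment
epithelium, which together make both manual and automated cell counting
hard. Quadrant detection collects the same light on four detectors, so the
split can be formed along four axes (0°, 45°, 90°, 135°).

`quadmosaic` implements the enhancement chain that fuses the four
directional images into one with non-directional cell-border contrast:

```
Q1..Q4  ──balance means──▶  S₀, S₄₅, S₉₀, S₁₃₅        (difference over sum)
        ──emboss ⟂ axis──▶  E₀, E₄₅, E₉₀, E₁₃₅        (h = 5 px, 150%)
        ──per-pixel min──▶  MinIP image               (dark cells, flat bg)
        ──blur/threshold/watershed──▶ cell centroids
        ──match vs manual──▶ FN / FP / merged rates
```

with the emboss filter defined as
`E(x,y) = clip₀²⁵⁵(128 + (amount/100)·(I(x,y) − I(x+Δx, y+Δy)))`,
`(Δx, Δy) = (round(h·cosθ), round(−h·sinθ))`, replicate padding.

It also ships a synthetic quadrant-image generator (hemispherical-cap cell
shading, shared low-frequency background, per-channel noise, ground-truth
centroids) so that every stage — and the full pipeline — is testable
without patient data.

## Worked example

```r
library(quadmosaic)

sim   <- generate_mosaic(mosaic_spec(seed = 1))   # 126 cells + ground truth
enh   <- enhance_quadrants(sim$qset)              # splits -> emboss -> MinIP
cents <- detect_cells(enh)                        # blur/threshold/watershed
m     <- match_centroids(cents, sim$truth, radius = 3)
print(m)
```

```
Warning: histogram is not bimodal; falling back to Otsu's threshold
<match_result: 126 manual / 126 auto, TP 126, FN 0 (0.0%), FP 0 (0.0%), merged 0, radius 3.00 px>
```

All 126 simulated cells are recovered within 3 px, with no spurious
detections and no two cells merged into one; the warning is expected on
this synthetic world (its MinIP histogram has no two-peak trough, so the
threshold falls back to Otsu — see the methods vignette). `fn_rate` /
`fp_rate` are percentages of the manual total, the quantities a grading
study reports.

A command-line interface wraps the same stages
(`simulate | split | enhance | detect | evaluate | pipeline`):

```sh
Rscript inst/cli/quadmosaic.R simulate --out-dir fix --seed 3
Rscript inst/cli/quadmosaic.R enhance  --q1 fix/q1.tif --q2 fix/q2.tif \
        --q3 fix/q3.tif --q4 fix/q4.tif --out minip.tif
Rscript inst/cli/quadmosaic.R detect   --in minip.tif --out auto.csv
Rscript inst/cli/quadmosaic.R evaluate --auto auto.csv --manual fix/truth.csv \
        --radius 3 --out report.json
```

## Layout

- `R/` — image I/O (grayscale PNG/TIFF codecs, centroid CSV), quadrant
  combination, emboss + MinIP enhancement, detection, evaluation,
  synthetic generator, pipeline orchestration
- `src/` — Rcpp primitives: CRC-32, connected components, exact Euclidean
  distance transform, regional maxima, priority-flood watershed
- `tests/testthat/` — unit and property tests per module plus
  `test-acceptance.R` (the acceptance criteria, one test per criterion)
- `vignettes/quadrant-detection-methods.Rmd` — models, parameter choices,
  and what the synthetic world does and does not establish
- `inst/cli/quadmosaic.R` — command-line entry point
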