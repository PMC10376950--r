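# bapair

Automated detection of broncho-arterial (BA) pairs on axial lung CT
slices and measurement of broncho-arterial ratios — the radiological
criterion for bronchiectasis — for researchers and image-analysis
engineers working on paediatric airway disease.

A measurable BA pair is a bronchus cross-section (dark air-filled lumen
inside a brighter wall, the "signet-ring" sign) adjacent to its
accompanying pulmonary artery (a bright, near-circular disk). The package
finds these pairs with a classical image-processing chain and measures,
per pair, four bronchus diameters `BD1..BD4`, four artery diameters
`AD1..AD4`, the areas `BAr`, `AAr` (pixel counts), and the two ratios

    BADR = ABD / AAD      with ABD = mean(BD1..BD4), AAD = mean(AD1..AD4)
    BAAR = BAr / AAr

Diameters are chords through the component centroid at 0/45/90/135
degrees in Euclidean pixels; bronchus diameters are inner (lumen)
diameters.

The per-slice pipeline: lung segmentation (TV denoising, conditional
alpha-beta correction, Otsu, largest contour, inversion + flood fill,
hole filling) → histogram cleaning (zero pixels at or below the PIT, the
highest intensity whose count reaches `NPT = ceil(2·peak/3)`) → artery
screening (balanced histogram threshold, 3×3 opening, four roundness
conditions: `10 ≤ A < 300`, circularity `4πA/P² > 0.3`, rotated
bounding-box ratio `> 0.4`, enclosed-circle ratio `> 0.4`) → host-contour
extraction by pixel overlap with kept arteries → bronchus detection as
hole-fill residues screened with `A > 3`, `Cr > 0.5`, both ratios
`> 0.6` → pairing (nearest overlapping artery) → measurement. A synthetic
phantom generator with ground truth validates every stage without
patient data. See the methods vignette
(`vignettes/ba-pair-pipeline.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

Generate a noise-free phantom slice with three planted signet-ring pairs,
run the pipeline, and score the detections against the planted truth:

```r
library(bapair)

ph  <- generate_slice(phantom_spec(seed = 7, noise_sigma = 0))
res <- run_pipeline(list(ph$image), out_dir = "demo")
res$table[, c("pair_id", "x", "y", "lung_side", "ABD", "AAD", "BADR", "BAAR")]
#>   pair_id   x   y lung_side   ABD   AAD BADR BAAR
#> 1       1 182 280     right  7.68 13.86 0.55 0.33
#> 2       2 334 282      left  9.74 11.80 0.83 0.67
#> 3       3 336 345      left 12.16 13.86 0.88 0.72

score_detection(ph$truth, res$pairs)[c("recall", "precision", "ratio_MAE")]
#> $recall    [1] 1
#> $precision [1] 1
#> $ratio_MAE [1] 0.01499088
```

All three planted pairs are recovered (the planted radius ratios are
0.571, 0.833 and 0.857; the measured BADRs 0.55, 0.83 and 0.88 agree to
within discretization). `demo/` now holds `pairs.csv`, `summary.csv`, a
per-slice thresholds log, the configuration snapshot, and an overlay PNG
with bronchi in red and arteries in blue.

The measurement arithmetic alone:

```r
compute_ratios(bd = c(4.12, 3.00, 6.01, 6.01),
               ad = c(9.16, 8.17, 10.00, 10.17),
               b_area = 12, a_area = 61)
#> BA measurement: ABD=4.79 AAD=9.38 BADR=0.51  BAr=12.00 AAr=61.00 BAAR=0.20
```

## Command line

```sh
Rscript inst/cli/bapair.R phantom --seed 1 --n-pairs 3 --out phantoms/
Rscript inst/cli/bapair.R run --input phantoms/ --format png --out results/
```

Exit codes: 0 ok, 1 usage error, 2 processing error. "No pairs found" is
a valid empty result, not an error.

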