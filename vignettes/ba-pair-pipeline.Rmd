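---
title: "Detecting broncho-arterial pairs and measuring BA ratios on axial CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting broncho-arterial pairs and measuring BA ratios on axial CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bapair)
```

## The measurement problem

Bronchiectasis is diagnosed radiologically through an increased
broncho-arterial (BA) ratio: the inner diameter of a bronchus divided by
the diameter of the pulmonary artery running beside it. On an axial CT
slice a measurable ("discrete") BA pair looks like a signet ring — a dark,
air-filled bronchial lumen inside a brighter wall, with a bright,
near-circular artery cross-section touching it. Finding these pairs by eye
and measuring them with calipers is slow and observer-dependent; `bapair`
implements an automated pipeline that finds candidate pairs by classical
image processing and measures both a diameter ratio (BADR) and an area
ratio (BAAR) for each.

The package operates on 8-bit grayscale axial slices normalised to
512x512 px (PNG directly, or single-frame uncompressed DICOM via a
windowing step). All thresholds live in one `pipeline_config()` object and
every run can serialise its configuration next to its outputs.

## Pipeline stages and their assumptions

**Lung segmentation** (`segment_lungs()`). Total-variation denoising
(Chambolle's dual algorithm; weight 0.1 on the [0,1] scale, exposed as
`tv_weight`) removes reconstruction noise while keeping the lung/body edge
in place. A conditional affine ("alpha-beta") correction then pulls the
slice mean towards 110 — `alpha = clamp(110/mean, 0.5, 2)`,
`beta = 110 - alpha*mean`, applied only when the mean is more than 15 away
— so that Otsu binarization behaves uniformly across differently exposed
slices. The binarized body is reduced to its largest 8-connected
component, inverted, flood-filled from the image corners to delete the
exterior, and hole-filled so vessels and airway walls remain part of the
lung field. At most the two largest regions are kept (left and right lung;
they may merge near the carina). A slice whose lung area is below 1% of
the image is flagged "no-lung" and skipped. The lung image keeps original
intensities: the mask never alters retained pixels.

**Histogram cleaning** (`clean_image()`). The zero-excluded histogram of
the lung image is dominated by parenchyma. Its peak count is split into
three equal horizontal bands; the number-of-pixels threshold NPT is the
lower limit of the top band, `ceiling(2*peak/3)` (`n_bands` configurable;
three bands is the default because finer splits either barely clean or eat
into vessels). The pixel-intensity threshold PIT is the highest intensity
whose count still reaches the NPT, and every pixel at or below the PIT is
set to zero — the boundary is inclusive by definition of the rule. This
removes parenchyma, lumen interiors and faint speckle in one stroke while
leaving vessels and walls untouched.

**Artery screening** (`detect_potential_arteries()`). A balanced-histogram
threshold isolates the brightest structures of the cleaned slice. The
iteration keeps a moving centre at the midpoint of the remaining intensity
interval and repeatedly removes the outer bin of the heavier side; we use
the symmetric floor-midpoint convention and stop as soon as both sides are
exhausted, which keeps the procedure well defined on spike histograms
(two equal spikes balance exactly halfway between them). The zero bin is
excluded, mirroring the cleaning stage. The binary result is opened with a
3x3 box to drop bright specks, and each 8-connected component is screened
with four roundness conditions:

* area `A` with `10 <= A < 300` px — smaller is noise, larger is not an
  artery cross-section;
* circularity `4*pi*A/P^2 > 0.3`, with `P` the Crofton (Cauchy projection,
  four directions) perimeter estimate;
* minimum-rotated-bounding-box side ratio `W/H > 0.4`;
* enclosed-circle ratio `A / (pi*R^2) > 0.4`, `R` the minimum enclosing
  circle radius.

Components failing any condition form the discarded-bright-object mask and
are erased from the cleaned slice, giving the *updated clean* image.

**Pairing** (`extract_adjacent_objects()`, `detect_potential_bronchi()`,
`extract_ba_pairs()`). The updated clean image is binarized and the
components that share at least one pixel with a kept artery become *host
contours* — adjacency is literal pixel-set intersection, because a
touching artery and bronchial wall merge into one 8-connected component.
Hole filling each host and subtracting the original binary leaves only the
enclosed holes; holes passing the bronchus screen (area > 3 px,
circularity > 0.5, both shape ratios > 0.6) are candidate lumens. Each
lumen is paired with the nearest kept artery overlapping its host (ties to
the smaller label); matches farther than 40 px apart are rejected as
implausible. The pair coordinate is the half-up-rounded midpoint of the
two centroids, and the lung side follows the radiological convention
(image-left is the patient's right lung; `flip_sides` inverts it, since
reported sides in the field are not always consistent). An artery shared
by several lumens yields pairs flagged non-discrete.

**Measurement** (`measure_pair()`). Four diameters are cast through the
component centroid at 0/45/90/135 degrees. Each diameter is the contiguous
run of component pixels containing the centre — a chord, so a C-shaped
artefact cannot inflate it — measured as Euclidean length: a run of `n`
pixels counts `1 + (n-1)*s` px with step `s = 1` on the axes and
`sqrt(2)` on the diagonals (a single pixel measures 1). Bronchus diameters
are inner (lumen) diameters. `BADR = mean(BD1..BD4) / mean(AD1..AD4)` and
`BAAR = BAr / AAr` with areas in pixel counts. Ratios are kept at full
precision; tables print two decimals, half-up by default (`rounding =
"truncate"` reproduces tools that truncate — published tables mix both
conventions on exact ties, and the ratios are insensitive to the choice).
Units are pixels throughout; a pixel-spacing factor can be applied
downstream where physical units are needed.

## Numerical choices

* **Perimeter.** The Crofton four-direction weighted crossing count is
  used because the circularity of rasterized disks then converges
  monotonically to 1 (0.88 at r=5 to 0.99 at r=40). The classic 3x3
  weighted-neighbourhood estimator plateaus near 0.91 and would bias the
  circularity gate. Tiny components can overshoot 1 slightly; a
  single-pixel component is defined as circularity 1.
* **Pixel geometry.** The bounding box and enclosing circle operate on the
  corners of the pixel squares, not the centres: a 1-px-thick line then
  has width 1, an axis-aligned 2x5 rectangle measures exactly 0.4, and a
  rasterized square's enclosed-circle ratio equals the continuum 2/pi
  exactly. The cost is a bias towards 1 for very small objects (a ~10 px
  rotated 2x5 rectangle reads 0.6 rather than 0.4); both screens use the
  ratios only as lower bounds, so the bias never rejects a round object.
* **Connectivity.** 8-connectivity everywhere, with deterministic
  row-major component numbering so all tie-breaks ("smallest label") are
  reproducible.
* **Degenerate inputs.** Blank slices warn and return an empty mask; an
  image with a single nonzero intensity gets threshold `v-1` (everything
  kept); a histogram with no intensity reaching the NPT gets PIT 0 and
  cleaning is a no-op; "no pairs found" is a valid, empty result, never an
  error.
* **Determinism.** Slices are processed independently with no shared
  state; identical input and configuration give byte-identical tables and
  overlays. The phantom generator runs on a private RNG stream derived
  from its seed and restores the caller's RNG state.

## The phantom: what it emulates and what it does not

`generate_slice(phantom_spec(...))` builds a 512x512 slice with a body
ellipse (intensity 170) on a dark background, two dark lung ellipses (35),
and, inside the lungs: artery disks (225) planted tangent to signet-ring
bronchi (wall around a lumen at parenchyma intensity), elongated bright
bars standing in for in-plane vessels, lone rings with no artery, faint
speckle just above parenchyma, and optional Gaussian noise. Radii default
to lumen 3–6 px and artery 5–9 px with a 3 px wall — the size regime the
screening gates target — and every object is recorded with its true
geometry, so `score_detection()` can compute recall, precision and the
error of the recovered ratio against `true_BADR = r_lumen/r_artery`.

The wall intensity defaults to 100, deliberately *between* the cleaning
threshold (just above parenchyma) and the balanced-histogram threshold
(which lands between wall and vessel intensity). This reproduces the
appearance the method relies on: walls survive cleaning and enclose their
lumens, but only arteries count as "bright". Planting walls at
near-vessel intensity instead makes the artery screen classify the rings
as non-round bright objects and erase them — with bright walls the
pipeline destroys every bronchus before hole-filling, on phantoms and by
extension on any data where walls rival vessels in brightness. That is a
real sensitivity of the method, not of the phantom.

Known gaps between phantom and patient data: perfect ellipses instead of
anatomy, no airway tree or vessel branching, no partial-volume blur at
object boundaries, no slice-to-slice continuity, no scanner artefacts.
Passing the phantom suite therefore demonstrates that the implementation
realises the method faithfully and recovers known geometry under the
method's stated assumptions — not that the method succeeds on arbitrary
clinical scans. With additive noise at sigma 6 the upper tail of the
parenchyma distribution survives the PIT cleaning, drags the balanced
threshold down into the tissue cluster and degrades recall markedly; the
validation suite therefore runs the noise-free regime, and the noise knob
remains available for robustness experiments.

## Problem sizes used in validation

The test suite exercises single synthetic slices (512x512) per stage, the
exhaustive geometry oracles on components up to 30 px (100 random cases),
100 random histograms against a step-by-step balanced-threshold reference,
and an end-to-end run over 20 phantom seeds with 3 planted pairs each,
scoring pooled recall (>= 0.9 expected, 1.0 observed), pooled precision
(>= 0.8 expected, 1.0 observed) and per-pair ratio error (<= 0.1).

## Known limitations

* Bronchi are found only as holes of artery-adjacent components: a
  bronchus whose wall is broken (open ring) or whose artery does not touch
  its wall is missed — consistent with the method's restriction to
  discrete, signet-ring pairs; elongated (in-plane) pairs are out of scope.
* The DICOM reader is intentionally minimal: single-frame, uncompressed
  little-endian CT only.
* All measurements are in pixels; comparisons across scans with different
  reconstruction fields of view need an external spacing correction.
* The four-diameter chords are axis-fixed (0/45/90/135 degrees), not
  aligned to the object's principal axes.
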