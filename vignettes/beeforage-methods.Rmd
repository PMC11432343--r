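---
title: "Methods: from tiled video detections to foraging statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tiled video detections to foraging statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeforage)
```

## What this package computes

`beeforage` turns per-frame bumblebee detections from fixed overhead video
of a flowering patch into three behavioural statistics, per video:

* **patch attractiveness** $A = \sum_t c_t / T$ — total detections over
  total frames $T$, bee-free frames included; a per-frame mean visitation
  intensity;
* **cover-standardised carrying capacity**
  $K = \left(\sum_t c_t \,/\, \#\{t : c_t > 0\}\right) / C$ — the mean
  simultaneous bee count conditioned on presence, divided by the percent
  flower cover $C$ of the quadrat;
* **on-flower time proportion** — the share of cumulative bumblebee-time
  (detection × frame units) in which the detected bee sat on an
  inflorescence rather than travelling between them.

Upstream of these sit deterministic geometry and image operations
(calibration, tiling, duplicate merging, quadrat clipping, colour-band
segmentation), and downstream sits a model-selection ladder for inference
on the per-video table. All of it is testable without field video through
the synthetic-scene generator.

## Geometry conventions

Pixel coordinates are 0-based and every rectangle is half-open,
$[x_1, x_2) \times [y_1, y_2)$. This makes areas, membership tests and the
tiling arithmetic exact: a centroid exactly on a quadrat's right or bottom
edge is *outside*, on the left or top edge *inside*. The physical scale
`mm_per_px` comes from a millimetre ruler photographed in the scene
(`calibrate_scale()`) and is assumed isotropic, since a single pixel length
is calibrated.

Tiled inference pads the frame to the next multiple of the tile side
(640 px by default) before cutting; padding is added on the right and
bottom only (a 5120 × 2880 frame becomes 5120 × 3200, i.e. 8 × 5 = 40
tiles), matching how the detector's pre-processing expands the height.
`tile_box_to_frame()` / `frame_box_to_tile()` are exact inverses for boxes
inside one tile.

The analysis quadrat is a physical 60 × 60 cm square whose upper-left
corner is identified once per video; the pixel side is
`round(600 / mm_per_px)`, so the reconstructed physical side is within one
pixel-equivalent of 600 mm.

## Detection post-processing

Raw detector output is filtered twice:

1. **Confidence**, inclusive at the threshold. The shipped per-species
   defaults are 0.7 for red clover and 0.8 for trefoil and knotweed
   (`species_conf_thresholds()`); "at least" is the natural reading of a
   stated cut-off and is pinned down by a boundary test.
2. **Duplicate merging.** A bee straddling a tile seam is detected once
   per tile. Boxes are linked when their centroid-to-centroid Euclidean
   distance is at most half an average bumblebee body — 15 mm, converted
   per video with `merge_distance_px()`. "Distance between boxes" is taken
   centroid-to-centroid, consistent with the centroid-based quadrat rule.
   Linking is closed transitively (connected components), because pairwise
   merging alone would depend on input order; each component becomes one
   box (union hull, maximum member confidence — the strongest evidence for
   the object survives). Merging is applied globally within a frame, not
   only across seams: the distance scale is the same and the global rule
   needs no knowledge of the tile layout.

Detections are then kept iff their centroid lies in the quadrat; boxes are
never cropped. Evaluation against manual annotations uses greedy
one-to-one matching by ascending centroid distance (match radius defaults
to the merge distance — the manual-vs-predicted matching rule is otherwise
unspecified) and the standard
$F_1 = 2TP/(2TP + FP + FN)$, with $F_1 = 1$ when both sets are empty: no
errors are present.

## Colour model

All channels live on a 0–255 scale with hue period 256, the ImageJ HSB
convention in which the species thresholds were determined; conversion
from RGB happens only at the raster-reading boundary (`rgb_to_hsv255()`).
A band test is inclusive at both bounds. Two of the shipped bands
(knotweed, clover) have a saturation channel whose printed lower bound
exceeds its upper bound; such channels are treated as **inverted**
pass-bands — a value passes iff it is ≥ lower *or* ≤ upper — mirroring
ImageJ's threshold inversion. This semantics is an interpretation of the
printed triplets, configurable per channel in `colour_band()`, not a claim
about the original analysis code.

**Flower cover** is the fraction of quadrat pixels passing the band in one
random frame per video (seed-controlled); one frame suffices because the
patch, unlike the bees, is static at the five-minute scale.

The **optimal flower colour** (OFC) is the channel-wise median of all
in-band pixel colours pooled over ten random frames. "Median of the colour
masks" is ambiguous; reading it as the median pooled masked colour yields
a colour, which is what a reference point must be. The hue median is the
plain (non-circular) median: every shipped band's pass range is contiguous
on the hue circle without straddling the wrap, so pooled in-band hues are
totally ordered and the plain median is well defined. A band crossing the
wrap would need a circular median; the package would surface this as an
OFC outside its own band.

**Heatmaps** average the circular-hue Euclidean distance
$d = \sqrt{\min(|\Delta h|, 256 - |\Delta h|)^2 + \Delta s^2 + \Delta v^2}$
from each pixel to the OFC over a sample of frames (3000 by default),
excluding at each frame the pixels under that frame's bounding boxes so
the bees themselves never contaminate the vegetation map. A pixel covered
in every sampled frame has no valid observation and is reported as
undefined (`NA`), never as zero distance. Deviation histograms sample up
to 100,000 defined pixels without replacement — all of them when fewer are
available — either from the whole map or from pixels that ever lay under a
box.

## On-flower classification and the time budget

A bee hides the vegetation beneath it, so its box region is inspected in a
*reference* frame in which the region is bee-free: the nearest frame in
time with no intersecting detection, preferring the earlier frame on ties;
the search window defaults to the whole video. The bee is called on-flower
when the in-band pixel fraction of the region **reaches 20 %**
(inclusive — the boundary test pins 0.200 to `TRUE` and 0.199 to
`FALSE`). Calls with no valid reference frame are excluded from the
proportions rather than imputed, and their count is carried in the QC
output; imputation would bias the budget toward whichever class happens to
be crowded.

Carrying capacity divides by cover **as a percentage** (0–100), matching
how cover is reported; the unit matters and is fixed here so results are
comparable across videos.

## The model-selection ladder

Per-video metrics are analysed with a fixed, deterministic ladder
(`fit_ladder()`):

1. fit the simple linear model and, if random terms are supplied, the
   mixed model with the same fixed effects and random intercepts (wind
   strength class, temperature);
2. keep the mixed model iff its AIC is lower **and** the fit is not
   singular; both models are fitted by maximum likelihood
   (`REML = FALSE`) so their AICs are commensurable;
3. test the selected model's residuals for normality (Shapiro–Wilk) and
   heteroscedasticity (Goldfeld–Quandt, two-sided F on the
   half-split refits), both at $\alpha = 0.05$ — the level is a package
   choice, the tests are not;
4. if heteroscedastic (simple-model route), report HC3 sandwich standard
   errors.

The Goldfeld–Quandt test and the HC covariances are implemented in-package
(they are a few lines of well-defined linear algebra) and verified against
the textbook formulas in the test suite. Mixed-model p-values use the
normal approximation on the t ratio; no Satterthwaite machinery is
assumed, and the approximation is documented rather than hidden.

Response transformations (square root, cube root, arbitrary power with
exact inverse) are available per analysis question. One published summary
labels the simultaneous-count response with the power −3 while the
accompanying text speaks of cube-root transformation; both are provided
and the default is whichever the analyst states — the discrepancy is
surfaced, not silently resolved.

## The synthetic world

The generator states one world and keeps it fixed:

* frames default to the recording geometry (5120 × 2880 px, 30 fps) but
  tests use 200 × 200 px frames with a 180-px quadrat
  (`mm_per_px = 10/3`) purely for speed — the arithmetic is
  scale-invariant;
* flowers are non-overlapping disks, coloured strictly inside the target
  band over an out-of-band background; the declared cover is the exact
  painted in-quadrat pixel fraction, so segmentation must recover it to
  the rasterisation pixel;
* bees are dark ellipses of 30 mm body length (the merge distance is half
  of that); per-frame counts are i.i.d. Poisson with stated mean λ
  (0.4–0.5 in the tests, the order of magnitude of the observed mean
  visitation); each bee is on a flower with stated probability `p_on`,
  its box fully inside a disk when on and clear of all disks when off, so
  ground-truth labels are unambiguous;
* tile-seam artefacts are emulated by injecting a duplicate box per bee
  with stated probability, offset by less than half the merge distance;
  distinct bees are kept ≥ 2.5 merge distances apart so only injected
  duplicates merge.

What the generator does **not** emulate: wind-blown plant motion, shadows
and illumination drift, partial occlusion, detector localisation noise,
and temporally correlated stays. A green synthetic test therefore
establishes the correctness of the arithmetic and the recovery of stated
parameters under clean conditions — not field robustness of the upstream
detector, which is out of scope here.

## Numerical choices and degenerate inputs

* All sampling takes an explicit seed, recorded in the returned objects.
* Empty detection sets are legal everywhere and propagate zeros; an
  all-zero count vector yields attractiveness 0, undefined (NA, not 0)
  carrying capacity and mean simultaneity.
* `merge_boxes` output is sorted by box coordinates, making it
  permutation-invariant as tested.
* Rectangle rasterisation (`rect_to_idx`) floors the near corner and
  ceilings the far corner, so fractional boxes cover every touched pixel.

## Known limitations

* No binary raster readers are assumed: frame files are plain-text PPM, or
  frames are supplied as in-memory arrays / accessor functions. PNG/JPEG
  decoding belongs to an upstream step.
* The quadrat is assumed axis-aligned in the image; a rotated physical
  quadrat would need a perspective step that is out of scope.
* Per-individual handling durations require tracking identities across
  frames, which per-frame counting deliberately avoids.
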