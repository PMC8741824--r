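---
title: "Colour-based fallow weed detection: methods and design"
author: "spotweed authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour-based fallow weed detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotweed)
```

## The problem

During a fallow phase every growing plant is a weed, so weed detection
reduces to separating green vegetation from a soil-and-stubble background.
That makes simple colour algorithms viable on low-cost embedded hardware,
where they drive site-specific weed control: each detection is mapped to a
lateral strip of the camera's on-ground field of view and fires a relay
(solenoid, sprayer section) for a fixed duration. This package implements
that whole stack — detection, actuation mapping, evaluation, and a
synthetic-scene generator that makes the stack testable without field
video.

## The four detectors

All four operate on 8-bit RGB frames resized to 416 × 320 pixels (a
throughput choice for embedded processors; the resize is bilinear and is a
no-op when the input already matches).

**Excess green (ExG).** Per pixel,

$$\mathrm{ExG} = 2G - R - B,$$

computed in a signed intermediate and clipped to $[0, 255]$, because all
thresholds are declared on zero-indexed 8-bit arrays. Achromatic pixels
(soil, stubble in shade) score 0; green leaves score high. ExG is the most
sensitive of the four but also reacts to anything with a weak green cast,
including blown-out glare.

**Normalised excess green (NExG).** Channels are first normalised by the
channel sum,

$$r = \frac{R}{R+G+B},\quad g = \frac{G}{R+G+B},\quad b = \frac{B}{R+G+B},$$

then $\mathrm{NExG} = 2g - r - b$, scaled by 255 and clipped. Normalising
removes the overall illumination level, at the cost of amplifying dark
pixels: a dim green pixel can score as high as a bright one. Black pixels
($R+G+B=0$) are defined to score 0 — black is never vegetation.

**HSV banding.** The frame is converted to hue–saturation–value and a pixel
is vegetation when all three channels fall inside configured bands
(inclusive on both ends). Hue is kept on the half-circle 8-bit convention,
$[0, 179]$, under which pure green (120°) sits at 60 and the shipped green
bands (30–92 by day for the combined algorithm, 35–84 for pure HSV)
bracket it; on a $[0,255]$ full-circle scale those same numbers would sit
in the red-orange range and select soil, so the half-circle reading is the
only self-consistent one. The value band's upper bound is the detector's
defence against specular glare: blown-out reflections have near-maximal
value and are rejected before any greenness is consulted.

**Combined (ExHSV).** A pixel must lie inside the greenness-index band
*and* the HSV bands. The greenness term is NExG by default; a profile
switch (`useRawExG`) substitutes raw ExG, since both variants are used in
practice and the trade-off (illumination robustness vs. dark-pixel
amplification) is environment-dependent.

## The frame pipeline

For the index algorithms (ExG, NExG) the grayscale index map passes
through two thresholds in sequence:

1. a **defined threshold** — a fixed band, 13–200 by day and 29–200 by
   night in the shipped presets. The fixed floor is what keeps the
   detector quiet on weed-free frames, where a purely data-driven
   (Otsu-style) threshold would be forced to call something vegetation;
2. an **adaptive threshold** — a pixel survives only if its index exceeds
   the Gaussian-weighted local mean of a 31 × 31 window by more than an
   offset of 2. This suppresses broad, low-contrast casts (e.g. an overall
   greenish white balance) while keeping locally contrasting leaves.

The HSV mask is already binary and skips the adaptive stage; the combined
mask feeds the adaptive stage computed on its greenness index. The window
size, offset, and the Gaussian weighting (with $\sigma = 0.3((n-1)/2 - 1)
+ 0.8$ for window size $n$, the common computer-vision default) are
package choices: 31 px is roughly twice the diameter of the smallest weeds
worth treating at this resolution, and an offset of 2 admits any genuine
local contrast while rejecting the exactly-uniform case. Borders are
replicated. All three constants are profile fields and can be overridden.

The binary mask is then cleaned by morphological opening followed by
closing with a disc-shaped structuring element (3 px by default — the
minimal element that removes single-pixel speckle without eating small
leaves), holes are filled, and 8-connected components become detections.
Components smaller than the minimum object size (10 px in all presets) are
discarded; that floor is what makes single-pixel noise harmless even when
it survives morphology. Each detection carries a 0-based, half-open
bounding box, its centre, and the filled pixel area, and detections are
sorted by bounding-box origin so output is deterministic (component
labelling order is otherwise an implementation detail). Whether the size
filter runs before or after morphology is a genuine free choice; it runs
after, on the final contours, so the reported area is the area the
actuation decision is based on.

## Zones and actuation

The frame width maps onto the on-ground field of view (1 m by default)
divided into `nZones` equal strips (4 × 25 cm). A detection is assigned by
its centroid: `zone = floor(cx · nZones / frameWidth)`, half-open bins, so
every in-frame x belongs to exactly one zone. The centroid (not the box
extent) decides, because the centroid is the weed-centre the pipeline
computes. Per frame, each distinct zone hit produces at most one
activation (default 200 ms — a typical solenoid actuation, configurable);
a zone already active has its end time extended rather than gaining a
queued duplicate, so a line of contiguous weeds produces continuous
spraying without relay chatter. The shipped backend is a mock that records
timestamped transitions; hardware backends implement the same
`setChannel` contract. No forward-speed lag compensation is applied — that
belongs to the sprayer integration, not the detector.

## Evaluation

Recall is the fraction of truly present weeds detected; precision is the
fraction of detections that are correct:

$$\mathrm{Recall} = \frac{TP}{\text{total weeds present}},\qquad
  \mathrm{Precision} = \frac{TP}{TP + FP}.$$

Field practice scores these by eye against a high-definition reference
video; an automated harness needs an explicit matching rule. The package
uses greedy nearest-centroid matching with a 50 px tolerance at 416 px
frame width (about 12 cm on the ground — comfortably tighter than the
25 cm actuation zone, so a match implies the right zone fires). Each
ground-truth weed matches at most once; extra detections on one weed are
false positives; inputs are canonically sorted first so the result is
order-invariant. A weed seen in several frames counts once per run,
deduplicated by ground-truth id. Metrics with zero denominators are
reported as `n/a`, mirroring the em-dash cells of field reports — never
silently as zero. `aggregateMetrics()` summarises a per-field ×
per-algorithm table with means, standard errors and medians, excluding
missing cells; the bundled seven-field table (`fieldPerformance()`)
exercises exactly that path.

## The synthetic scenes

`sceneBattery()` renders parametric scenes whose ground truth is exact by
construction: soil backgrounds (red-orange, dark brown, tilled with row
shading) with per-pixel texture noise (s.d. 6 intensity levels), pale
straw streaks whose hue sits just below the green bands, specular patches
rendered blown-out (value pinned at 255, faint green tint) so they pass a
raw greenness floor but fail the HSV value cap — the mechanism behind
glare false positives in sunlit stubble — and weeds as discs, rosettes or
thin grass blades in specified HSV colours, followed by Gaussian blur and
an illumination gain. Ground-truth area is the painted pixel count before
blur, since blur makes any post-hoc area ambiguous. All randomness flows
through a single seed recorded in the scene's spec.

The five styles map onto the regimes that drive detector behaviour in the
field: `day_green` (well-separated, strongly green discs — weed colours
are drawn with hue 110–130°, saturation 120–145 and value 100–165, chosen
so every index and band lands inside all four day presets, and centroids
at least 60 px apart so no two weeds merge into one component: conditions
under which a correct pipeline must score perfectly), `night` (darker,
artificial light), `stubble_glare` (heavy straw plus specular patches —
the false-positive regime for raw indices), `grass_thin` (blades one or
two pixels wide that blur into the background — the missed-detection
regime for all colour algorithms), and `purple_stressed` (hue 280–320°,
outside every green band — stressed rosettes that colour-only detection
cannot see).

What the generator deliberately does not emulate: real leaf shape and
venation, cast shadows, motion blur anisotropy, rolling-shutter skew,
mixed-species canopies, and soil moisture gradients. Perfect scores on
`day_green` therefore certify the pipeline's correctness, not field
performance; the bundled field table is the record of what colour-only
detection achieves on real transects (mean precision near 79%, mean
recall near 52%, with strong field-to-field spread).

## Problem sizes and determinism

The test suite and the acceptance script run the pipeline at the native
416 × 320 resolution on batteries of 10 scenes (20 for the glare
comparison), which keeps a full run in the tens of seconds while giving
every style several dozen weeds. Dual-route checks back the vectorised
index maps with per-pixel loop evaluation, component extraction with an
R-level flood fill, the adaptive threshold with a brute-force local mean,
and greedy matching with exhaustive optimal matching on small layouts.
Identical seeds and configuration give byte-identical detection logs.

## Known limitations

Colour-only detection inherits the field limitations the synthetic
batteries reproduce qualitatively: stressed or purple foliage is invisible
to green bands, thin grass blades vanish under blur, and raw greenness
indices false-trigger on glare. Threshold presets are environment-tuned
values, not universal constants — the profile files exist precisely
because new backgrounds need re-tuning. Video container decoding is out of
scope: the package consumes image sequences (PNG/JPEG/TIFF) and synthetic
streams, and writes annotated frames as PNGs; frame-rate figures from
`runBenchmark()` are wall-clock measurements on whatever hardware runs
them and are reported, never asserted.
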