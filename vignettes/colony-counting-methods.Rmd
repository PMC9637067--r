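---
title: "Seeded colony counting: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeded colony counting: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Counting colony forming units (CFU) on an agar plate is a routine readout in
microbiology: each viable cell or cell cluster grows into one visible colony,
so the count proxies viable cell density. In blue/white screening the
per-color counts carry the biological signal (lacZ-expressing colonies turn
blue on X-gal; insert-disrupted ones stay white). Manual point-and-click
counting is the gold standard but slow; `cfuseg` automates it for backlit
photographs taken with ordinary lab equipment, and classifies colonies by
color.

The central idea is *a priori* parameterization: the user clicks one
representative colony per color class, and every later stage — threshold
search, cluster selection, morphology cut-offs, segment pruning — is
calibrated from the measured attributes of those clicked colonies rather
than from hard-coded constants. That is what makes the method robust to
image scale, lighting, and colony morphology it has never seen.

## Pipeline

1. **Plate ROI.** The dish is a bright disk on a dark surround. We binarize
   at Otsu's threshold, take the largest bright component, and fit the
   minimum enclosing circle of its traced boundary. No inward margin is
   applied by default, so colonies at the wall stay countable. (How the
   plate mask "should" be computed is an open design point; the circle fit
   is our choice, and `--roi cx,cy,r` overrides it.)
2. **Denoising.** A 3x3 median filter per RGB channel, edge-replicated.
3. **Prototypes.** Each seed is flood-filled with a fixed-range tolerance of
   20 gray levels against the seed's own gray value, bounded by the ROI and
   by a 20%-of-ROI area cap (a fill that large means the seed hit
   background). The region's mean gray, circular mean hue, area, perimeter,
   circularity, inertia and bounding box are recorded. Multiple seeds per
   label are averaged.
4. **Adaptive threshold search.** Pixels darker than their local
   Gaussian-weighted mean minus an offset `C` become foreground:
   `dst = 255` iff `src(x, y) < T(x, y)` with
   `T(x, y) = G_s(x, y) - C`; equality goes to background (the formula only
   covers strict inequalities; assigning ties to background biases against
   single-pixel noise). The window size `s` starts at the prototype's
   largest bounding-box dimension (smaller windows carve colonies into
   donuts) and grows over 8 steps of `2 * max(2, s0 %/% 4)`; `C` ranges
   over 1, 3, ..., 29. A candidate binarization is **valid** when the
   histogram of original gray values at foreground pixels is unimodal, its
   peak contains the prototype's mean gray, and the area under the peak is
   at least one prototype's worth of pixels; among valid candidates the
   largest area under the peak wins, with ties resolved toward smaller `s`
   then smaller `C`.
5. **Contours and features.** One contour per 8-connected component of the
   combined mask (dust under 4 px discarded). Per contour: polygon area and
   perimeter from the traced boundary, circularity `4*pi*A/P^2`, inertia as
   the minor/major axis ratio of the moment-equivalent ellipse, circular
   mean hue over interior pixels, and area ratio = polygon area over
   minimum-enclosing-circle area.
6. **DBSCAN.** Features (area, circularity, inertia, area ratio, hue as a
   sin/cos pair) are z-scored and clustered; `min_samples` is one fifth of
   the contour count (floored at 2, capped at 20) and `eps` comes from the
   knee of the sorted k-th-nearest-neighbor distance curve with
   `k = min_samples`. The cluster containing the prototype's own contour is
   the single-colony population; members passing strict cut-offs
   (area within 0.3-3x the prototype, circularity >= 0.6, inertia >= 0.5,
   hue within 30 degrees) are accepted as single colonies.
7. **Watershed separation.** Everything else is an unresolved region:
   merged colonies, border debris, noise. Colonies are domed, so their
   centers are darker than their rims under backlight; we detect local
   minima whose prominence exceeds a noise tolerance, flood the gray relief
   from those markers (one segment per marker), and accept a segment iff
   its hue, circularity, inertia and area each lie within 3 SD of the
   single-colony statistics (SD floored at 10% of the mean). Regions with
   no marker pass through pruning unsplit, so matte colonies without a dark
   center are not lost.
8. **Report.** Counts per color label plus total, a per-detection table,
   and an overlay image (blue colonies circled in blue, others in green).

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| median kernel | 3 | px | salt noise removal without rounding small colonies |
| flood tolerance | 20 | gray | fixed-range fill of the clicked colony core |
| `s` grid | start at prototype bbox, 8 steps | px | window must exceed colony size; upper bound is a time/robustness trade |
| `C` grid | 1..29 step 2 | gray | offset below the local mean; small C admits noise, large C erodes rims |
| Savitzky-Golay | window 11, order 3 | bins | smooths Poisson counting noise while preserving peak shape |
| unimodality | 1 mode with prominence > 5% of max | – | see "deviations" below |
| peak-run tolerance | 2% of max (search); 0 (bare op) | – | rides out residual flank wiggles in the decreasing run |
| DBSCAN `min_samples` | n/5, in [2, 20] | – | the 1/5 rule, capped: uncapped it is pathologically strict on dense plates |
| single-colony cut-offs | 0.3-3x area, 0.6 circ, 0.5 inertia, 30 deg hue | – | permissive envelope around the prototype |
| prune band | mean +- 3 SD, SD floor 10% of mean | – | tiny clusters have near-zero SD; the floor keeps them usable |
| noise tolerance | max(5, 0.10 x (background - prototype gray)) | gray | see "deviations" below |

All are exposed through `run_pipeline(config = ...)`.

## Interpretations and deviations worth knowing

* **Which histogram?** A literal histogram of a binary image has two bins
  and can never be "unimodal around the prototype gray". We read the
  criterion as the histogram of *original* gray values at foreground
  pixels, which makes all three validity conditions well-posed.
* **Unimodality by prominence, not height.** Counting local maxima that
  *exceed 5% of the global maximum in height* misfires on real foreground
  histograms: the decreasing flank of a genuine single peak carries
  counting-noise wiggles well above 5% height, and every valid binarization
  would be declared multimodal. We count maxima whose *prominence* exceeds
  5% of the global maximum instead; the two rules agree on well-separated
  modes.
* **Multi-color plates.** With two colony classes both darker than the
  agar, the foreground histogram is inherently bimodal for every `(s, C)`,
  so no per-color search could succeed on the raw mask. Per-color masks are
  therefore gated competitively by hue: each foreground pixel belongs to
  the prototype with the nearest circular hue distance. With one prototype
  this is a no-op.
* **Prototype re-measurement.** A fixed-range flood fill with tolerance 20
  covers only the darker core of a domed colony (roughly a third to a half
  of its area). The threshold search correctly starts `s` from that core's
  bounding box, but morphology cut-offs compared against the core area
  would reject every true single colony. The pipeline therefore re-measures
  the clicked colony from its own contour *in the chosen binarization*
  before applying cut-offs — the a priori colony as segmented.
* **Watershed markers on the raw relief.** Markers flood the gray image
  itself, not a distance transform: distance-transform markers assume
  roughly uniform subsegment sizes, which colony clumps do not satisfy.
  Minima are detected on the median-denoised gray view.
* **Noise tolerance at 0.10 x contrast.** A tolerance of a quarter of the
  background-to-prototype contrast looked safe on paper but measurably
  swallows genuine colony centers: at 60-80% pairwise overlap the saddle
  between two centers retains only ~30-60% of the center-to-rim depth
  after rasterization and median filtering, while noise extrema die below
  ~5 gray levels. One tenth of the contrast (floored at 5) separates the
  two populations cleanly.
* **Perimeter convention.** Perimeters are exact polygon lengths of the
  traced boundary. This makes the circularity of a pixel-aligned square
  exactly pi/4, at the cost of rasterized disks measuring ~0.87 (an 8-chain
  overestimates a smooth arc by 5-8%). All shape cut-offs are calibrated to
  this convention; "corrected" perimeter estimators would silently shift
  them.
* **`area_ratio`** is contour area over minimum-enclosing-circle area — a
  convexity proxy consistent with the other shape features; the term is
  not defined more precisely in the original description, so this is an
  interpretation.
* **DBSCAN border ties** go to the cluster whose expansion reaches the
  point first (equivalently, the cluster holding the lowest-index core
  neighbor), making clustering deterministic; plateau maxima reduce to
  their centroid; equal-area `(s, C)` ties prefer smaller `s` then `C`.

## The synthetic world

`generate_plate()` renders what the algorithm assumes: a bright dish
(value 210) on a dark surround (40), a faint mottled dish wall
(165 +- 10 — the mottle matters: it produces the many spurious border
extrema that the pruning stage exists to reject), colonies as near-circular
disks whose value rises from `rim - depth` at the center to `rim` (150)
along `(1 - (d/r)^2)^2`, blue colonies at hue 240 / saturation 0.55, white
(cream) colonies at hue 60 / saturation 0.18, optional pairwise overlaps at
60-80% of summed radii, border colonies whose rim crosses into the wall
band while the body stays on the agar, a linear illumination gradient, and
Gaussian sensor noise. A quartic rather than quadratic dome is deliberate:
it concentrates colony area near the rim value, giving the rim-peaked
unimodal gray histogram real domed colonies produce (a quadratic profile
yields a uniform, flat histogram no colony shows).

Everything is scaled down from smartphone resolution so the whole suite
runs in minutes on one CPU: 800 px frames with ~6 px colonies for most
fixtures, and 1200 px frames with ~16 px colonies for the downscaling
study, chosen so that a 0.25x scale leaves ~4 px colonies — proportionally
the regime the original robustness experiment probed. What the generator
does **not** emulate: agar texture and condensation, soft colony edges
(anti-aliasing), off-white lighting color casts, vignetting, triple-or-more
colony clumps, and colony-size/density correlation. A green test
establishes that the algorithm recovers the stated world's structure; it
does not certify performance on any particular laboratory's photographs.

## Degenerate inputs and numerical edges

Contours with fewer than 5 boundary points cannot support an ellipse fit
and are routed to noise; prototype regions under 9 px are rejected with an
error. An empty foreground histogram fails assessment rather than erroring.
Fewer than 5 contours skips DBSCAN entirely (everything becomes a
single-colony candidate, filtered by the cut-offs). The Gaussian window
uses the conventional size-derived sigma `0.3 * ((s - 1)/2 - 1) + 0.8`. A
blank dish fails the threshold search with a classed error naming the
stage. All randomness lives in the generator; the pipeline itself is
deterministic, and identical inputs give byte-identical reports.

## Known limitations

Very dense plates (upwards of ~2000 CFU) stack colonies on top of one
another and defeat minima detection — the same regime the original method
declares out of reach. Color classes are separated by hue alone, so two
classes of nearly identical hue (e.g. two whites) cannot be distinguished.
TIFF input is not supported in this build (no reader in the dependency
set); PNG and JPEG are. The seedless case is out of scope by design: the
prototype *is* the calibration.
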