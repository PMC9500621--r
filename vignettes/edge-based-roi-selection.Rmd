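---
title: "Edge-based selection of tumor bounding boxes in breast ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-based selection of tumor bounding boxes in breast ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(busroi)
```

## The problem and the model

A breast-ultrasound (BUS) image typically contains one lesion, and the first
step of computer-aided diagnosis is localizing the rectangular region of
interest (ROI) that contains it. Several object detectors can each propose a
candidate box for the same image; their quality varies image by image. The
idea implemented here is to arbitrate between candidates using an *edge map*
of the image — a grayscale image, produced by an edge detector, in which the
tumor boundary is bright and homogeneous tissue is dark.

For a candidate box spanning columns $i = i_s..i_e$ and rows $j = j_s..j_e$
(0-based, inclusive; width $N$, height $M$) over the normalized edge map
$EM \in [0,1]$ and its binarization $BEM \in \{0,1\}$:

$$S = \sum_{i=i_s}^{i_e}\sum_{j=j_s}^{j_e} EM(i,j), \qquad
  D = \frac{1}{MN}\sum_{i=i_s}^{i_e}\sum_{j=j_s}^{j_e} BEM(i,j), \qquad
  SD = S \times D.$$

$S$ (edge mass) grows with coverage of the boundary: it screens out boxes
that miss part of the tumor. $D$ (edge density) is the fraction of
high-intensity edge pixels inside the box: it screens out boxes that cover
the boundary but drag in large amounts of background. The candidate with the
highest $SD$ is selected. The rule assumes (a) the edge detector concentrates
intensity on the lesion boundary more than anywhere else in the image, and
(b) exactly one lesion per image, so a single closed bright structure
dominates. Images violating these assumptions (multiple lesions, strong
acoustic-shadow edges) are outside the model.

Binarization uses adaptive *intermode* thresholding, computed once per image
on the full edge map (not per box, so that $D$ of different candidates is
comparable): the 256-bin histogram of the edge intensities is smoothed with a
3-bin moving average until exactly two local maxima remain, and the threshold
is the midpoint of the two mode bins, mapped back to $[0,1]$.

## Numerical and procedural choices

* **Coordinates.** Boxes are 0-based with inclusive corners; width is
  $x_{max}-x_{min}+1$. This matches the inclusive double sums above. A box
  touching another at a single corner pixel *overlaps* it — relevant for the
  detection criterion, which asks for at least one shared pixel.
* **Binarization comparison** is strict (`value > threshold`), so an
  all-zero map stays all-zero under threshold 0.
* **Intermode details.** Local maxima are strict, with the histogram
  zero-padded at both ends (so modes sitting in bins 0 or 255 count; the
  two-delta histogram at 0 and 255 thresholds at 127.5/255 = 0.5). The
  smoothing cap is 10,000 passes. If the histogram has fewer than two maxima
  (constant or strongly unimodal maps) or never reaches bimodality, the
  histogram mean is used as a fallback with a warning; the pipeline counts
  these per run. Smoothing stops early in the unimodal case because a moving
  average can never split one peak into two.
* **Rounding** is everywhere "nearest integer, half away from zero"
  (box rescaling between image frames, average-combiner corners). R's
  default half-to-even would make results depend on parity.
* **Tie-breaking.** Equal $SD$ scores select the earlier candidate in the
  configured model order; the order is part of the run configuration, so
  results are deterministic and permutation changes matter only on exact
  ties.
* **Failure handling.** A model with no box for an image is skipped; if all
  models fail (or the intersection combiner is empty), the method reports no
  ROI, which lowers its detection rate and excludes the image from its
  precision/recall/F1 means.
* **"Union" combining** returns the smallest *enclosing rectangle* of the
  present boxes, since downstream evaluation treats a prediction as a single
  box; the pixelwise union of boxes is generally not rectangular. The
  intersection of boxes is always a box, so no such reading is needed there.
* **Aggregation** uses the sample standard deviation ($n-1$), the
  conventional reading of "mean ± SD" reporting.
* **Box rescaling.** Detector boxes produced in a model-input frame (e.g.
  640×640) are rescaled into the original image frame *before* scoring, by
  scaling each corner and clamping into the frame. Scaling down and back up
  moves corners by at most one pixel.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_iterations` (intermode) | 10,000 | passes | far beyond the tens of passes real histograms need; a loop guard, not a tuning knob |
| `sharpen` radius / amount | 2 / 1 | px / – | standard unsharp-mask strength for speckle-laden ultrasound |
| `contrast_enhance` clip_limit / tile | 2 / 8 | – / grid cells | CLAHE as parameterized by the EBImage backend: an 8×8 grid of contextual regions with moderate clipping |
| phantom frame | 546 × 479 | px | typical lateral × axial extent of clinical B-mode images |
| boundary intensity / band width | 200 / 6 | 8-bit / px | bright, thin closed boundary as learned edge detectors produce |
| clutter density / intensity | 0.02 / 120 | fraction / 8-bit | sparse mid-intensity spurious edges so that density discrimination is non-trivial |
| noise SD | 8 | 8-bit | mild sensor/inference noise |

The artificial-RGB transform stacks (original, sharpened,
contrast-enhanced) as three channels; channel 1 is always the bit-exact
input. The precise filters behind "sharpened" and "contrast-enhanced" vary
across the literature; unsharp masking and CLAHE are the standard choices
and both are fully configurable.

## What the synthetic generator emulates — and what it does not

`generate_phantom()` renders an elliptical bright boundary band with sparse
background clutter and Gaussian noise; the gold-standard box is the tight
bounding box of the noise-free band, mirroring how expert tumor outlines are
reduced to gold ROIs. `simulate_detections()` perturbs the gold box per
simulated detector with a multiplicative size bias, independent Gaussian
corner jitter, and a detection-failure probability.

The default four-detector ensemble is calibrated to the operating
characteristics reported for fine-tuned detector ensembles on clinical BUS
data: per-model detection rates of roughly 81–90%, mean pixel-overlap F1 of
0.71–0.84 with per-image spreads around 0.1, one unbiased best-localizing
member, and systematically over- and under-sizing members. Labels
(benign/malignant) are assigned by ellipse aspect ratio, echoing the
taller-than-wide presentation of suspicious masses; they exist so per-class
aggregation is exercised, not as a biological claim.

Real edge maps differ from phantoms in ways that matter for external
validity: clutter is structured (glandular interfaces, shadowing) rather
than i.i.d. speckle; boundaries are incomplete where the lesion is
isoechoic; and real detector errors are *correlated across models and
heterogeneous across images* — occasionally grossly wrong — whereas the
simulator draws independent moderate jitter. Two consequences show up in the
benchmark and deserve honesty: the corner-averaging combiner looks very
strong under independent zero-mean jitter (averaging cancels noise), which
is precisely the structure real ensembles lack; and the selection rule's
margin over the best single simulated detector is small, because an
unbiased Gaussian-jitter detector is already near-optimal. Passing the
benchmark therefore demonstrates that the scoring machinery discriminates
coverage from dilution as designed, not that a particular margin would be
obtained on clinical data.

## Problem sizes

The test suite and examples use 200 phantoms of 546 × 479 pixels for the
benchmark, 200 reduced phantoms (180 × 160) for the hypothetical-box
selection property, 300 for the unbiased-detector recovery property, and
1000 random small instances for each brute-force oracle comparison. These
sizes give stable stochastic summaries (binomial standard errors of a few
percent) while keeping a full run in tens of seconds.

## Known limitations

* One lesion per image; no notion of multiple or zero true lesions.
* The SD score is scale-dependent through $S$; it is only used to *rank*
  boxes within one image and must not be compared across images.
* Confidence scores of detectors are ignored by design; the selection is a
  pure function of boxes and the edge map.
* The intermode fallback (histogram mean) is a heuristic for degenerate
  maps; such images are flagged in the run counters and are rare on
  realistic inputs (typically none to a handful per 200 phantoms).
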