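---
title: "Auditing DR-classifier saliency with fundusXAI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing DR-classifier saliency with fundusXAI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusXAI)
```

## The question the toolkit answers

Deep classifiers grade diabetic retinopathy (DR) from fundus photographs on
the five-level ICDR scale, but a grade alone says nothing about *why* the
model decided as it did. Clinicians grade by lesions: microaneurysms (MA)
alone mean mild DR; exudates (EX/SE) and dot hemorrhages (HE) moderate DR;
more than 20 hemorrhages in each of the four quadrants severe DR;
neovascularization (NV) proliferative DR. A trustworthy classifier should
therefore attend to those lesions. fundusXAI operationalizes that audit:

1. **Attribution.** For each image, compute a saliency field for the class
   the model actually *predicted*: Grad-CAM (conv-layer feature maps
   weighted by spatially pooled class-score gradients, rectified) and
   Integrated Gradients (average input gradient along the straight path
   from a baseline image, scaled by input − baseline).
2. **Binarization.** Resize the attribution to the image grid, min-max
   normalize to a heatmap $H_i \in [0,1]$, and keep the top tail:
   $A_i(x,y) = 1 \iff H_i(x,y) \ge T$, where $T$ is the 90th percentile of
   $H_i$ for Grad-CAM and the 97th for IG.
3. **Overlap.** For each lesion type with binary mask $M_i$, form
   $I_i = A_i \wedge M_i$. Any overlap ($\sum I_i > 0$) counts as a *hit* —
   the amount of overlap is deliberately not scored, because coarse
   (Grad-CAM) or boundary-spilling (IG) saliency makes area-based scores
   uninformative; IoU is still recorded for reference.
4. **Stratified counting.** Hits are tabulated per (method, DR grade,
   prediction correctness, lesion type).
5. **Agreement.** When a human has also judged, per image and lesion,
   whether the saliency overlay highlights that lesion, Cohen's kappa per
   stratum quantifies manual/automatic agreement, with `N/A` when chance
   agreement is 1 and a dash for empty strata.

## Attribution details and the choices behind them

**Target class.** Always the predicted class (argmax of the probability
vector, ties to the lowest index), never the true label; correctness is
kept alongside each record so strata can separate the two situations.

**Pre-softmax scores.** Both methods differentiate the pre-softmax class
score. For Grad-CAM this is standard practice (softmax saturation starves
gradients exactly where the model is confident); for IG it makes the
completeness identity $\sum \text{attr} = F(x) - F(x')$ checkable with two
forward passes of the same score.

**IG quadrature.** The path integral is approximated with a composite
trapezoid rule (default 64 intervals; a left-Riemann rule is available).
On an affine model any step count is exact; on the shipped fixture model
the completeness residual falls monotonically as steps double and is below
$10^{-3}$ relative at 256 steps. The default **baseline is the all-zero
(black) image**, the common convention. A consequence worth knowing: IG
weights each pixel's averaged gradient by $x - x'$, so dark-on-bright
lesions (microaneurysms, hemorrhages) receive systematically smaller
magnitudes from a black baseline than bright lesions do. This is a
documented property of the method, not a defect of the pipeline; the
Grad-CAM route is the robust localizer for dark lesions.

**Channel reduction.** IG yields per-pixel-per-channel values; the default
single-channel reduction is the sum of absolute values (evidence magnitude
regardless of sign), with a signed sum available.

**Percentile convention.** The threshold is the linear-interpolation
percentile (R `quantile` type 7) over *all* image pixels; an optional FOV
mask can restrict the population. Ties at the threshold are active (the
rule is $\ge$), so the active fraction is at least $(100-p)\%$. A constant
heatmap cannot be normalized; it becomes all-zero, every pixel is active
under the $\ge$ rule, and a degenerate flag travels with the record so
reports can exclude such images.

**Pipeline order.** Resize (bilinear, half-pixel-center convention) →
normalize → threshold, so that $[0,1]$ and the percentile population refer
to the final image grid.

## Masks and patches

Masks are single-channel PNGs; any pixel above zero is foreground. The
optic disc and macula are anatomically unique, so segmentation output for
them may be reduced to the largest 8-connected component (ties broken by
the lexicographically smallest top-left pixel); lesion masks are used
exactly as generated, never post-processed. Image-mask pairs can be tiled
into row-major non-overlapping square patches (a 1120×1120 pair at 224 px
yields 25), and stitching the tiles reconstructs the input bit-exactly.

## Cohen's kappa conventions

$\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from the two raters'
marginals. The rendering conventions follow the field's tables: four
decimals, `N/A` when $p_e = 1$ (both raters constant and identical — no
variability to correct for), a dash when the stratum is empty. When the
raters are constant on *different* categories $p_e = 0$ and $\kappa = 0$;
the verbal "no variability" rule is ambiguous there and this package
resolves it by declaring `N/A` only at $p_e = 1$. When exactly one rater
is constant, $p_o = p_e$ and $\kappa = 0$ identically — worth remembering
when reading tables where the automatic rater hits every image in a
stratum.

## The synthetic study conditions

The generator emulates what the audit needs and nothing more: a circular
field of view (radius 0.47 of a 224 px side) with radial brightness
falloff and mild Gaussian pixel noise (σ = 0.01), a bright optic disc
(radius 0.08, nasally displaced), a darker macula (radius 0.055, central),
and lesions as rasterized discs — MA radius 2–4 px, EX 2–5, SE 4–8, HE 3–6
— plus neovascular tufts of curly strokes within an 11 px radius. Masks
are pixel-exact by construction: the same rasterization paints the image
and writes the mask, shapes never overlap each other or the landmarks, and
empty lesion types get genuinely empty masks (no false positives). An
optional bright "camera spot" confounder can be planted *without* a mask,
mimicking lens artifacts that attract saliency.

Grade labels follow a reduced ICDR reading implemented in `grade_rule()`:
no lesions → 0; only MA → 1; NV → 4; at least 21 hemorrhages ("more than
20") in each axis-aligned quadrant and no NV → 3; otherwise 2. Venous
beading and IRMA, which also enter the clinical severe-DR definition, are
not rendered — a documented simplification. Grade-3 scenes plant 96
hemorrhages, distributed round-robin so every quadrant holds 24.

What the generator does **not** emulate: vessels, texture, optics blur,
inter-camera variation, annotation noise, or lesion ambiguity. Passing
tests on these scenes certify the *pipeline arithmetic* — attribution,
thresholding, intersection, counting, agreement — under known geometry;
they say nothing about how well any real classifier or segmenter performs
on real fundus images.

## The fixture classifier

A fixed-weight, fully differentiable scorer stands in for a trained
grader: 4× average pooling, a 5×5 convolution with seven templates (raw
brightness; color-keyed center-surround detectors for MA, EX, SE, HE, NV;
a generic brightness-contrast channel), softplus activations (β = 25), a
field-of-view gate, global average pooling, and a linear 5-class head
centered on a lesion-free reference scene. Gradients are exact (verified
against central finite differences), which is what makes the fixture
useful: Grad-CAM, IG completeness and the adapter contract can all be
checked without an autodiff framework.

Two construction notes. Softplus rather than ReLU keeps the IG path
integral smooth, so the trapezoid rule converges fast and
finite-difference checks are stable; activations remain non-negative as
the conv-layer contract expects. And the head is a *shared detection
vector plus a small class-specific tilt*: with one weight matrix serving
both jobs, balanced weights (which let the class-activation map localize
every lesion type comparably) and differentiated weights (which separate
the argmax) are in direct tension; the shared part contributes identically
to every logit and cancels in the argmax, resolving the tension. The
fixture mis-grades some scenes — mild scenes with few microaneurysms drift
to grade 0, heavy-exudate scenes to grade 3 — which is intentional: the
stratified tables need a realistic mix of correct and incorrect
predictions.

## Numerical choices

- Percentile: `quantile` type 7 (linear interpolation), documented for
  bit-reproducibility; conventions differ across libraries by ±1 pixel at
  ties.
- Bilinear resize: half-pixel-center sampling with clamped edges
  (identical results to EBImage's `resize`).
- IoU denominator: the union $|A \vee M|$ (Jaccard); both-empty is defined
  as 0 and flagged.
- Both IG rules evaluate the integrand at exact multiples of $1/\text{steps}$;
  the trapezoid rule halves the end weights.
- Float TIFF stores only $[0,1]$ portably, so raw attributions outside
  that range are min-max scaled on write with the range in a sidecar file.
- Sample standard deviation (n−1) in score statistics; singleton strata
  report 0.

## Problem sizes used by the test suite

Scenes are 224 px; the deeper suites run 20 scenes for IG completeness at
256 steps, 50 scenes for the end-to-end hit audit (Grad-CAM at the 90th
percentile: every planted lesion type must overlap the top decile, every
absent type must not — absent types can only hit through mask false
positives, which synthetic masks do not contain), 100 random heatmaps for
the threshold laws, and every joint binary table up to n = 8 for the kappa
oracle. These sizes were chosen so the whole audit runs comfortably on a
single CPU while still exercising each property far from its trivial
cases.

## Known limitations

- The scene palette separates lesion classes by color signatures more
  cleanly than pathology ever does; the fixture's templates exploit that.
- The black-baseline IG under-attribution of dark lesions (above) means
  IG hit counts for MA/HE should be read with the baseline in mind;
  a gray or blurred baseline is configurable where that matters.
- The severe-DR rule is hemorrhage-count-only.
- Cohen's kappa is the unweighted two-rater form; no weighting, no more
  than two raters.
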