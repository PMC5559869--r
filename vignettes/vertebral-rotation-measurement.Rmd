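---
title: "Measuring vertebral axial rotation by maximum symmetry: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vertebral axial rotation by maximum symmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertrot)
```

## The measurement problem

After instrumented fusion for adolescent idiopathic scoliosis, follow-up CT
at two post-operative timepoints can show whether axial rotation keeps
evolving: within single vertebrae (intra-vertebral), within discs between
adjacent vertebrae (inter-vertebral / intra-discal), and for the fused
segment as a whole (en-bloc movement against the un-instrumented neighbours).
The raw observable is the axial orientation of each vertebral endplate on a
*true-axial* slice — a reformatted plane lying in the endplate itself rather
than the scanner's axial plane. Endplate outlines are traced manually
(automatic thresholding is unreliable next to metal instrumentation), so the
computational pipeline starts from closed polygons with pixel spacing, not
from grey-level images.

## The symmetry model

The core assumption is anatomical: a vertebral cross-section is approximately
mirror-symmetric about its anteroposterior axis, so *the axis of maximum
symmetry defines the vertebra's angular orientation*. For a binary mask $S$
and an axis through the foreground centroid at angle $\theta$, the package
scores

$$R(\theta) = \frac{|S \cap \mathrm{mirror}(S,\theta)|}{|S|} \in [0,1],$$

which is 1 exactly when $S$ is mirror-symmetric about the axis and is
180°-periodic. The reflection is evaluated in continuous coordinates with
bilinear sampling of the mask rather than by pixel-index flipping; this
removes the pixel-grid's preferred directions from the measurement, which
matters for the central correctness property (equivariance, below). The
overlap is normalised by $|S|$; since the mirrored set has the same area,
this is equivalent up to a monotone transform to an overlap-over-union
score, and it is directly checkable against a per-pixel counting oracle.

Angles are reported in degrees in $[0, 180)$, measured clockwise (viewed
from above) from the anteroposterior reference line perpendicular to the
scanner bed. The reference travels with every reformatted slice, so angles
are comparable across endplates and timepoints; every quantity the analysis
consumes downstream is a *difference* of two such angles, which makes the
choice of the reference's zero a pure convention.

### Angular grid, peaks, and ambiguity

`compute_symmetry_profile()` samples $R$ over $[0,180)$ at `angle_step`
(default 0.1°, matching the reporting precision of the measurement), smooths
with a short circular moving average (1° window), picks local maxima, and
refines each peak by parabolic interpolation of the three surrounding
samples. Two numerical guards are deliberate:

* a **minimum prominence** (default 0.01 in ratio units) suppresses
  raster-jitter pseudo-peaks, so a near-elliptical endplate reports exactly
  its two anatomical candidate axes;
* a **flat-profile tolerance** (default 0.02 in ratio units on the profile's
  range): a disc-like mask whose profile never develops a dominant axis is
  declared unmeasurable outright. The default sits just above the residual
  90°-periodic modulation that pixel-grid anisotropy leaves on a perfect
  disc rasterized at 0.5 mm.

A profile is **ambiguous** when two or more peaks lie within 2% of the
global maximum and are separated by more than 10°. In practice this happens
for ovoid, near-elliptical endplates, which admit two perpendicular
near-symmetry axes. Where the original workflow resolved such cases by a
human inspecting the symmetry-ratio curve, `select_rotation_angle()` makes
the rule explicit and testable: with a caller-supplied prior (the same
endplate at the other timepoint, or an adjacent endplate) the peak
circularly closest to the prior wins and the result is flagged
`ambiguous_resolved`; without a prior the endplate is `unmeasurable` and the
patient is excluded from cohort summaries — mirroring the exclusion of
datasets whose rotation could not be identified. Exact ties go to the
smaller angle, deterministically.

## Rotation calculus and sign conventions

Endplate orientation is axial (undirected), so differences live on a
180°-periodic circle; `wrap_angle_diff()` maps them into $(-90°, 90°]$.
Inter-endplate rotation is $\varphi_u - \varphi_l$ (cephalad over caudal),
clockwise positive viewed from above. Clinically realistic rotations are
within a few degrees of each other, far from the $\pm 90°$ seam, so the wrap
handling is lossless for real inputs while keeping the seam case
well-defined (1° over 179° is a +2° rotation, not −178°).

A change between timepoints is $\text{value}_{t2} - \text{value}_{t1}$.
Relative to the curve apex — which may itself be a vertebra or a disc —
negative changes above and positive changes below the apex mean rotation
*back toward the pre-operative deformity* (loss of correction). At the apex
itself the loss flag is undefined and recorded as `NA`. Unmeasurable
endplates propagate as missing values, never as zeros.

## The significance gate

Although the symmetry search itself is automatic, the true-axial plane and
the traced outline are manual, so repeated measurements of the same change
disagree. Repeatability is summarised Bland–Altman style: for repeated
change measurements $\alpha_n, \alpha_m$ of the same levels,
$\Delta\alpha = |\alpha_n - \alpha_m|$, and the 95% limit of agreement is
$1.96 \times \mathrm{SD}(\Delta\alpha)$ (sample SD, $n-1$; repeatability
sets are small). Only changes strictly exceeding the limit are significant.
An intra-observer SD of 4.2° gives a gate of
$1.96 \times 4.2 = 8.23 \approx 8.2°$.

Two conventions deserve note. First, the default takes the SD of the
*absolute* differences; the classical Bland–Altman variant on signed
differences is available via `method = "signed"`. The absolute-difference
convention is implemented as the default for fidelity with the established
workflow this package operationalises. Second, for simulated Gaussian
measurement noise of SD $\sigma$ per measurement, the absolute difference is
half-normal and
$\mathrm{SD}(\Delta\alpha) = \sqrt{2\sigma^2(1 - 2/\pi)}$ — the closed form
(`analytic_loa95()`) against which the simulation path is validated.

## What the synthetic generator emulates

The phantom family (`shape_params()`) is a superellipse body (exponent 2.5;
flatter-sided than an ellipse) with two optional posterior pedicle lobes and
a localized posterior flattening — the canal notch — whose amplitude is
`posterior_flattening * asymmetry_strength`. The design is the minimal
family with the right symmetry structure:

* pedicles on, or asymmetry on: exactly **one** mirror axis (superior
  endplates traced through the pedicles; inferior endplates with the notch
  only);
* both off: a pure superellipse with **two** perpendicular axes (the
  ambiguous, ovoid case);
* `disc_shape_params()`: a circle, symmetric about every diameter (the flat,
  unmeasurable case).

The notch is a *localized* radial dip rather than a smooth low-order
modulation for a numerical reason: the reflection axis passes through the
centroid, and centroid-anchored mirroring absorbs first-harmonic
(translation-like) radius changes almost completely, so global fore–aft
modulations barely separate the two candidate axes. A localized dip
concentrates power in higher harmonics and separates them decisively.

Default dimensions (32 × 24 mm body, 7 × 6 mm pedicles) are typical
mid-thoracic endplate proportions. A synthetic patient
(`spine_study_spec()`) spans T4–L1 with fusion T5–T12 and apex T8 by
default — a thoracic construct imaged with exactly one adjacent
un-instrumented vertebra on each side — with a smooth residual apical
rotation pattern (amplitude 12°) around a 90° baseline. Injected
inter/intra-vertebral changes are realized by rotating every endplate
cephalad of the target entity's lower endplate, which changes exactly that
entity's relative rotation and nothing else; en-bloc motion is the special
case where the two junction discs receive equal and opposite injections.
Manual-tracing noise is an independent radial Gaussian perturbation of the
polygon vertices (SD in mm) followed by arc-length resampling, which
perturbs the outline without biasing its orientation. All randomness is
seeded per operation; no global state.

What the generator does **not** emulate: CT grey levels, metal artefact from
the rod, scanner noise, partial-volume effects at the endplate, or real
anatomical variation across thoracic levels (levels are i.i.d. around the
default shape). Passing tests therefore demonstrate the correctness of the
*computational* chain given faithful outlines, not the clinical accuracy of
manual tracing on artefact-degraded images — that part of the error budget
enters through the limits-of-agreement gate instead.

## True-axial reformatting

`fit_endplate_plane()` fits a total-least-squares plane (SVD) through at
least three non-collinear landmark points, orients the normal cranially —
which fixes the viewed-from-above handedness the sign convention needs — and
projects the scanner anteroposterior axis into the plane as the in-plane
reference. `extract_true_axial()` resamples the volume on that plane by
trilinear interpolation and rebinarizes at 0.5, emitting the slice with
anterior along +y so that downstream angles need no further correction.
Slices are taken exactly at the fitted plane; how an observer standardises
position within the endplate's thickness is not modelled. Degenerate inputs
fail loudly: collinear landmarks, a plane normal parallel to the
anteroposterior axis (reference undefined), a plane missing the volume, and
voxels too coarse to resolve the phantom each raise a typed error.

## Numerical choices and problem sizes

* Raster spacing 0.4 mm and angle step 0.1° are the default working
  resolution; on noise-free pedicled phantoms this yields a maximum
  recovery error around 0.3° and RMSE below 0.1°, comfortably inside the
  0.6° (`angle_step` + 0.5°) design tolerance. Halving or doubling the
  raster spacing moves measured angles by well under the angular grid.
* The symmetry sweep (1800 angles × a few thousand foreground pixels) runs
  in compiled code; one endplate measures in well under a second.
* Polygon rasterization uses even-odd scan filling of pixel centres with a
  half-pixel grid offset, so axis-aligned polygon edges never coincide with
  pixel centres; raster areas match shoelace areas to well under 2% at
  0.5 mm spacing.
* The validation suite exercises ~200-phantom rotation-recovery sweeps,
  20-shape × 17-offset equivariance grids, a 32-patient noise-free cohort
  with a known injection pattern, $10^5$ simulated rater pairs, and tilted
  volumes up to 30°; these sizes keep the full run in minutes on one CPU
  while leaving the statistical checks well-powered.

## Known limitations

* The symmetry-ratio formula is this package's operationalisation of the
  maximum-symmetry principle; the historical plugin's exact ratio and
  smoothing are not public, so agreement is established against the
  package's own oracles and invariants (equivariance, fixed points,
  per-pixel counting), not against the original implementation. Published
  per-image angle values from that workflow serve only as interface-shaped
  examples in the tests.
* The en-bloc criterion (both junction-disc mean changes significant with
  construct-consistent opposite signs) is an explicit, configurable
  operationalisation of what was originally a narrative assessment.
* Rotation changes are not mapped to rib hump or Cobb angle; no such mapping
  is defined, and none is attempted here.
* Cohort-level numbers from any particular clinical dataset (junction means,
  counts of changed patients) depend on that cohort's CTs; the package
  reproduces the *machinery*, and its cohort outputs are validated on
  synthetic studies with known injected truth.
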