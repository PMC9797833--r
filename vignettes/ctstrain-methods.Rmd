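---
title: "Measuring longitudinal strain from cine CT blood-pool segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring longitudinal strain from cine CT blood-pool segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctstrain)
```

## The measurement problem

ECG-gated ("cine") cardiac CT is reconstructed at fixed fractions of the R-R
interval, typically every 10%. Automated deep-learning tools can segment the
left-ventricular (LV) and left-atrial (LA) blood pools in every phase and
predict the three standard long-axis imaging planes (2-, 3- and 4-chamber).
Given those two outputs, longitudinal strain (LS) — the fractional shortening
of the LV endocardial boundary between end-diastole (ED) and end-systole
(ES) — becomes measurable without any manual contouring:

1. reslice each label volume along each long-axis plane;
2. extract the LV endocardial contour in the slice, using the LA label to
   find and remove the mitral-valve segment (the LV/LA interface is not
   endocardium);
3. measure the open contour's length `P` per phase;
4. `LS = (P_ES - P_ED) / P_ED`, with ED/ES chosen as the phases of largest
   and smallest 3D LV blood-pool volume.

Negative LS means shortening; clinically, LS around -0.20 is normal and
values much closer to 0 indicate dysfunction. Per-view LS is then thresholded
to call wall-motion abnormalities (WMA) at the view and patient level, with
the cutoff chosen from a training cohort's ROC curve.

This vignette records the package's model choices, conventions, tunable
parameters, and the reasoning behind the decisions that were genuinely open.

## Reslicing conventions

A `cine_segmentation` stores integer label grids (0 background, 1 LV, 2 LA)
with a NIfTI-style 4x4 affine mapping 0-based voxel indices to world mm.
A world point belongs to the voxel whose centre is nearest. Reslicing samples
labels **nearest-neighbour only** — interpolating integer labels is
meaningless — on a regular in-plane grid spanned by the plane's two
orthonormal direction vectors (checked to 1e-6). Pixels outside the volume
are background, and a plane that misses the labelled volume entirely yields
an all-background slice flagged `empty` with a warning rather than an error.

The default in-plane pixel spacing is the smallest voxel dimension, so no
boundary resolution is lost. For phantom studies the package's tests and the
acceptance script set 0.5 mm explicitly: clinical cardiac CT is reconstructed
on a 512 x 512 matrix over a ~240 mm field of view (~0.47 mm pixels), and the
10-pixel disk used in contour correction then corresponds to a ~5 mm physical
smoothing scale, as it does on clinical data. The reslice extent defaults to
the bounding box of all non-background voxels plus a 6 mm margin, so the LA
is always in the field of view when present.

## Contour extraction and the three perimeter methods

The LV boundary is defined on pixels: a boundary pixel is an LV pixel with at
least one 4-neighbour that is not LV (image borders count). The boundary of
the largest 8-connected LV component is ordered by Moore-neighbour tracing
and measured as a polyline through pixel centres, diagonal steps contributing
sqrt(2) times the spacing. Boundary pixels with an LA pixel in their
8-neighbourhood form the mitral interface; removing that run opens the
contour at the valve. If a slice contains no LA, the closed contour is
measured and the view is flagged non-compliant rather than dropped.

* **Naive (method A)** measures that open chain directly. It carries two
  systematic effects: papillary-muscle indentations add spurious length, and
  the pixel chain of a smooth curve is itself ~4-5% longer than the curve
  (staircase digitisation bias).
* **Hull (method B)** first applies a morphological closing with a disk
  structuring element (radius 10 pixels, configurable), replaces the mask by
  its filled convex hull, and measures the hull mask's boundary chain with
  the same metric, again opened at the valve. Convexification removes the
  papillary notches, but the measurement still rides on a pixel chain, so
  digitisation and surface-texture inflation remain. Measuring the
  *rasterised* hull rather than the exact hull polygon is deliberate: it
  keeps the three methods on one metric (for a convex shape, hull and naive
  lengths then agree), and it reproduces the known behaviour that the
  hull-corrected perimeter is still sensitive to boundary texture.
* **Spline (method C)** downsamples the open hull chain by keeping every 5th
  point (configurable; both mitral endpoints always kept), fits a natural
  cubic spline — zero second derivative at the open ends — through the
  retained points parameterised by cumulative chord length, and integrates
  its arc length by dense sampling (at least 20 samples per knot). With
  0.5 mm pixels the knots sit ~2.5 mm apart, so the spline removes the
  staircase and fine texture while following the anatomy. Fewer than 8
  points after downsampling falls back to the hull length with a warning.

Degenerate inputs are handled explicitly: a single-pixel LV yields a
one-point chain; multiple LV components keep the largest and record the
count; an entirely-mitral boundary is an error.

Two numerical consequences are worth stating because they shape what the
tests can claim. First, the chain metric's +4-5% inflation and the
half-pixel inset of boundary pixel centres partially cancel against the
few-millimetre loss from valve-segment removal, so *absolute* perimeters
from any method sit a few percent from the analytic truth, with
method-dependent sign. LS, a ratio of like-measured lengths, cancels the
shared parts; that is why strain is accurate to ~0.01-0.015 while raw
perimeters are not. Second, because papillary indentations and frame-noise
do not scale with contraction while the cavity does, the naive method's
error is phase-dependent and noisy across subjects — exactly the mechanism
the hull and spline corrections target.

## Strain, FAC and EF

ED and ES are selected once per study from the 3D LV voxel volume (largest /
smallest; ties to the earliest phase; a constant-volume cine warns and
forces ES to the second phase so LS is defined and zero). A per-view
selection from slice areas is available behind `per_view_ed_es` but is not
the default: one global ED/ES keeps LS, fractional area change (FAC) and
ejection fraction (EF) on the same pair of timeframes. FAC uses the raw LV
pixel area of the slice — not the convexified area — since the cavity area,
papillary voids included, is what area-based function indices measure. EF is
the standard (EDV - ESV)/EDV on voxel-counted volumes. LS is reported as a
signed fraction; "higher" cutoffs always mean less-negative values.

## Wall-motion classification and statistics

Per-view LS values are compared against a cutoff `tau`: a view is called
abnormal when `LS >= tau` (equality counts as abnormal, conservatively
toward detection); a patient is abnormal when any view is. Cutoffs are
fitted on a training cohort only: candidate thresholds are midpoints
between consecutive sorted unique scores plus +/-infinity, the ROC curve is
traced over them, AUC is the trapezoid over (1 - specificity, sensitivity)
(identical to Mann-Whitney concordance, which the tests verify by exhaustive
pair counting), and the optimal cutoff minimises the Euclidean distance to
the (0, 1) corner with ties broken toward higher specificity. Both a
per-view cutoff set and a single pooled cutoff are fitted and reported; a
view whose training data contain one class only inherits the pooled cutoff.

Expert wall-motion reads enter as per-segment labels (16 AHA segments, no
apical cap, three readers; hypokinetic/akinetic/dyskinetic pooled into
"abnormal"). A segment is consensus-abnormal with two or more non-normal
reads, a view is abnormal if any mapped segment is, a study if any view is.
The segment-to-view mapping is a plain editable table; the default sends
anterior/inferior walls to the 2-chamber view, anteroseptal/inferolateral to
the 3-chamber, inferoseptal/anterolateral to the 4-chamber, apical segments
following their wall.

The evaluation layer reports confusion counts with accuracy, sensitivity,
specificity and PPV, each with a 95% Wald interval on its own denominator
clipped to [0, 100]% — the clipped normal approximation reproduces printed
intervals of the design this package follows exactly (e.g. a sensitivity of
90.0% at n = 20 gives 76.9-100). Rates with zero denominators are reported
absent (`NA`), never NaN. Agreement uses Cohen's kappa (two raters) and
Fleiss' kappa (three or more); proportions are compared with a pooled
two-proportion z-test; correlations with Fisher's r-to-z. The r-to-z
comparison is applied to dependent samples (same views measured by
different methods) without a dependency adjustment because that is the
stated analysis design; it is approximate there, and the package documents
rather than hides this.

## The synthetic phantom

`phantom_spec()` / `generate_phantom()` produce a contracting left heart
with analytic ground truth:

* **Geometry.** The LV cavity at ED is an ellipsoid (default semi-axes
  24 x 24 x 38 mm) cut by a flat mitral plane at 68% of the long semi-axis;
  the LA sits above the plane, wider than the mitral orifice at every phase,
  so LA-adjacency marks the whole basal cap as valve consistently at ED and
  ES. The heart receives a seeded random azimuthal orientation relative to
  the voxel grid — patients are not scanner-aligned, and without this one
  view plane would be grid-aligned and enjoy artificially clean
  rasterisation.
* **Contraction.** A per-phase linear scale `s(t)` (raised-sine by default,
  `s = 1` at ED, minimum `s_es` at mid-cycle) is applied about the point
  where the long axis pierces the mitral plane, so the smooth contour of
  every long-axis view scales exactly by `s`: true LS is `s_es - 1`, true
  FAC `1 - s_es^2`, true EF `1 - s_es^3` under uniform contraction.
  Regional hypokinesis applies a reduced contraction within an angular
  sector about the long axis, giving view-level abnormality ground truth.
* **Papillary muscles.** Spherical-cap indentations of fixed physical depth
  (default 6 mm) anchored to the scaled endocardial surface at
  mid-ventricular level, at seeded uniform azimuths. Because the bite size
  does not scale with contraction, its relative effect grows at ES — the
  phase asymmetry that corrupts naive LS.
* **Surface texture.** Two seeded components, both of constant amplitude in
  mm: static band-limited angular modes (default RMS 0.8 mm, frequencies up
  to 7) representing anatomical surface irregularity, and fine per-frame
  jitter (default RMS 0.5 mm, angular frequencies 25-50, independent random
  phases each frame) representing frame-to-frame inconsistency of automated
  segmentations — the failure mode the spline correction addresses. An
  optional slow drift of the static pattern exists but defaults to off:
  long-wavelength shape change is not removable by any local smoothing and
  would conflate shape noise with texture noise.
* **Truth.** Computed from the smooth geometry only, by dense numeric
  parameterisation of the per-view ellipse arc below the mitral plane
  (4001 samples) and an azimuthal quadrature for EF; the stated uniform
  contraction identities hold to the quadrature accuracy (~1e-6).

What the phantom does *not* emulate: myocardial tissue contrast, valve
anatomy beyond a planar interface, through-plane motion of the planes,
electrophysiological timing, and correlated inter-view segmentation errors.
Passing tests therefore demonstrate the measurement chain's correctness and
its artifact-robustness ordering, not clinical-level accuracy figures; the
clinical cutoffs and correlation magnitudes of the motivating study are not
reproducible without its cohort.

## Problem sizes used in tests and the acceptance script

Validation experiments run at three rendering scales, chosen as a
throughput/fidelity trade per experiment: single-phantom checks at
96^3 voxels of 1.25 mm, the 100-phantom population for the agreement trend
at 80^3 of 1.5 mm, and the train/test cohort demonstrations at 64^3 of
1.9 mm. All pipeline runs on phantoms reslice at 0.5 mm. The cutoff-recovery
cohort uses 30 studies with end-systolic scale factors drawn in
(0.78, 0.82) and a hypokinetic-sector deficit of 0.15 — the smallest deficit
for which cutoff recovery is claimed.

## Known limitations

* Perimeter accuracy is resolution-bound: valve-segment removal costs about
  two pixel rows of contour per insertion, so absolute perimeters are
  systematically a few percent short even when LS is accurate.
* The naive method's digitisation inflation and these removal losses
  partially cancel; comparisons of *absolute* perimeter error between
  methods on valve-opened contours are therefore not meaningful, and the
  package's error-ranking claims are made on closed contours.
* The structuring-element radius is defined in pixels, as in the design this
  package follows; the physical smoothing scale therefore changes with the
  reslice resolution. Both are explicit in `strain_config()`.
* Fleiss'/Cohen's kappa and the z-tests assume independent subjects; strain
  values of the three views of one study are not independent, so
  cross-view pooled statistics are descriptive rather than inferential.
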