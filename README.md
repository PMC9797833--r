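# ctstrain

Longitudinal strain (LS) and wall-motion classification from time-resolved
(cine) cardiac CT blood-pool segmentations.

## What it does and for whom

4D ECG-gated cardiac CT, segmented automatically into left-ventricular (LV)
and left-atrial (LA) blood pools with predicted 2-/3-/4-chamber long-axis
planes, contains everything needed to measure LS without manual contouring.
`ctstrain` is for imaging researchers who have such segmentations (e.g. from
a deep-learning pipeline) and want quantitative, reproducible strain and
wall-motion-abnormality (WMA) calls:

* reslices label volumes (NIfTI) along long-axis planes (JSON) with
  nearest-neighbour label sampling;
* extracts the LV endocardial contour per phase, using the LA label to
  locate and remove the mitral-valve segment;
* measures the open contour length `P` by three methods of increasing
  robustness — the raw pixel chain (**naive**), a convex-hull corrected
  mask bridging papillary-muscle indentations (**hull**), and a natural
  cubic spline through the downsampled hull chain suppressing surface
  texture and digitisation bias (**spline**);
* computes, per view and method,

  `LS = (P_ES − P_ED) / P_ED`,

  with end-diastole/end-systole chosen as the phases of largest/smallest 3D
  LV volume, alongside fractional area change
  `FAC = (A_ED − A_ES)/A_ED` and ejection fraction `EF = (EDV − ESV)/EDV`;
* fits per-view and single LS cutoffs on a training cohort from the ROC
  curve (optimal operating point = closest to the (0,1) corner, ties toward
  specificity) and classifies views (`LS ≥ τ` ⇒ abnormal) and patients
  (any abnormal view) in an independent testing cohort;
* provides the associated statistics: confusion metrics with clipped 95%
  Wald intervals, Cohen's and Fleiss' kappa, pooled two-proportion z-test,
  Fisher r-to-z comparison of correlations, and linear fits with confidence
  bands;
* ships a seeded synthetic left-heart phantom — contracting ellipsoidal LV
  with attached LA, papillary indentations, surface texture, per-frame
  segmentation jitter, optional regional hypokinesis — with analytic ground
  truth for every quantity above.

## Worked example

Generate a default phantom (uniform contraction to 80% scale, papillary
indentations, textured surface) and run the full pipeline:

```r
library(ctstrain)

ph  <- generate_phantom(phantom_spec(seed = 1))
ph
#> ct_phantom: 10 phases on 96x96x96 grid @ 1.25 mm
#>   truth LS: 4CH -0.200, 3CH -0.200, 2CH -0.200
#>   truth EF: 0.488

res <- run_study(ph$cine, ph$planes,
                 strain_config(all_phases = FALSE, pixel_spacing = 0.5),
                 study_id = "demo")
res
#> study_result 'demo': EF 0.492 (ED phase 1, ES phase 6)
#>  view method  p_ed  p_es      ls    fac compliant
#>   4CH  naive 199.1 144.3 -0.2749 0.3814      TRUE
#>   4CH   hull 160.9 126.1 -0.2166 0.3814      TRUE
#>   4CH spline 153.4 120.9 -0.2119 0.3814      TRUE
#>   3CH  naive 168.7 135.0 -0.2000 0.3807      TRUE
#>   3CH   hull 154.8 124.0 -0.1988 0.3807      TRUE
#>   3CH spline 149.6 119.9 -0.1986 0.3807      TRUE
#>   2CH  naive 172.4 145.3 -0.1573 0.3594      TRUE
#>   2CH   hull 159.3 126.9 -0.2036 0.3594      TRUE
#>   2CH spline 152.3 121.5 -0.2018 0.3594      TRUE
```

Reading the output: the measured EF (0.492) matches the analytic truth
(0.488). The naive perimeters are inflated and erratic — a papillary
indentation in the 4-chamber slice pushes its ED perimeter to 199 mm and its
LS to −0.27, while surface texture drags the 2-chamber naive LS to −0.16.
The hull and spline corrections pull every view back to the true strain of
−0.20 (spline within about 0.01 in all views). Classification with a single
fitted cutoff then proceeds as:

```r
tab   <- subset(res$table, method == "spline")
calls <- classify_view(tab$ls, tab$view, thresholds = -0.170)
#> all FALSE: every view shortens more than the cutoff, i.e. normal
classify_patient(calls)
#> FALSE
```

Cohort-level use (`run_cohort`) fits cutoffs on training records only and
reports per-view, pooled-view and per-patient confusion metrics for both
threshold modes; `write_phantom`, `read_cine_nifti`, `read_planes_json`,
`read_expert_labels` and `write_results_csv` cover the file formats. A thin
command-line front end lives at `inst/cli/ctstrain.R`
(`phantom | strain | classify | evaluate` subcommands).

See `vignettes/ctstrain-methods.Rmd` for the conventions (voxel-centre
world mapping, chain metric, valve removal), the phantom's model and its
limits, and the reasoning behind every tunable default.

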