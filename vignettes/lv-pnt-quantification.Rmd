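---
title: "Dual-convention left-ventricular quantification on cine phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-convention left-ventricular quantification on cine phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvpnt)
```

## The measurement problem

Short-axis cine MRI quantifies left-ventricular (LV) volumes, ejection
fraction and mass by tracing endocardial and epicardial contours on a stack
of slices and summing cross-sectional areas times the effective slice
spacing (Simpson's slice-summation rule). The contouring convention is
ambiguous where papillary muscles and trabeculations (P&T) protrude into the
cavity: they can be counted as myocardium (the *including* convention,
`minc`) or swept into the blood pool behind a smooth contour along the
compacted myocardium (the *excluding* convention, `mex`). In hypertrophic
ventricles - the package's motivating case is the LV hypertrophy of Fabry
disease - P&T hypertrophy makes the choice consequential: the two
conventions can differ by 20% or more in mass, and the excluding convention
inflates stroke volume because systolic trabecular compaction moves tissue
across the smooth contour between end-diastole (ED) and end-systole (ES).

Real patient images for this comparison are not publicly available, so the
package pairs the measurement pipeline with a digital cine phantom that has
exact ground truth. Everything the pipeline reports can therefore be checked
against analytically known volumes, and phase-contrast aortic flow provides
the same internal stroke-volume reference that is used clinically.

## The phantom

`phantom_spec()` describes one ventricle; `build_phantom()` renders it:

* **Cavity**: a truncated half-ellipsoid (in-plane semi-axes `a`, `b`,
  long axis `c`; base plane at `z = 0`). The smooth (compacted-myocardium)
  cavity volume contracts by `ejection_fraction_true` over a raised-cosine
  cycle; the in-plane semi-axes scale as the square root of the volume
  factor while the long axis is held fixed.
* **Compact wall**: a concentric shell whose thickness interpolates from
  the ED to the (thicker) ES value.
* **Papillary muscles**: cylinders with elliptical end caps, attached near
  the mid-cavity wall at fixed angles, moving inward with contraction. The
  caps matter: flat cylinder ends aligned with slice sampling planes create
  whole discs of exactly half-filled voxels, a degenerate partial-volume
  configuration no real anatomy produces.
* **Trabeculations**: a sinusoidal radial perturbation of the endocardial
  surface (default 12 ridges per revolution, long-axis taper), with a
  minimum-depth floor (`trabecular_min_depth`, default 1.6 mm): where the
  ridge field is shallower than the floor no tissue exists, so ridges are
  discrete finger-like structures rather than infinitesimally thin wings
  that no segmentation - manual or automatic - could resolve or would count.
  The ridge amplitude interpolates from its ED to its smaller ES value:
  systolic compaction. Tissue that the contracting smooth surface overtakes
  is re-labelled compact wall, which is the second, geometric route of
  compaction.
* **Imaging**: voxelization by sub-voxel supersampling (partial volume),
  bSSFP-like contrast (blood 500 a.u., myocardium 200 a.u., background
  20 a.u.), additive Gaussian noise (SD 12 a.u. by default; an
  approximation to Rician noise valid at this signal-to-noise ratio), 8 mm
  slices with a 2 mm gap, 1.4 mm pixels, 20 phases. A blood-only slab above
  the base emulates the atrium/outflow tract and exercises the basal
  slice-selection rule.
* **Velocity series**: through-plane aortic velocity maps with a blunt
  plug profile (order-16 power-law boundary layer, the physiological shape
  for the ascending aorta - a Poiseuille parabola would put half the lumen
  below half-maximum speed and make any peak-speed ROI detector miss half
  the area). Per-phase amplitudes are scaled so the discrete systolic
  forward integral over the true lumen equals the cavity volume lost
  between consecutive phases, exactly, before noise. Ground truth is
  computed from the same geometry before noise is added.

`cohort_preset()` holds two calibrated parameter distributions. The
constants were derived by closed-form inversion of the target cohort means
(half-ellipsoid and shell volumes, cylinder volumes, mean ridge depth) and
then refined against the rendered voxel model; they are fixed numbers in
`R/phantom-presets.R`. Targets are the published cohort means this phantom
family emulates: control 163/54 ml ED/ES blood volume, 130/113 g mass
including/excluding P&T (P&T fraction 0.13); hypertrophic 127/34 ml,
178/144 g (fraction 0.20) with ~11 ml of P&T volume compacting away between
ED and ES. Between-subject spread uses modest log-normal size and parameter
jitter; heights and weights are adult-male normals (178 +/- 7 cm,
80 +/- 10 kg, truncated positive), which the study population does not
report and we therefore choose once.

What the phantom does **not** model: torso/coil sensitivity, k-space
artifacts and bSSFP banding, arrhythmia or breath-hold misregistration,
long-axis shortening, regurgitant flow, and through-plane motion of the
aortic plane. Passing tests on the phantom therefore demonstrate
correctness of the measurement chain under ideal acquisition, not
robustness to those confounders.

## The segmentation

`segment_subject()` replaces the protocol's manual tracing with
deterministic operators. The two numeric rules of the protocol are applied
verbatim; everything else is a documented default of this implementation.

1. **Intensity classes.** A three-class k-means split (background /
   myocardium / blood) with deterministic range-based initialization;
   thresholds are midpoints between adjacent cluster centres, which for
   ideal two-tissue mixing sits at the 50% partial-volume point. If the
   blood and myocardium classes separate by fewer than 3 pooled
   within-class SDs the subject is rejected with a diagnostic
   (`lvpnt_contrast_error`) - this catches pure-noise and flat inputs.
2. **Phase selection.** The blood-pool volume curve (largest bright
   component per slice, slice-summed) is computed for every phase; ED is
   its maximum and ES its minimum, ties to the earliest phase
   (`find_ed_es_phases()`).
3. **Smooth endocardial region.** The key geometric step. The anchor is
   the compact wall thickness: on the epicardial distance transform,
   blood pixels that touch myocardium cannot be shallower than the wall,
   so the minimum of their depths estimates it; the smooth cavity is the
   epicardial region deeper than that, a contour parallel to the
   epicardium along the compacted myocardium. This stays well defined at
   ES, when compacted trabeculae and papillary muscles crowd out the blood
   pool. (A convex hull of the blood pool - the fallback used on apical
   slices with too few wall-adjacent blood samples - collapses there, and
   morphological closing can never recover wall-attached structures: a
   disc avoiding the pool always fits just outside the rim.)
4. **Free-wall reference.** Sample mean and sample SD (n - 1) of the raw
   intensities in the lateral 120-degree mid-wall sector of a
   mid-ventricular ED slice (`freewall_reference_stats()`). The sector
   centre is configurable; rotating it is one of the nuisance
   perturbations used to emulate repeated human reads.
5. **P&T classification.** The protocol rule: a cavity pixel is P&T when
   its intensity lies within 1 SD of the free-wall mean
   (`classify_pnt()`, two-sided inclusive band; with SD = 0 the band
   degenerates to exact equality). Band hits seed myocardium-class
   connected components inside the smooth region, so whole structures are
   outlined, as a human would. Components whose in-plane width falls
   strictly below 1.5 mm are returned to the blood pool
   (`filter_thin_trabeculae()`; width is operationalized as survival of a
   morphological opening with a disc of that diameter, rounded to whole
   pixels - at 1.4 mm spacing the rounded threshold is one pixel and the
   filter is a no-op, since nothing below the threshold is resolvable).
6. **Cavities.** The blood-only (`minc`) cavity is everything blood-class
   inside the epicardium plus the unclassified remainder of the smooth
   region, minus confirmed P&T; disconnected end-systolic blood pockets
   between trabeculae stay cavity. The smooth-contour (`mex`) cavity is
   the wall interior united with P&T, closed with a 5 mm disc
   (`smooth_endocardial_contour()`), so P&T land in the blood pool.
7. **Slice selection.** The basal slice is the first (from the base) in
   which at least 50% of the cavity boundary touches myocardium - the wall
   mask is opened first so a one-pixel partial-volume rim does not count
   as enclosure; the apical slice is the last showing intracavity blood
   pool (`select_slices()`). Mass summation additionally extends past the
   apical blood slice to the last slice with epicardium, because the
   apical cap still carries myocardium.

Epicardial masks are produced at ED only and endocardial masks at ED and
ES, matching the tracing protocol; no ES/ED mass-matching step is
performed.

## Quantification and flow

`ventricular_measures()` computes, per convention: EDV, ESV, SV = EDV -
ESV, EF = 100 SV / EDV, and mass at ED (myocardial volume times 1.05 g/ml,
the conventional density; the source protocol does not state one). Indexed
mass uses Mosteller body surface area, `sqrt(height * weight / 3600)` -
again a documented choice, affecting only the indexed value. The P&T mass
fraction is `100 * (LVM_inc - LVM_ex) / LVM_inc` (`pnt_fraction()`).
Internally everything is full precision; rounding to table precision is
left to the caller.

`detect_vessel_roi()` finds the aortic lumen as the largest region whose
temporal-peak speed exceeds half the global peak, grown by hysteresis into
the low-velocity boundary layer (neighbours join while their peak speed
stays above a fifth of the core threshold - noise floors do not reach it).
`integrate_flow()` sums velocity times pixel area over the ROI per phase
and integrates the forward (positive) per-phase flow over the cycle.
Forward-only integration is a documented simplification: the phantom
models no regurgitation, so nothing is lost; on real data with aortic
insufficiency it would overestimate net flow.

## Statistics

`paired_t()` and `independent_t()` wrap the classical tests (Welch form by
default between groups; the source protocol says only
"independent-samples"), with explicit degenerate-input errors instead of
misleading output when differences are constant. `bland_altman()` returns
the mean difference, SD of differences, mean +/- 1.96 SD limits of
agreement and the coefficient of repeatability (1.96 SD of differences;
some literature uses 2 SD - the multiplier is an argument).
`cohort_table()` assembles the group-by-method summary (mean +/- SEM,
within-group paired p-values between conventions, between-group p-values
per convention); `flow_concordance()` tests volumetric minus aortic stroke
volume against zero. `observer_repeatability()` emulates repeated
measurement by re-rendering each subject's noise and rotating the
free-wall sector before re-segmenting; this is a stand-in for human
intra-/inter-observer variability, not a claim of equivalence to it.

## Numerical choices and degenerate inputs

* Ties in phase selection go to the earliest phase; ties in ground-truth
  voxel labels go to blood before wall before P&T (fixed column order).
* Masks are binary pixel grids; slice index 1 is the most basal slice;
  all physical widths are converted through `pixel_spacing`.
* Supersampled ground truth uses class-fraction sums (continuous), so it
  is slightly larger than any binary mask can measure for sub-pixel
  tissue; the ridge depth floor keeps such tissue out of the phantom. For
  noiseless validation an *odd* supersampling factor is used, because
  even factors place sub-samples symmetrically across stepped edges and
  mass-produce exact 50% partial-volume ties whose classification is
  arbitrary.
* Degenerate inputs error with classed conditions
  (`lvpnt_validation_error`, `lvpnt_contrast_error`,
  `lvpnt_segmentation_error`, `lvpnt_flow_error`,
  `lvpnt_degenerate_error`) rather than returning quiet nonsense.

## Validation design and problem sizes

The test suite validates the chain at three levels, with sizes chosen so
the full suite runs in about a minute: worked examples and closed forms
(exact); property tests on reduced phantoms (8-10 phases, supersampling
1-2); and a full-size synthetic cohort of 20 hypertrophic subjects at the
package defaults for the cohort-level checks - measured P&T mass fraction
near 20%, volumetric-minus-aortic stroke volume within 1 ml under the
including convention, and an excluding-convention overestimation inside
the published band. Noiseless single-subject validation (20 phases,
supersampling 3) checks volumes and mass within 3% of ground truth and
per-class mask overlap (Dice) of at least 0.95. `scripts/acceptance.R`
re-runs the cohort-level computation end to end and writes the three
headline numbers as JSON.

## Known limitations

* The excluding-convention stroke-volume overestimation on the
  hypertrophic preset runs at 13-14 ml, in the upper half of the
  published 11 +/- 4 ml band: at end-systole the measured P&T volume
  saturates against the crowded cavity, a geometric effect the simple
  ellipsoid-plus-ridges anatomy exaggerates somewhat.
* On the control preset the measured P&T fraction is faithful, but with a
  thin (7 mm) wall the wall-thickness anchor is more sensitive to the
  sub-pixel placement of the compacted surface than in thick-walled
  ventricles; fraction errors of 1-3 percentage points can occur at
  1.4 mm pixels.
* The normal-range reclassification count reported in the motivating
  study depends on external indexed-mass thresholds that are not public;
  `run_pipeline()` exposes the cutoff as a user input
  (`lvm_index_cutoff`) and reports exceedance counts only when one is
  supplied.
* All validation is synthetic; see the phantom's non-goals above for what
  that does and does not establish about real acquisitions.

## A short tour

```{r tour, eval = FALSE}
library(lvpnt)

subjects <- generate_cohort("fabry", 20, seed = 42)
measures <- measure_cohort(subjects)
tab <- cohort_table(measures)
tab$summary

flow_concordance(measures, "minc")   # ~0-1 ml: included P&T conserve SV
flow_concordance(measures, "mex")    # ~13-14 ml overestimation

rep <- observer_repeatability(subjects, perturbation_seed = 1)
ggplot2::autoplot(rep$lvedv)

seg <- segment_subject(subjects[[1]]$cine)
plot_volume_curve(seg)
plot_segmentation_overlay(subjects[[1]]$cine, seg)
```
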