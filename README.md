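# lvpnt

Dual-convention left-ventricular (LV) quantification on synthetic short-axis
cine MRI, for researchers studying how the treatment of papillary muscles and
trabeculations (P&T) changes ventricular measures — particularly in
hypertrophic ventricles such as those of Fabry disease, where P&T carry a
disproportionate share of the myocardial mass.

Cine MRI quantifies LV volumes and mass by contouring a short-axis stack and
summing slice areas times the effective slice spacing (Simpson's rule):

- **EDV, ESV** — cavity volume at end-diastole / end-systole (ml)
- **SV** = EDV − ESV; **EF** = 100·SV/EDV (%)
- **LVM** — myocardial volume at end-diastole × 1.05 g/ml (g), optionally
  indexed to Mosteller body surface area (g/m²)

Two endocardial conventions coexist. Including P&T in the myocardium
(`minc`): structures with signal within 1 SD of the free-wall myocardial
signal are outlined as myocardium, discarding structures thinner than
1.5 mm. Excluding P&T (`mex`): the endocardial border follows a smooth path
along the compacted myocardium and P&T join the blood pool. The P&T mass
fraction is `100·(LVM_inc − LVM_ex)/LVM_inc`. Velocity-encoded aortic flow,
integrated over the lumen and the cardiac cycle, provides an internal
stroke-volume reference that arbitrates between the conventions.

Because suitable patient images are not public, the package ships a digital
cine phantom — half-ellipsoid cavity, concentric wall, cylindrical papillary
muscles, sinusoidal trabecular ridges with systolic compaction,
partial-volume voxelization, Gaussian noise, and a matched aortic velocity
series — with exact ground truth, plus calibrated `control` and `fabry`
cohort presets. Everything the pipeline measures can be checked against
known truth.

## Worked example

```r
library(lvpnt)

subjects <- generate_cohort("fabry", 20, seed = 42)   # ~1 min
measures <- measure_cohort(subjects)

minc <- subset(measures, method == "minc")
mex  <- subset(measures, method == "mex")

mean(minc$pnt_fraction_pct)        # 19.84  — % of LV mass that is P&T
mean(minc$lvsv - minc$aortic_sv)   # 0.64   — ml, volumetric vs aortic SV
mean(mex$lvsv - mex$aortic_sv)     # 14.15  — ml, overestimation when P&T
                                   #          are swept into the blood pool
```

Read: on a 20-subject hypertrophic cohort, P&T contribute about 20% of LV
mass; stroke volume measured with P&T *included* matches the aortic-flow
reference to within a millilitre, while *excluding* P&T overestimates it by
roughly 14 ml, because trabecular tissue compacts across the smooth contour
between diastole and systole. Cohort tables, paired/independent tests and
Bland-Altman repeatability come from `cohort_table()`, `flow_concordance()`,
`bland_altman()` and `observer_repeatability()`; `run_pipeline()` writes a
full CSV/JSON report bundle, and `write_subject_nifti()` exports NIfTI
series. See the vignette (`vignettes/lv-pnt-quantification.Rmd`) for the
model, the segmentation operators and the calibration.

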