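# vncaskel

Whole-skeleton virtual non-calcium (VNCa) bone-marrow quantification from
dual-energy CT, for imaging scientists studying marrow infiltration in
multiple myeloma and related haemopathies.

Whole-body CT finds the osteolytic lesions that define myeloma bone disease,
but diffuse plasma-cell infiltration of the marrow precedes visible bone
destruction. A paired low/high tube-voltage acquisition (90 / 150 kVp)
measures two attenuation values per voxel, which lets the mineral component
be projected out and the attenuation of the underlying marrow read directly:
fatty (yellow) marrow sits near −100 HU, cellular (red) marrow near +50 HU,
and infiltration shifts the calcium-subtracted value upward. This package
implements the complete analysis over the whole imaged skeleton:

- **Three-material decomposition.** Each voxel `(L, H)` is solved exactly as
  `Y + s·(R − Y) + t·(k, 1)` with yellow marrow `Y = (−108, −84)` HU, red
  marrow `R = (52, 51)` HU and calcium slope `k = 1.65`; the VNCa value is
  the attenuation of the calcium-free point `Y + s(R − Y)`, affine in the
  marrow coordinate `s`: `VNCa = −96 + 147.5·s` HU.
- **Skeleton segmentation.** Bone-window (W 1800 / L 400) median
  normalization, a fixed 120 HU initial threshold, two iterations of 3-D
  morphological Chan–Vese active contours (`mu = lambda1 = lambda2 = 1`),
  then rule-based refinement (slice hole-filling, metal removal above
  3000 HU, low-HU soft-tissue cleanup).
- **Quantification.** Whole-skeleton first-order histogram statistics (mean,
  median, sample SD, skewness `g1`, excess kurtosis `g2`) and circular
  regional / lesion ROIs under the reading protocol (≤ 5 lesions, diameter
  > 5 mm).
- **Cohort statistics.** Tie-corrected Spearman correlation (exact
  permutation p for n ≤ 8), Wilcoxon signed-rank (exact 2^n enumeration for
  n ≤ 12), median/IQR summaries.
- **Phantom cohort.** A seedable generator of paired-energy volumes with
  ground-truth masks and coupled clinical covariates, so the whole chain is
  testable without patient data.

## Worked example

Simulate a 21-subject cohort, run the full pipeline (decompose → segment →
quantify → stats) and print the study report:

```r
library(vncaskel)
cfg <- pipeline_config(n_subjects = 21, seed = 7)
res <- run_pipeline(cfg)
print(res)
```

```
pipeline_result: 21 subject(s) analysed, 0 failure(s)
Whole-skeleton VNCa: median -66.6 HU (IQR -74.7, -54.1)
  vs infiltration_pct: Spearman rho +0.973, p = 1.623e-13 (n = 21, approximate)
  vs haemoglobin: Spearman rho -0.817, p = 6.229e-06 (n = 21, approximate)
  vs age: Spearman rho -0.079, p = 0.734 (n = 21, approximate)
  whole_vs_regional: Wilcoxon signed-rank: W = 2, p = 8.579e-05 (n_eff = 21, approximate); medians -66.6 vs -35.1
  whole_vs_lesion: Wilcoxon signed-rank: W = 0, p = 0.000143 (n_eff = 19, approximate); medians -67.8 vs 15.9
  notes: comparison with lesion_mean: 2 incomplete pair(s) dropped
```

Reading this: per-subject whole-skeleton mean VNCa values centre near
−67 HU — marrow that is mostly fatty but shifted up from the −96 HU yellow
endpoint by its cellular fraction. The correlation with the simulated biopsy
infiltration percentage is strongly positive and the haemoglobin correlation
negative (more infiltration → more red-like marrow → higher VNCa, and more
anaemia), age is uncorrelated by construction, and whole-skeleton values sit
well below both regional ROI values and focal-lesion values, the lesions
having lost their mineral and gained cellularity. Two subjects without
lesions are dropped from the lesion comparison, and the drop is logged.

The same stages are scriptable from a shell via `inst/cli/vncaskel`
(`simulate`, `decompose`, `segment`, `quantify`, `stats`, `run-all`,
`reference-summary`), reading and writing NIfTI volumes and CSV tables.

A published 21-patient table of per-subject whole-skeleton histogram values
ships as `inst/extdata/reference_cohort_histograms.csv` (accessor
`reference_cohort()`); applying `cohort_median_iqr()` to its mean column
gives a median of −59.9 HU and lower quartile of −66.3 HU.

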