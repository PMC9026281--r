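---
title: "Whole-skeleton virtual non-calcium marrow quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-skeleton virtual non-calcium marrow quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vncaskel)
```

## The problem

In multiple myeloma, clonal plasma cells infiltrate the bone marrow. Whole-body
CT detects the osteolytic lesions that this eventually produces, but diffuse
marrow infiltration precedes visible bone destruction. Dual-energy CT offers a
quantitative handle: because calcium attenuates much more strongly at low tube
voltage than at high voltage, while marrow fat and cellular marrow differ only
mildly between energies, a paired 90/150 kVp acquisition lets one *subtract*
the mineral component of every voxel and read off the attenuation of the
underlying marrow. Cellular (red) marrow sits near +50 HU; fatty (yellow)
marrow near -100 HU; plasma-cell infiltration shifts the calcium-subtracted
value upward. This package implements the full analysis chain over the *whole
imaged skeleton* rather than a handful of reader-chosen regions: decomposition,
skeleton segmentation, first-order histogram statistics, and the cohort-level
rank statistics, plus a synthetic phantom cohort that makes the chain testable
end to end.

## The three-material model

Each voxel's two-energy measurement $(L, H)$ (HU at low and high energy) is
modelled as a point in the plane spanned by the marrow line and the calcium
direction:

$$(L, H) \;=\; Y + s\,(R - Y) + t\,(k, 1),$$

where $Y = (-108, -84)$ and $R = (52, 51)$ are the two-energy coordinates of
pure yellow and red marrow, $k = 1.65$ is the calcium slope (HU gained at low
energy per HU gained at high energy along the mineral direction), $s$ is the
marrow-line coordinate (0 = yellow, 1 = red), and $t \ge 0$ is the mineral
amount expressed as its high-energy HU contribution. These constants are the
vendor's bone-marrow decomposition defaults for this acquisition. The system
is a plain $2\times 2$ linear solve per voxel (`vnca_decompose_voxel()`), with
determinant $(R_L - Y_L) - k\,(R_H - Y_H) = -62.75$ for the default basis, so
it is well-conditioned and exact — no iteration, no tolerance.

The **virtual non-calcium (VNCa)** value reported for a voxel is the
attenuation of its calcium-free point $Y + s(R - Y)$. Which energy that HU
number refers to is not published by the vendor; this package reports, by
default, the 50:50 mix of the point's two-energy coordinates, so that VNCa
values sit on the same scale as the 120 kVp-equivalent weighted-average
viewing images (`convention = "mix"`, with `"low"` and `"high"` selectable).
Under the default basis the VNCa value is affine in $s$:
$\mathrm{VNCa} = -96 + 147.5\,s$, i.e. $-96$ HU for pure yellow and $+51.5$ HU
for pure red marrow. Two properties pin the implementation down and are tested
directly: adding any amount of mineral along $(k, 1)$ leaves VNCa unchanged to
$10^{-9}$, and decomposition exactly inverts the forward voxel model.

## Skeleton segmentation

Segmentation follows a fixed, randomness-free recipe on the 50:50
weighted-average image:

1. **Window and normalize.** HU are clipped to the bone window
   $[L - W/2,\, L + W/2]$ with $W = 1800$, $L = 400$, the volume median of the
   clipped values is subtracted, and the result is rescaled affinely to
   $[0, 1]$. Median *subtraction* (rather than division) is used because HU
   medians are routinely zero or negative; the operation is monotone, so voxel
   ordering is preserved.
2. **Initial contour.** A fixed 120 HU threshold on the *raw* weighted-average
   values, with a closed comparison (a voxel at exactly 120 HU is included).
   Keeping the threshold on raw HU keeps the printed value meaningful, while
   the contour evolution runs on the normalized image.
3. **Morphological active contour.** Two iterations of the morphological
   Chan–Vese scheme minimizing
   $\mu\,\mathrm{Length}(C) + \lambda_1 \int_{\text{inside}} |I - c_1|^2
   + \lambda_2 \int_{\text{outside}} |I - c_2|^2$ with
   $\mu = \lambda_1 = \lambda_2 = 1$. Each iteration refits the region means
   $c_1, c_2$, flips voxels in the morphological-gradient zone by the sign of
   $\lambda_1 (I - c_1)^2 - \lambda_2 (I - c_2)^2$ (an exact tie leaves the
   voxel untouched), then applies $\mu$ rounds of the alternating
   sup-inf / inf-sup smoothing pair built from the standard nine
   $3\times3\times3$ planar structuring elements. $c_1$ and $c_2$ are fitted
   quantities, never user-set constants; $\lambda_1 = \lambda_2 = 1$ is the
   configured equality. Everything runs in 3-D.
4. **Refinement.** Optional per-slice 2-D hole filling (the
   radiologist-in-the-loop step that captures fatty long-bone marrow; off by
   default), removal of metal (raw HU above 3000, plus one dilation ring),
   removal of non-filled mask voxels below a 100 HU floor, and optional crop
   boxes. The floor implements the pipeline's low-side "further HU
   thresholding" cleanup: the skeleton threshold search domain lies above
   100 HU, so mask voxels below it are soft tissue or CSF. Voxels added by the
   explicit fill step are exempt, because that step exists precisely to retain
   low-HU marrow.

One numerical point deserves emphasis. Morphological curvature smoothing is a
discrete curve-shortening flow: it rounds sharp concave corners. On a
voxelized cavity enclosed by bone (spinal canal, skull interior) this
permanently annexes a one-voxel rim of corner voxels — reference
implementations of the same operators behave identically — even though the
data term correctly classifies those voxels as background. The 100 HU
refinement floor removes exactly this rim (soft tissue at ~35 HU), which is
why the final masks contain no cavity voxels at all. Without the floor the
masks would carry a ~1-2% cavity rim, which is worth knowing if you disable
refinement.

Degenerate contour states (empty inside or outside region) return the state
unchanged with a warning by default so that batch cohort runs survive a bad
subject; `strict = TRUE` raises instead.

## Quantification

Whole-skeleton statistics are first-order histogram moments over the masked
VNCa voxels: mean; median (middle order statistic, mean of the two middles for
even counts); sample SD ($n-1$); skewness $g_1 = m_3 / m_2^{3/2}$; and
kurtosis reported as *excess* kurtosis $g_2 = m_4/m_2^2 - 3$ (a raw-kurtosis
switch exists, since published tables rarely state the convention and
heavy-tailed marrow histograms are consistent with either). Sample rather than
population denominators were chosen and are stated here because the published
table does not say which it used.

Circular ROIs use the voxel-centre-in-circle rule on a single axial slice —
the simplest exactly reproducible membership rule; partial-volume weighting is
deliberately out of scope. The reading protocol is enforced: at most 5 lesion
ROIs per subject, each with diameter strictly greater than 5 mm; regional
(vertebral / iliac analog) ROIs are exempt from the diameter rule.

## Cohort statistics

Spearman's correlation ranks both variables with midranks for ties and takes
the Pearson correlation of the rank vectors. The two-sided p-value is exact —
all $n!$ permutations enumerated — for $n \le 8$, and the $t$ approximation
with $n-2$ degrees of freedom above that. The Wilcoxon signed-rank test drops
zero differences, midranks $|d|$, reports $W = \min(W^+, W^-)$, and computes
the two-sided p exactly by enumerating all $2^n$ sign assignments for
effective $n \le 12$, else by normal approximation with tie-corrected variance
and continuity correction. Both cutoffs are configurable; the defaults keep
every exact branch well under a second while covering the sample sizes where
exactness matters. Missing data are handled pairwise-complete per analysis,
and every drop or skipped analysis is logged in the report rather than
silently swallowed — in a 21-subject cohort where only 15 have biopsies, which
subjects entered which analysis is part of the result.

Median/IQR summaries use linear interpolation between order statistics at
positions $1 + (n-1)p$ (base R's type 7) by default, with type 6 and type 8
estimators selectable. On the packaged 21-patient reference table this
estimator reproduces the published median (-59.9 HU) and lower quartile
(-66.3 HU) exactly; the published upper quartile (-51.8 HU) is not
reproducible from the printed column by any standard estimator (type 7 gives
-53.3 HU), so no claim is made about it.

## The phantom cohort

The generator exists so that every stage above can be tested against known
ground truth without any patient data. It is CT-like in *topology*, not
anatomy: a soft-tissue body cylinder (35 HU) in air (-1000 HU) containing a
spine analog (cortical annulus, radius 8-10 voxels, around a trabecular core
around a 3-voxel spinal-canal cavity), a skull analog (spherical cortical
shell around a brain cavity), and two long-bone tubes with marrow cores —
64×64×96 voxels at 2 mm spacing, small enough that a full-cohort run takes
about a minute. Only the shell-plus-cavity structure matters to the
segmentation math.

Tissue HU are formed by the *forward* material model, so decomposition tests
are exact round trips: cortical bone carries 600 units of mineral
(weighted-average ≈ 700 HU, dense cortical bone), trabecular compartments 180
units (vertebral trabecular ≈ 150-200 HU depending on marrow composition) —
both realistic CT values, and both chosen so the noiseless skeleton sits above
the 120 HU threshold, as real mineralized bone does. The marrow red fraction
follows an affine link to biopsy infiltration,
$f = \mathrm{clip}(0.2 + 0.6\,\mathrm{inf}/100)$, scaled per site (spine 1.0,
long bones 0.6 — adult long-bone marrow is fattier). The link is an assumption
of the generator, not an extraction from any measurement: no per-patient
marrow-composition ground truth exists to fit it. Its strength is dialled by
`rho_inf` (1 = deterministic link, 0 = independent), implemented by mixing an
independent uniform variate into the infiltration signal. Haemoglobin
decreases in infiltration (default slope -0.35 g/L per percent, SD 8 g/L
around a 145 g/L intercept, matching the anaemia patterns of such cohorts),
age is drawn around 67 ± 8 years, infiltration itself from three equal strata
(≤10%, 11-60%, >60%) mirroring the tertile structure typical of biopsy-graded
cohorts. Lesions (0-5 per subject, more likely with higher infiltration;
6-9 mm diameter; mineral deficit 60-100%; red-marrow excess 0.2-0.5) are
spheres placed wholly inside the spine's trabecular annulus, and ~15% of
subjects carry a 10 000 HU metal prosthesis replacing part of one long bone.
Noise is i.i.d. Gaussian per energy image, independent between energies,
default SD 15 HU — the simplest model that exercises robustness; correlated
noise is deliberately not the default.

What the phantom does *not* emulate: partial-volume mixing at compartment
boundaries, beam hardening and scanner reconstruction effects, anatomical
variation, and spatially correlated noise. Passing tests therefore demonstrate
that the *algorithms* are implemented correctly and recover known structure
under idealized imaging, not that the pipeline meets any clinical performance
bar on real scans.

## Design choices made where the design was open

- **1-based `(x, y, slice)` indexing.** R arrays and every R imaging package
  index from 1; the package states the convention once and uses it everywhere,
  including the CLI.
- **VNCa reporting convention.** 50:50 mix, documented and configurable (see
  above), because the vendor convention is unpublished.
- **No masking inside decomposition.** The VNCa map is computed everywhere,
  air included; selecting marrow-bearing voxels is segmentation's job. The
  stages stay orthogonal and individually testable.
- **$\mu$ as smoothing rounds.** The boundary-length penalty of the
  morphological scheme is realized as the number of alternating smoothing
  rounds per iteration; $\mu = 1$ means one round.
- **Exactness cutoffs** ($n \le 8$ permutation Spearman, $n \le 12$ Wilcoxon
  enumeration) keep exact branches sub-second; both are arguments, not
  constants.
- **Problem sizes in tests.** Phantom tests run on the default 64×64×96 grid;
  contour-convergence properties are asserted on balls of radius 10 voxels,
  where discrete curvature flow genuinely attains Dice ≥ 0.99 (at radius 7 the
  staircase band alone caps agreement near 0.96, for this and for reference
  implementations of the same operators alike). Pipeline-level covariate
  recovery uses 50 subjects at coupling 0.9.

## Known limitations

- The segmentation is tuned for the shell-plus-cavity topology and a fixed
  window/threshold; pathologically osteopenic bone below 120 HU at the
  weighted average would be missed, exactly as in the semi-automatic protocol
  it reproduces (where a radiologist supplies fill slices).
- Histogram statistics assume the mask selects marrow-bearing voxels; cortical
  voxels map to the yellow end of the marrow line and dilute whole-skeleton
  means toward -96 HU. This mirrors the whole-skeleton protocol rather than a
  marrow-only ideal.
- The exact Wilcoxon enumerates $2^n$ assignments and the exact Spearman $n!$
  permutations; raising the cutoffs far beyond the defaults is exponential.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(n_subjects = 21, seed = 7)
res <- run_pipeline(cfg)
print(res)
```

The result object carries the per-subject table (whole-skeleton moments,
regional and lesion ROI means, covariates), the study report (median/IQR,
the three Spearman correlations, the two Wilcoxon comparisons, and the log of
any skipped analyses), and a manifest sufficient to re-run the analysis
bit-for-bit.
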