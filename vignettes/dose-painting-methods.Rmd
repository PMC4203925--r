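---
title: "Methods: threshold-based dose painting and plan comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-based dose painting and plan comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosepaint)
```

## The model

Dose painting prescribes a spatially non-uniform radiation dose from a
biological image. `dosepaint` implements the discrete-level variant used in
veterinary and early clinical planning studies: the tumor (GTV) receives a
base dose everywhere, a threshold defines a high-risk sub-volume from PET
uptake, and the sub-volume is split into `n_levels` equal-width uptake bins,
each escalated by a linear rule. The underlying assumption is a linear
association between tracer uptake and required dose — biologically crude,
but the convention that commercial planning systems can deliver.

All uptake is handled as the standardized uptake value (SUV, dimensionless).
Within the GTV let `SUV_max` be the maximum, `SUV_c` the cut-off expressed
in percent of `SUV_max`, and `SUV_iso` a bin midpoint on the same scale. A
level's prescription, in percent of the base dose, is

```
Dose(%) = 100 + (SUV_iso - SUV_c) / (100 - SUV_c) * (E - 100)
```

with escalation ceiling `E = 150%` by default. The cut-off maps to 100% and
`SUV_iso = 100` would map to `E`; the top bin's midpoint sits below 100, so
the highest prescribed level stays below the ceiling (65.25 Gy vs 67.5 Gy
for five bins at 45 Gy base). For equal-width bins the bin midpoints satisfy
`(SUV_iso,k - SUV_c) / (100 - SUV_c) = (2k - 1) / (2n)`, so the level
percentages are independent of the cut-off: five levels always receive 105,
115, 125, 135, 145% of base. This cut-off invariance is a useful sanity
check — any dependence of the dose ladder on the threshold indicates a
binning bug — and it is asserted in the test suite over random cut-offs.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `base_dose_gy` | 45 | Gy | dose at 100%, delivered to the whole GTV |
| `max_escalation_pct` | 150 | % | ceiling of the linear rule |
| `n_levels` | 5 | – | number of escalation bins |
| threshold (tracer A) | 40 | % of SUV_max | glycolysis-tracer cut-off |
| threshold (tracer B, early) | 1.4 | SUV | hypoxia-tracer cut-off (~10 mmHg) |
| threshold (tracer B, late) | 2.0 | ratio | tumor-to-muscle; see below |
| QI band | [0.95, 1.05] | ratio | satisfactory voxelwise dose ratio |
| `bin_width_gy` | 0.5 | Gy | joint histogram resolution |
| `delivery_sigma_mm` | 0 | mm | optional delivery-blur surrogate |

No published cut-off exists for late (≈24 h) hypoxia-tracer scans; the
tumor-to-muscle method is the accepted fallback and the default ratio of
2.0 is this package's choice, always echoed in the outputs so a user cannot
mistake it for an external standard. The muscle reference statistic is the
mean SUV over the muscle ROI (the median would also be defensible; the mean
is the simplest convention and is stated here so results are interpretable).

## Conventions and numerical choices

- **Bins** are half-open `[lower, upper)` with the top bin closed at 100% of
  max, so the partition of the sub-volume is exact and the argmax voxel is
  always in the top level. A voxel exactly at the cut-off belongs to DP1,
  and a cut-off at exactly 100% of max selects the argmax voxel set rather
  than being flagged empty.
- **Axial axis** is the third voxel index. A level confined to one axial
  slice is degenerate (not a volume an arc-therapy optimizer will accept);
  `drop_degenerate_levels()` assesses validity on the levels as built, then
  merges each degenerate level's voxels into the nearest lower surviving
  level — the voxels keep an escalated dose, only the top prescription is
  lost, matching clinical plan-transfer behavior. With no surviving lower
  level the voxels revert to the base dose.
- **Grid identity** is required, not checked approximately: shapes exactly,
  spacing/origin within 1e-6 mm (float header round-trip noise).
  Registration and resampling are out of scope.
- **Doses** are carried at full precision; CSV reports round to 0.1 Gy and
  QI fractions to 2 decimals; JSON keeps full precision. Cohort means are
  unweighted arithmetic means of unrounded per-case values.
- **QVH curve** is the survival-function convention (fraction of voxels
  with ratio ≥ x) on a fixed grid 0…2 step 0.001; the QI band is a closed
  interval. The ratio direction is numerator = covering plan, denominator =
  reference plan.
- **Dice with two empty masks is undefined** and reported as `NA`, never 0
  or 1 — top levels often vanish, and 0/0 must not fabricate agreement.
  `NA` levels are excluded from trend averages.
- **Delivery surrogate.** Arc-therapy optimization and dose calculation are
  deliberately out of scope; `emulate_delivery()` offers a clearly labeled
  stand-in: support-normalized Gaussian blur (the zero-prescription region
  is treated as missing, not as true zero dose), which preserves constants
  exactly and conserves the GTV mean dose to well under 1% for sigma up to
  3 mm on targets of clinical size.

## The phantom: what it emulates, and what it does not

`generate_phantom()` produces the study conditions the pipeline is tested
under: a 48³ grid at 2 mm isotropic spacing; an ellipsoidal GTV of 63.3 ccm
(the cohort-average tumor volume; axis ratio 1:1.2:0.8 so that thin
top-level caps — and hence single-slice degeneracy — genuinely occur); a
muscle slab at constant background SUV 0.7 with 5% CV noise; and two tracer
fields with SUV_max 12.5 and 2.8, the cohort-average glycolysis- and
hypoxia-tracer maxima.

Uptake heterogeneity is modeled as a Gaussian random field: white noise
filtered with a Gaussian of width `smoothness_mm` (default 4 mm, of the
order of a PET point-spread function), standardized, and mixed from a
shared and two tracer-specific fields as

```
Z_i = sqrt(|rho|) * s_i * L_shared + sqrt(1 - |rho|) * L_i,   s_a = 1, s_b = sign(rho)
```

which gives the two latent fields correlation exactly `rho`. (A mixing
coefficient of `rho` with residual `sqrt(1 - rho^2)`, the other common
construction, would give correlation `rho²` between two fields built this
way; the square-root mixing is what makes the `correlation_rho` knob mean
what it says.) Inside the GTV the latent field passes through a softplus
(strictly positive, monotone — thresholding behaves as it would on real
uptake) and is rescaled linearly so the within-GTV maximum equals `suv_max`
exactly.

The phantom is calibrated only to scalar summaries of a five-case canine
cohort (volumes, maxima, background); it makes no claim of distributional
realism, contains no scanner physics (PSF, attenuation, scatter,
reconstruction noise), no pharmacokinetics, and its GTV is convex. Passing
tests therefore demonstrate the *pipeline's* correctness and the metrics'
behavior under controlled correlation, not performance on clinical images.

## Design choices in the property experiments

Two choices in the stochastic tests deserve explanation.

*Equal tracer maxima in the correlation sweep.* With unequal maxima over a
common positive background, the two tracers' percent-of-max scales are
related by an affine (not proportional) map, so the per-level annuli of the
two plans misalign systematically even at `rho = 1`. The sweep that checks
"overlap degrades as correlation drops" therefore fixes
`suv_max_a = suv_max_b`, making `rho` the only varied factor; the unequal
default maxima remain in place everywhere else.

*Cumulative Dice for the level trend.* Per-bin Dice of the thin middle
annuli is noisy, and at high correlation the tiny top bins of both plans sit
on the shared peak, producing a U-shaped profile. The cumulative
(super-threshold) variant compares nested high-dose regions, measures
co-localization of "dose ≥ level k" directly, and is monotone in both level
and correlation; the trend test uses it. Both variants are available
(`dice_per_level(..., mode =)`), with per-bin the reporting default.

Problem sizes in the suite: the partition oracle runs on 50 random 8³
volumes against a brute-force per-voxel loop; the correlation/trend
experiment uses 20 seeds × 3 correlations on a 30³ grid with a 30 ccm GTV;
the full-size 48³ phantom is exercised in the end-to-end and degeneracy
tests. These sizes give stable averages (Monte-Carlo error on the mean
correlation ≈ 0.04) while keeping the default test run fast.

## Known limitations

- Prescription maps stand in for optimized, deliverable plans. The
  comparison metrics are computed on what the planner is *asked* to
  deliver; differences introduced by beam optimization are not modeled
  (the optional Gaussian blur is a blunt surrogate).
- Printed per-case dose ranges in clinical reports (e.g. DP4 60.3–60.8 Gy)
  cannot arise from the exact equal-bin rule, which is cut-off-invariant;
  they likely reflect workstation rounding of bin boundaries. This package
  does not round during segmentation and reproduces the level means, not
  the ranges.
- With `n = 5` cases in the motivating cohort, cohort summaries are
  descriptive (per-case values and means); no inferential statistics are
  provided, by design.
- Tumor-to-muscle thresholding for late scans rests on a package-chosen
  default ratio; conclusions sensitive to that cut-off should be checked
  over a range of ratios.
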