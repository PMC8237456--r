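---
title: "Modelling hybrid CFRT + SBRT/SIB plan parameters from anatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hybrid CFRT + SBRT/SIB plan parameters from anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridplan)
```

## The problem

Locally advanced (stage III) non-small-cell lung cancer presents two
distinct targets: the primary tumour (PT) and the mediastinal lymph-node
disease (LN). Hybrid planning treats them with different fractionations in
one course: conventionally fractionated radiotherapy (CFRT, ~2 Gy per
fraction) of the nodal target plus a stereotactic boost of the primary.
`hybridplan` models the two regimes

* **C&S** — CFRT 2 Gy × 30 to PTV~LN~, then an SBRT boost 12.5 Gy × 4 to
  PTV~PT~;
* **C&SIB** — CFRT 2 Gy × 26 to PTV~LN~, then a sequential 4-fraction plan
  that combines 2 Gy × 4 to PTV~LN~ with a 12.5 Gy × 4 integrated boost to
  PTV~PT~.

Because the two components use very different fraction sizes, a hybrid plan
is scored twice: on the summed *physical* dose and on the summed
*EQD2-corrected* dose, in which the boost component is converted voxel-wise
to the equivalent dose in 2-Gy fractions before summation. The package then
asks the knowledge-based-planning question: how well are the resulting plan
parameters predicted by the patient's anatomy alone, via simple regression
models on geometry features?

## The radiobiological model

Under the linear-quadratic model, a total dose $D$ delivered in fractions
of $d = D/n$ is equivalent to

$$\mathrm{EQD}_2 = D\,\frac{d + \alpha/\beta}{2 + \alpha/\beta}$$

in 2-Gy fractions. Two consequences drive the whole analysis:

* at $d = 2$ Gy the conversion is the identity, so the CFRT component is
  never converted (`sum_hybrid()` adds it as-is);
* at the boost prescription ($D = 50$ Gy, $d = 12.5$ Gy) with lung
  $\alpha/\beta = 3$ Gy the factor is $15.5/5 = 3.1$: lung tissue at the
  edge of the boost sees roughly three times its physical dose in EQD2.

```{r}
eqd2_scalar(50, 4, 3) / 50
```

Per-voxel $\alpha/\beta$ is resolved by structure priority
(`alpha_beta_map()`): targets (10 Gy) outrank spinal cord (2), esophagus
(10) and heart (3), which outrank lung (3); unassigned voxels take a
configurable default (3). Only the lung value is anchored in the
radiobiology convention this analysis follows; the others are defaults and
deliberately configurable. No LQ extensions (time factors, LQ-L) are
modelled.

**Boost prescription adjustment.** The nodal CFRT plan deposits unintended
dose in the primary target. `adjust_boost_prescription()` converts that
dose (its D99) to EQD2, subtracts it from the EQD2-corrected boost
prescription and converts the remainder back to a fraction dose. The
conversion back is genuinely ambiguous — "in proportion" could mean a
physical rescaling or an exact inversion of the quadratic. We default to
exact inversion (`invert_eqd2()`, the positive root of
$n\,d\,(d + \alpha/\beta) = E\,(2 + \alpha/\beta)$) because it makes the
delivered boost EQD2 equal the remaining EQD2 by construction, and expose
the proportional variant behind `mode = "proportional"` for comparison.

## Plan parameters

For a summed dose grid and a structure set, `plan_parameters()` computes
the conformity index $CI = V_{RX}^2 / (TV \cdot V_{RI})$ (nodal target and
PT+LN union at 60 Gy; primary target at 140 Gy in the EQD2 domain only),
the homogeneity index $HI = D_5/D_{95}$, lung V~20~ and mean dose (total
and ipsilateral), spinal-cord maximum, heart D~5~/D~30~/maximum/mean, and
esophagus maximum and V~50~. Numerical conventions, chosen so every metric
is exactly checkable by voxel counting:

* $D_x$ is the sorted-voxel empirical inverse CDF ("higher" side): the
  `ceiling(p/100·n)`-th largest voxel dose, not a DVH interpolation;
* maximum dose is the maximum voxel value (no 0.035-cc clinical-maximum
  convention, which the source analysis does not specify);
* V~x~ is a voxel fraction in percent; esophagus V~50~ is reported in %
  (the original unit is not stated — a volume flag would be a one-line
  change);
* the DVH helper uses 0.05 Gy bins, and all test tolerances are at least
  one bin;
* the PT+LN union counts overlap voxels once; $V_{RI} = 0$ yields CI 0
  with a warning rather than NaN.

The 140 Gy EQD2 level for the primary-target CI is treated as a plain
threshold input; with the default tumour $\alpha/\beta$ of 10 Gy the
phantom plans peak near 100 Gy EQD2 and the metric reports 0 (flagged), so
it is retained for interface completeness rather than fitted.

## Geometry features

`extract_features()` reduces a structure set to the feature vector used by
the regressions: target volumes (cc) and the neck-corrected nodal volume,
target-to-lung volume ratios (corrected and uncorrected), minimum surface
distances (cm) from the primary target to the nodal target, esophagus and
heart, signed cranio-caudal overlap thickness (cm), and the overlap-volume
ratios of heart∩LN (to heart and to LN — the latter is the S-type models'
predictor) and esophagus∩LN (to esophagus). Decisions where the definition
was open:

* minimum distance is true 3D Euclidean distance between voxel centres
  (exact anisotropic distance transform), not a projected 2D distance —
  the conservative, testable reading;
* overlap thickness is defined purely on cranio-caudal slab extents
  (outer slice faces), which is what lets it go negative when the axial
  spans are disjoint;
* neck-node components are identified by explicit component tags
  (`"neck_node"`), not by automatic anatomical classification;
* lung ratios use the delineated lung masks as given; internal-target
  subtleties of lung minus tumour delineation are not modelled.

## The synthetic cohort

No clinical images ship with the package; two generators stand in.

**Voxel phantoms** (`make_phantom()`): two lung ellipsoids, a heart
ellipsoid, esophageal tube and cord cylinder, a spherical primary-target
PTV and a prolate (2:1:1) nodal PTV. Three geometry features are directly
controllable because the analysis turns on them: the PT–LN surface gap
(solved analytically from the sphere-to-ellipsoid distance), the signed
cranio-caudal overlap (solved from slab extents), and the heart–LN overlap
volume (solved by bisection on the heart's anterior offset, defaulting to
an overlap ratio of ~0.07, the cohort median). Defaults reproduce the
cohort's central anatomy (primary PTV 30.7 cc in 10.9–100.1, nodal PTV
199.5 cc in 24.8–452.3, gap 4.0 cm in 1.2–7.1, overlap 1.9 cm in
−4.5–6.1); a seeded jitter varies organ positions across a cohort. At
extreme combinations the two targets' controls couple (a large axial gap
bounds the surface gap from below); the generator then realizes the
closest feasible geometry.

**Analytic dose** (`make_dose()`): each component is a prescription
plateau inside its target (optionally with a centre-weighted hotspot, 10%
for the boost), a thin at-prescription shell out to a margin (1 mm boost,
2.5 mm CFRT — this is what keeps conformity indices below 1 and
anatomy-dependent), a sigmoid falloff in signed surface distance reaching
the 50% isodose within 6 mm for the boost (12 mm for CFRT), and a small
exponentially decaying scatter floor. The integrated-boost plan is the
voxel-wise maximum of its PT and LN components. This emulates the
*dosimetric consequences* of planning (coverage, falloff, interaction of
nearby targets) but none of its mechanics — no beams, fluence, optimizer
or CT densities — so tests passing on phantoms demonstrate correctness of
the measurement and modelling chain, not planning realism.

**Feature cohorts** (`sample_feature_cohort()`): features drawn uniformly
over the cohort ranges (only medians and ranges are known; no distribution
shape is assumed), parameters generated by evaluating a model catalog at
the features plus Gaussian noise *on each model's link scale* (log for
S-type). Zero noise reproduces the catalog exactly, which is what makes
coefficient-recovery tests exact. The residual noise level of the real
cohort is unknown; `noise_sd` is a test parameter, not an estimate.

## Regression families

Following the classical curve-estimation convention of the statistics
package the analysis emulates, all four families are ordinary least
squares on transformed variables — never iterative nonlinear fits:

| form | model | fit |
|---|---|---|
| `linear_multi` | $y = b_0 + \sum b_i x_i$ | OLS |
| `s_type` | $y = e^{b_0 + b_1/x}$ | OLS of $\ln y$ on $1/x$ |
| `inverse` | $y = b_0 + b_1/x$ | OLS of $y$ on $1/x$ |
| `cubic` | $y = b_0 + b_1 x + b_2 x^2 + b_3 x^3$ | OLS |

$R^2$ for the transformed families is reported on the link scale — that is
what the fit minimizes and what the emulated software reports. Goodness
bands: high $R^2 \ge 0.7$, moderate $[0.5, 0.7)$, poor below. Correlation
bands: high $r \ge 0.8$, moderate $[0.6, 0.8)$. S-type and inverse fits
drop rows outside the family's domain ($x \le 0$, and $y \le 0$ for
S-type): anatomies with no heart–LN overlap fall outside the S-type
models' support, mirroring the restriction of those models to overlapping
cases. Spearman's $r$ is the Pearson correlation of mid-ranks; its p-value
uses the t approximation for $n \ge 10$ and a permutation null below
(exhaustive to $n = 6$), with a locally fixed RNG state so pipelines stay
deterministic. p-values are the overall F for the linear families and the
slope t-test for the two-parameter ones; no multiplicity correction is
applied.

**The bundled catalog.** Four heart S-type equations are published with
coefficients and are bundled verbatim
(`bundled_catalog()`, provenance `"printed-with-coefficients"`):
$e^{8.11 - 0.024/x}$ and $e^{7.677 - 0.017/x}$ (heart D~30~ and mean heart
dose, stereotactic-boost regime), $e^{8.098 - 0.024/x}$ and
$e^{7.656 - 0.017/x}$ (integrated-boost regime). Their response unit is
nowhere stated; $e^{8.11} \approx 3327$ is only plausible as cGy, so the
catalog declares cGy and makes it an overridable attribute. Every other
model row is published with an $R^2$ only and is stored as form+predictor
metadata that refuses to predict until refitted on a cohort.
`synthetic_reference_catalog()` fills those rows with documented synthetic
coefficients (provenance `"synthetic"`) so that fully specified cohorts can
be generated; its integrated-boost lung coefficients sit slightly above the
stereotactic ones, giving regime comparisons a defined ground truth. Where
the running text and the figure caption disagree on which predictors enter
a linear model, the caption's list is taken as canonical.

## The pipeline

`run_pipeline()` chains cohort → Spearman concordance → fits →
holdout prediction → regime comparison, deterministically under one seed,
and writes the report tables as CSV. The default holdout of 2 mirrors the
two-new-patient validation design. Problem sizes used by the shipped
analysis scripts and tests — 6–12 phantoms at 4–5 mm voxels, feature
cohorts of 10–40 — were chosen as the smallest sizes at which every
qualitative behaviour (coverage, EQD2 inflation, coefficient recovery,
regime ordering) is stable and exactly testable.

One subtlety: even a boost prescribed at 2 Gy per fraction does not make
the EQD2 and physical tables identical on voxel phantoms, because falloff
voxels receive *less* than 2 Gy per fraction and deflate under conversion;
the identity holds exactly only for uniform 2 Gy/fraction dose, and that
is how it is tested.

## Limitations

* The dose model is phenomenological; absolute parameter values on
  phantoms should not be read clinically.
* The published patient-cohort $R^2$ values are not reproducible without
  the patient data; what the package verifies is exact coefficient
  recovery, band classification, and the internal consistency of the
  analysis chain.
* DICOM RT input is not parsed; masks and doses enter as NIfTI, arrays, or
  planar contours (`rasterize_contours()`).
* Non-lung $\alpha/\beta$ values and the esophagus V~50~ unit are
  conventions, kept configurable because the source analysis leaves them
  unstated.
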