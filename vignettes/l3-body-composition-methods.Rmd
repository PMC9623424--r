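---
title: "Methods: L3 body composition and test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: L3 body composition and test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l3bodycomp)
```

## The measurement problem

Cross-sectional areas of adipose tissue and skeletal muscle on a single
axial CT slice at the third lumbar vertebra (L3) correlate strongly with
whole-body compartment volumes, which makes *opportunistic* CT — scans
acquired for staging or unrelated indications — an attractive, cost-free
source of body-composition measurements for oncology cohorts. Using such
scans longitudinally raises a measurement question: when the same patient is
imaged years apart, around an intervention such as breast-cancer surgery,
how much of the change in measured areas is real biology and how much is
measurement unreliability? This package implements both halves of the
answer: the segmentation pipeline that produces per-scan areas, and the
paired reliability statistics that quantify their test–retest behaviour.

## Segmentation model

Every pixel of the L3 slice is classified by the conjunction of an
attenuation condition and a spatial condition:

* **HU windows.** Adipose tissue is `[-190, -30]` HU for subcutaneous (SAT)
  and intermuscular (IMAT) fat and `[-150, -50]` HU for visceral fat (VAT).
  Skeletal muscle is split into five density classes — very low (VLDM), low
  (LDM), normal (NDM), high (HDM) and very high density (VHDM) — spanning
  `-29` to `200` HU. Lower-density muscle indicates fattier, myosteatotic
  muscle.
* **Compartment prior.** SAT, IMAT and VAT overlap completely in HU; they
  are distinguished only by anatomical compartment (subcutaneous rim,
  muscular ring, visceral cavity). The compartment map is a required input,
  standing in for radiologist-guided delineation; no automatic fascia
  detection is attempted.

Two conventions deserve explanation because the published windows alone do
not determine them:

* **Shared endpoints.** The muscle windows are conventionally quoted as
  touching ranges (`0–35`, `35–101`, `101–151`, `151–200` HU). Classifying
  on closed versions of those intervals would double-count the boundary
  values, so the scheme assigns each shared integer endpoint to the
  lower-density class: VLDM `[-29, 0]`, LDM `[1, 35]`, NDM `[36, 101]`,
  HDM `[102, 151]`, VHDM `[152, 200]`. `validate_threshold_scheme()`
  enforces that the muscular-compartment intervals tile `[-190, 200]`
  exactly once; the scheme is a YAML file, so alternative endpoint policies
  can be explored explicitly.
* **Visceral pixels outside the VAT window.** Because the visceral-fat
  window is narrower than the generic fat window, visceral pixels in
  `[-190, -151]` or `[-49, -30]` HU remain unclassified rather than being
  silently absorbed; organ parenchyma (positive HU) likewise stays
  unclassified.

Areas are pixel counts times the physical pixel area
(`row_spacing × col_spacing`, supporting non-square pixels), reported in
cm². Total adipose tissue (TAT) is SAT + IMAT + VAT and total skeletal
muscle (TSM) the sum of the five muscle classes — identities, computed
exactly.

## Waist circumference

The body mask is `HU ≥ -250` (midway between air and soft tissue; the
threshold is a package choice, not a published value). The largest
8-connected component is kept, interior holes are filled, and the external
contour is taken as the 0.5 iso-level of the mask after Gaussian smoothing
(SD 2 px). Smoothing matters: the iso-contour of a raw binary mask follows
pixel-edge midpoints and systematically misestimates the perimeter of
oblique boundaries, whereas the smoothed mask's 0.5 level tracks the true
sub-pixel boundary of a convex body. On phantoms this contour reproduces
the analytic circle perimeter and the Ramanujan ellipse perimeter to about
0.05% — comfortably inside the 1% the tests demand. An active-contour
("snake") model would add parameters without adding accuracy on this task;
the iso-contour is deterministic and parameter-free. The contour is traced
in physical mm coordinates, so anisotropic pixels are handled by
construction.

## Reliability statistics

**Percent change** of a group mean is `100 × mean(post − pre) / mean(pre)`.
It is computed from the mean *difference*, not from independently rounded
pre and post means: published change tables are internally consistent under
this reading at two decimals, while re-deriving the difference from rounded
means is not (the bundled `reference_change_table()` demonstrates both
facts).

**Wilcoxon signed-rank test.** Zero differences are dropped (classic
convention; the count is reported), absolute differences are ranked with
midranks for ties, and `W = min(W+, W−)`. With ≤ 15 nonzero differences
and no ties the two-sided p-value is exact, computed from the full null
distribution of `W+` via the generating polynomial `∏(1 + x^r)`; otherwise
a normal approximation with tie correction and continuity correction is
used. The exact branch is verified in the tests against brute-force
enumeration of all `2^n` sign assignments, and both branches against an
independent implementation of the same conventions.

**ICC(3,1).** Test–retest reliability is the single-measure, consistency
form of the intraclass correlation under the two-way mixed model: patients
are random, the measurement occasion (pre vs post surgery) is fixed. From
the subjects × occasions layout,

$$\mathrm{ICC}(3,1) = \frac{MS_B - MS_E}{MS_B + (k-1)\,MS_E},$$

with `MS_B` the between-subjects mean square and `MS_E` the residual after
removing subject and occasion effects (`k = 2` here). Consistency means a
constant pre→post shift does not reduce the ICC — appropriate when the
question is whether patients keep their rank order, not whether the scanner
is unbiased. The two-sided 95% CI uses `F = MS_B/MS_E` with `n−1` and
`(n−1)(k−1)` degrees of freedom. Negative estimates arise legitimately in
small, noisy strata and are reported exactly as computed, never clamped;
the original software behind published ICC tables does not document its CI
method, so exact numeric agreement with any particular package is not
claimed, only agreement with the standard F-based interval for this model.

**Stratification.** Paired records are split at a cutoff of 3 years,
converted at 365.25 days/year with the boundary inclusive on the within
side ("three or fewer years apart"): 1095 days is within, 1096 beyond.
Incomplete pairs are dropped listwise with a logged count. Quartiles use
linear interpolation of order statistics (type 7); a published convention
is not stated, so this default is documented rather than inferred.

## The phantom: what it emulates and what it does not

`generate_l3_phantom()` renders concentric ellipses — subcutaneous fat rim,
muscular ring with randomly placed IMAT disks (radius 3–8 mm), visceral
cavity with VAT disks in organ parenchyma, central vertebral bone disk —
and records every pixel's true tissue. Default HU means (SAT/IMAT/VAT
−100/−80/−90; VLDM −15, LDM 20, NDM 60, HDM 125, VHDM 175; organ 40; bone
400) each sit at least 10 HU interior to their threshold interval, so
noise of SD ≤ 3 HU essentially never flips a class; with zero noise,
segmentation reproduces the ground truth pixel for pixel, which is the
package's strongest end-to-end invariant. The default muscle-class mix
(0.146/0.278/0.501/0.048/0.027) follows the approximate area shares of the
five classes in published L3 cohorts.

The phantom deliberately does **not** emulate anatomy (organ shapes, bowel
gas, vertebral posterior elements), scanner physics (beam hardening,
reconstruction kernels, slice thickness) or inter-scanner harmonisation;
noise is a single Gaussian SD knob. Passing phantom tests therefore
demonstrates that the *rules* are implemented correctly — thresholds,
compartment constraints, unit conversions, contour arithmetic — not that
the pipeline is robust to real-scan artefacts, which require the manual
compartment maps the protocol assumes anyway.

## The cohort simulator: reliability known by construction

`generate_paired_cohort()` realizes exactly the two variance components
that define the ICC: patient truth `T_i ~ N(μ, σ_b²)`, observations
`T_i + e` with `e ~ N(0, σ_w²)`, plus an optional systematic post-shift,
so `theoretical_icc()` = `σ_b²/(σ_b² + σ_w²)` is exact by design. Defaults
mirror a published opportunistic-CT breast-cancer cohort: n = 50 pairs,
per-tissue population means from its presurgery table, inter-scan interval
N(590.6, 536.8²) days floored at 1, and σ_b = 30, σ_w = 10 cm² giving a
designed ICC of 0.90 in the range the cohort reported. Negative area draws
are truncated at zero with a warning — resampling would distort the
variance components more than truncation does at these defaults, though
for tissues whose mean is small relative to σ_b (e.g. VHDM) truncation is
common and the *truncated* distribution is then the simulator's ground
truth. The image-level mode (`write_phantom_cohort()`) renders every
simulated scan as a phantom whose compartment geometry is scaled so the
rendered areas hit the simulated targets (exactly for count-allocated
tissues, to ~0.5% discretization error for the elliptical rims), producing
DICOM + compartment-map + manifest inputs for true end-to-end runs.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 512-px, 1-mm phantoms for
segmentation-fidelity checks (a realistic abdominal field of view);
400-px phantoms for the waist oracles; 128-px, 3-mm phantoms where only
the rules are exercised; 500 replicate cohorts at n = 50 for ICC recovery
and CI coverage; and a 10-patient rendered cohort for the end-to-end
pipeline check. These sizes give Monte-Carlo standard errors well inside
the tolerances asserted (e.g. SE ≈ 0.002 on the mean ICC over 500
replicates against a 0.02 band) while the full suite runs in seconds.
Degenerate inputs are contracts, not surprises: an all-zero difference
vector is a "no change" result, ICC on constant data is an explicit error,
a single observation summarises with SD 0 and a warning, and HU values are
clamped to the 12-bit CT range `[-1024, 3071]` with a logged count.

## Limitations

The package takes the selected L3 slice and its compartment map as inputs:
it does not locate vertebral levels, draw fascias, read compressed or
multi-frame DICOM, or attempt volumetric analysis. Reliability statistics
assume complete pre/post pairs and a two-level (pre/post) design; other
ICC forms (agreement, average-measures, one-way) are out of scope. The
cohort-specific ICC point estimates of any particular patient population
cannot be reproduced without its scans; what the package guarantees
instead is that its estimator agrees with the ANOVA definition to
numerical precision and recovers designed reliability on cohorts where the
truth is known.
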