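# l3bodycomp

Body composition from opportunistic CT at the third lumbar vertebra (L3),
with the statistics needed to trust it longitudinally.

Clinical CT scans acquired for staging or unrelated indications can be
reused ("opportunistically") to measure a patient's adiposity and skeletal
muscle: on a single axial slice at L3, cross-sectional tissue areas
correlate strongly with whole-body compartment volumes and predict outcomes
in oncology cohorts. This package is for researchers who want to extract
those measurements from archived scans and, crucially, to know how reliable
they are when the same patient is imaged years apart — for example around
breast-cancer surgery.

It provides:

* **Segmentation** — compartment-constrained Hounsfield-unit thresholding of
  an L3 slice into three adipose depots (subcutaneous SAT, intermuscular
  IMAT, visceral VAT; windows `[-190, -30]`, `[-190, -30]`, `[-150, -50]`
  HU) and five muscle density classes (VLDM/LDM/NDM/HDM/VHDM partitioning
  `[-29, 200]` HU), plus waist circumference from the body contour. SAT,
  IMAT and VAT overlap in HU and are separated by a compartment map (the
  spatial prior a radiologist would draw). Totals are identities:
  TAT = SAT + IMAT + VAT, TSM = sum of the five muscle classes.
* **Reliability statistics** — percent change on group means
  (`100·mean(post−pre)/mean(pre)`), Wilcoxon signed-rank tests (exact for
  small tie-free samples, normal approximation with tie and continuity
  corrections otherwise), and the single-measure consistency intraclass
  correlation under the two-way mixed model,

  ICC(3,1) = (MS_B − MS_E) / (MS_B + (k−1)·MS_E),

  with F-based 95% confidence intervals, overall and stratified by
  inter-scan interval (≤ 3 years vs longer, at 365.25 d/y).
* **Synthetic ground truth** — an L3 phantom generator (concentric ellipses
  with fat blobs, exact per-pixel truth) and a paired-cohort simulator with
  known between-/within-patient variance components, so the designed ICC is
  known by construction and every stage is testable without patient data.
* **I/O** — single-frame DICOM read/write with explicit HU rescaling,
  compartment maps as 8-bit PNG, YAML threshold schemes, CSV manifests and
  reports.

## Worked example

Segment a synthetic L3 slice and quantify it:

```r
library(l3bodycomp)

ph <- generate_l3_phantom(phantom_spec(noise_sd = 2, seed = 42))
labels <- segment_tissues(ph$slice, ph$compartments)
compute_areas(labels, ph$slice,
              waist_cm = measure_waist_circumference(ph$slice))
#> <body_composition> patient PHANTOM, NA
#>    SAT   IMAT    VAT   VLDM    LDM    NDM    HDM   VHDM    TAT    TSM
#> 306.36   7.39  52.74  19.54  37.40  66.73   6.54   3.60 366.49 133.81
#> waist: 93.27 cm
```

The areas are cm² at the phantom's 1 mm pixels: 306 cm² of subcutaneous
fat in the rim, 53 cm² of visceral fat in the cavity, 134 cm² of total
muscle in the ring; the waist (93.3 cm) is the body-ellipse perimeter. At
`noise_sd = 0` these equal the phantom's ground truth exactly.

Simulate a 50-patient paired cohort designed to have ICC 0.90
(σ_between = 30, σ_within = 10 cm²) and estimate its reliability:

```r
cs <- paired_cohort_spec(n_patients = 50, mean_areas = c(VAT = 118.2),
                         sigma_between = 30, sigma_within = 10, seed = 42)
co <- generate_paired_cohort(cs)
theoretical_icc(cs)
#> [1] 0.9
icc_3_1(co$pre, co$post)
#> ICC(3,1) = 0.899 (95% CI 0.828 to 0.941), n = 50, k = 2
wilcoxon_signed_rank(co$post - co$pre)
#> Wilcoxon signed rank (normal approximation): W = 615, n = 50 (0 zeros dropped), p = 0.8318
```

The estimate (0.899) recovers the designed reliability, and the Wilcoxon
test correctly finds no systematic pre/post shift (none was simulated).

For a full end-to-end run, `write_phantom_cohort()` renders a simulated
cohort as DICOM files with compartment maps and a manifest, and
`run_cohort(manifest, pipeline_config(out_dir = "report/"))` produces the
change table, overall and interval-stratified ICC tables, interval
summaries, `report.md` and `run.log`. The same pipeline runs from a shell
via the thin wrapper in `inst/exec/l3bodycomp`
(`simulate` / `segment` / `run` subcommands).

A bundled reference table (`reference_change_table()`) carries the
published pre/post change statistics of a 50-patient breast-cancer cohort
for arithmetic cross-checks and realistic simulator defaults.

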