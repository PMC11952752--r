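---
title: "rootshoot: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rootshoot: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootshoot)
```

`rootshoot` quantifies root and shoot growth of agar-grown seedlings from
flat-bed plate scans and carries the measurements through to heritability
estimates and post-GWAS haplotype tests. This vignette documents the
models behind each stage, the tunable parameters with their defaults and
units, and the choices made where more than one reasonable design exists.

## 1. Pixel classification

A scanned plate contains three visually distinct materials: green shoot
tissue, white (near-achromatic, bright) root tissue, and the blue or dark
agar background. Classification is rule-based rather than learned: each
class is defined by a conjunction of per-channel threshold intervals in
one or more color spaces, and a pixel takes the first class whose full
rule set it satisfies, in the fixed priority order shoot > root >
background.

Defaults (all configurable via `seg_params()`):

| class | rule set (all conditions ANDed) |
|---|---|
| shoot | HSV hue ∈ [60°, 180°] ∧ saturation ≥ 0.25 ∧ value ≥ 0.20 |
| root | HSV saturation ≤ 0.20 ∧ value ≥ 0.60 |
| background | anything else |

Rationale: green foliage occupies the mid-hue band at moderate-to-high
saturation over a wide brightness range; roots imaged on a scanner are
bright and nearly colorless, so a low saturation cap plus a brightness
floor isolates them; the background needs no rule of its own. Under
these defaults the two rule sets are mutually exclusive (a pixel cannot
be both saturated and unsaturated), but the priority order is defined
anyway so that arbitrary user-supplied rule sets still yield a strict
partition — every pixel gets exactly one label.

Two open design points were resolved as follows. First, conditions
within a class combine **conjunctively** (AND): interval rules in several
spaces then carve a convex-ish region per class, which is predictable to
tune; a disjunctive semantics can be emulated by loosening a single
space's intervals. Additional Lab or YCbCr constraints are therefore
optional extra conjuncts, default off. Second, conversions assume sRGB
primaries with D65 reference white; HSV hue is reported in degrees,
saturation/value in [0, 1], Lab in its native scale, YCbCr as full-range
BT.601.

No white-balance correction is applied before thresholding. The three
target classes are far apart in color space, so small illumination casts
do not move pixels across a class boundary; this keeps the pipeline free
of a per-batch calibration step.

Per-channel histogram equalization (the standard cumulative-histogram
remapping, with the occupied-minimum normalization so the lowest occupied
intensity maps to 0) is available via `equalize = TRUE` but **off by
default**: the default thresholds were chosen for unequalized scans, and
equalization of a plate that is mostly background stretches the
background's own noise more than it helps the foreground.

## 2. Mask cleanup and plant extraction

Two cleanup passes run per class, in this order:

* **Island removal** — connected components smaller than `min_island_px`
  (default 20 px) are relabelled background. At typical scan resolution
  a germinated seedling's organ is comfortably larger than 20 px,
  whereas dust, condensation droplets and compression speckle are not.
* **Border-object removal** — components of the combined foreground mask
  with any pixel within `border_margin_px` (default 2 px) of the image
  edge are relabelled background, default on. "Boundary" artifacts
  could alternatively be handled by cropping a fixed plate frame;
  removing border-touching components was chosen because it needs no
  knowledge of the frame geometry, and a margin of 0 (or the flag)
  disables it. Partially cropped plants at the image edge are thereby
  discarded rather than under-measured.

Both passes are idempotent, so re-running cleanup on an already-clean map
is a no-op (tested).

A seedling is one biological object but two color classes, and the root
often attaches to the rosette through a hypocotyl only one or two pixels
wide that may classify as neither class. Plant extraction therefore
dilates the union foreground mask by `bridge_radius_px` (default 5 px, a
Euclidean disc) before connected-components labelling, then transfers
the component labels back to the **undilated** pixels, so the bridge
never inflates area counts. Connectivity defaults to 8 because thin
diagonal root traces disconnect under 4-connectivity. Plants are
numbered left to right by centroid column. Plates carry an expected
plant count; a mismatch sets a machine-readable `qc_flag` on every row
of that plate and is never auto-corrected — downstream code and humans
can filter on the flag, but the measurement itself is left untouched.

The dilation radius bounds the geometry the pipeline can resolve: two
plants closer than about `2 * bridge_radius_px` px will merge into one
region (flagged via the expected count), and a shoot–root gap wider than
the radius will split a plant in two.

## 3. Growth model and derived statistics

Seedling area growth over the screening week is treated as exponential:
`A(t) = A0 * exp(r t)`. The rate `r` (per day) is estimated by ordinary
least squares of `ln A` on the untransformed day; `r²` and the number of
points used are reported alongside. The day grid is arbitrary; the
default scanning schedule is every second day from transfer (days 0, 2,
4, 6, 8). Zero or negative areas are dropped before the fit rather than
pseudo-counted: the logarithm is undefined there, and an early-day zero
shoot area is a segmentation dropout, not a measurement of absence. A
series with fewer than two positive observations is flagged
`fit_failed` and the pipeline continues.

Derived quantities:

* **Outlier pass** — within each genotype × condition (× organ) group,
  values farther than 3 population SDs (n denominator) from the group
  mean are removed in a **single** pass. Iterating the rule would keep
  shrinking the SD and remove points the criterion never named; groups
  of size ≤ 2 are never filtered because their SD estimate is
  meaningless.
* **STI** — the salt tolerance index of a trait is the genotype mean
  under salt divided by the genotype mean under control, undefined
  (missing, not an error) when the control mean is ≤ 0. The
  population-level "relative growth fraction" is the same ratio applied
  population-wide; because ratio-of-means and mean-of-ratios differ
  under genotype × treatment interaction, `relative_growth_fractions()`
  computes **both** and labels them.
* **Coordination** — the root:shoot rate ratio is computed per plant
  (undefined when the shoot rate is ≤ 0). Whether salt *spreads* this
  ratio across a population is a variance question, so each salt group
  is tested against control with the Brown–Forsythe test (one-way ANOVA
  on absolute deviations from group medians). No specific test is
  canonical for "the variance expanded"; Brown–Forsythe was chosen over
  Bartlett or an F-ratio test because ratio traits are heavy-tailed and
  the median-centered statistic is robust to that. Groups with n < 3
  are excluded with a warning.
* **Heritability** — broad-sense H² per condition from one-way
  random-effects variance components:
  σ²g = max(0, (MS_between − MS_within)/n̄) with
  n̄ = (N − Σnᵢ²/N)/(k − 1) for unbalanced designs, σ²e = MS_within,
  H² = σ²g/(σ²g + σ²e). The max(0, ·) truncation keeps H² in [0, 1];
  on balanced designs the estimate equals the intraclass correlation
  (cross-checked against a REML mixed model in the tests).

## 4. Association support

* **MAC-stratified Bonferroni** — SNPs with small minor allele counts
  give unstable association statistics, so correction is applied per
  MAC subpopulation: for cutoff m, n = #distinct SNPs with mac ≥ m
  (ties at the cutoff included, a SNP counted once across traits), and
  the bar is −log₁₀(α/n). A cutoff reached by no SNP yields an
  undefined row, not an error. Each SNP is then judged against the bar
  of **its own** stratum — the largest cutoff not exceeding its MAC —
  rather than one global threshold.
* **Locus clustering** — significant SNPs on one chromosome merge by
  single linkage when consecutive positions are within `window_bp`
  (default 10 000 bp, the typical genome-wide LD decay distance in
  *A. thaliana*; configurable). Loci are ranked by member SNP count,
  then trait count, then best −log₁₀ p, matching the prioritization
  logic of multi-SNP, multi-trait support. Positions are 1-based
  inclusive, as in VCF/GFF.
* **Haplotype grouping** — accessions sharing an identical allele
  pattern over the chosen SNPs (typically all SNPs in a candidate
  gene's coding region) form a haplotype. Accessions with **any**
  missing call over the subset are set aside and reported rather than
  treated as a third allele state: with short patterns a single NA
  would otherwise mint spurious haplotypes. Haplotypes with fewer than
  3 accessions are excluded from testing. Labels (H1, H2, …) follow
  descending member count with ties broken by pattern string — a
  determinism convention, not biology; labels are not comparable across
  datasets.
* **Phenotype test** — one-way fixed-effects ANOVA across retained
  haplotypes, Tukey HSD pairwise comparisons at α = 0.05, and a compact
  letter display built by insert-and-absorb. The letter display is
  exact by construction — groups share no letter **iff** some Tukey
  pair between them is significant — and the test suite verifies the
  equivalence pair by pair on randomized fixtures. The all-equal
  degenerate case (zero between- and within-group variance) is defined
  as F = 0, p = 1, one shared letter.

## 5. What the synthetic generators do and do not emulate

`generate_plate()` draws each plant as a filled disc (rosette proxy)
above a 1–3 px wide vertical root trace whose lateral position performs
a bounded ±3 px random walk; the trace starts one pixel inside the disc
so the drawn plant is always one 8-connected component. Class colors
default to the scanned-plate trichotomy (green/white/blue) with optional
per-channel Gaussian jitter; plants are placed on an even horizontal
grid with a minimum gap (default 12 px) chosen so that the default
bridge radius can never merge two plants, and infeasible layouts error
rather than overlap. The generator returns the exact drawn label map
and per-plant pixel counts, so segmentation can be scored without
re-deriving geometry, and identical seeds give byte-identical images.

What this deliberately does **not** emulate: overlapping or touching
plants, leaves occluding roots, agar reflections and condensation,
color gradients across the scanner bed, and JPEG artifacts. A green
segmentation suite on these fixtures therefore establishes contract
correctness (exact pixel accounting, component logic, QC flags) and
robustness to moderate additive color noise — not performance on
pathological real scans, which is what the QC flags and configurable
thresholds are for.

`generate_series()` adds multiplicative log-normal noise (σ on the log
scale, default 0.1 — about 10% area error, a realistic segmentation
repeatability) to an exact exponential; `generate_genotypes()` builds
distinct random SNP patterns, assigns accessions near-evenly, and adds
Gaussian noise to haplotype effect means. In the heritability recovery
check the drawn genotype effects are standardized to unit realized
variance, so the simulation states σ²g = 1 exactly rather than up to
sampling error of the effects draw — the check then measures estimator
recovery, not the luck of one draw.

## 6. Numerical and degenerate-input conventions

* Intensities are 8-bit integers; images are H × W × 3 arrays in
  row/column (matrix) orientation; coordinates are 0-based half-open in
  bounding boxes, 1-based inside R matrices.
* Equalization of a constant channel returns it unchanged (degenerate
  histogram).
* A constant area series fits rate 0 with undefined r² (0/0 total sum
  of squares) reported as `NA`.
* Guarded divisions (STI, rate ratio, correlation with zero variance)
  return missing values, never errors, so one degenerate plant cannot
  abort a screen.
* All generators and the CLI take explicit seeds; reruns with the same
  seed and config are bit-identical.

## 7. Known limitations

* Threshold classification has no spatial regularization; a green
  reflection on the agar larger than `min_island_px` will classify as
  shoot. The defaults were chosen for clean scans of the white/green/
  blue trichotomy.
* The exponential model is a screening-scale approximation; growth over
  longer windows saturates and would need a logistic or spline model,
  which is out of scope here.
* Heritability uses the moment (ANOVA) estimator; for strongly
  unbalanced designs with missing cells a REML mixed model is the
  better tool, and the balanced-design agreement shown in the tests is
  the supported regime.
* TIFF input is not supported (no reader in the dependency set); PNG,
  JPEG and plain-text PPM are.
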