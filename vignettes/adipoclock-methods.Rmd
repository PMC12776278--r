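---
title: "Methods: longitudinal tissue-age analysis of adipose transplants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal tissue-age analysis of adipose transplants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoclock)
```

## The experimental design this package models

Heterochronic transplantation grafts tissue between animals of different
ages; isochronic transplantation between animals of the same age is the
matched control. `adipoclock` models a four-group subcutaneous white
adipose tissue (WAT) design — young-to-young (YY), young-to-old (YO),
old-to-young (OY), old-to-old (OO) — plus sham-operated controls. Each
transplant unit contributes three samples: donor WAT *before*
transplantation, the same graft *after* a follow-up period, and the
recipient's untouched *native* WAT. The longitudinal Before/After pairing
within donor is what gives the design its power: biological-age change is
measured within grafts, not between animals.

Default design parameters follow the modeled study: young donors 4 months,
old donors 18 months, a 10-week (2.5-month) follow-up, graft mass 1% of
recipient body weight, and a configurable number of donors per group
(default 8; per-group sizes are not published, so they are a parameter,
never an inference).

## Linear clocks and the preprocessing contract

A clock is a sparse linear model over named features:
`value = intercept + sum(coef_i * x_i)`, with target scale either
chronological age or log-hazard (mortality clocks; predictions stay on the
log-hazard scale throughout). Methylation clocks apply directly to beta
values; transcriptomic clocks apply to processed expression with a fixed
five-step pipeline:

1. RLE (median-of-ratios) size-factor normalization;
2. `log2(x + 1)`;
3. per-feature z-scaling across samples (zero-variance features are set to
   0 rather than amplifying floating-point jitter);
4. injection of clock features absent from the data as constant rows at
   their stored imputation means;
5. centering by the per-feature median over young donor-before samples.

The provenance of each `processed_matrix` records exactly these five steps.
Where the published description is underspecified, the package fixes one
choice and documents it: the log is base 2 with pseudo-count 1; "scaling"
is per-feature standardization across samples; imputation happens after
scaling so imputed rows are constants on the processed scale; methylation
entropy is the mean per-CpG binary entropy in bits with beta clamped to
`[1e-6, 1 - 1e-6]`. The kernel-SVM mortality clock is represented in its
linear form only; kernel machinery is out of scope.

One numerical property worth knowing: under the median-of-ratios
definition, multiplying one sample's counts by a constant `c` moves the
geometric-mean reference by `c^(1/n)`, so the normalized matrix is
invariant only up to a single global factor. Between-sample ratios are
exactly invariant, and the per-feature standardization in step 3 removes
the residual constant, so clock predictions are unaffected. The test suite
asserts the invariance in this (correct) form.

## Longitudinal statistics

* **Within-group contrasts** fit `value ~ role + donor` by OLS with donor
  as a categorical fixed effect, reporting each non-reference role
  coefficient with its t-test p-value. Confounded designs (role constant
  within donor) raise a rank-deficiency error rather than returning NaN.
* **Between-group dynamics** fit `value ~ stage * group` for each pair of
  groups; the interaction coefficient is the difference in Before-to-After
  dynamics. All six group pairs form one BH family.
* **Measurement-error-aware contrasts** fit
  `value ~ stage + batch + (1 | donor)` by REML (lme4) with relative
  inverse-variance weights `1 / (sd_i^2 + 1e-8 * mean(sd^2))` built from
  the per-prediction standard deviations. Weights are *relative*: scaling
  every sd by a common factor leaves the fit unchanged, and all-zero sds
  give unit weights. This was a genuinely open design point — an additive
  "known variance plus residual" formulation is the main alternative — and
  the relative-weight form was chosen because it preserves the
  scale-invariance property and reduces exactly to the unweighted paired
  model when sds are equal and donor variance is zero. Satterthwaite
  degrees of freedom (lmerTest) supply p-values.
* **Sham calibration** regresses predicted age on chronological age over
  sham samples only (OLS); deviations
  `prediction - (intercept + slope * age)` isolate transplant effects from
  expected aging. With fewer than two distinct sham ages, an
  intercept-only fallback is fitted and flagged. The synthetic sham arm
  alternates young and old starting ages precisely so this regression is
  identifiable.
* **BH adjustment** is `stats::p.adjust(method = "BH")` behind input
  validation; every family is explicit at the call site and recorded in
  the run manifest.

## Clock deconvolution and the gene screen

For a linear clock, the Before-to-After change in predicted age decomposes
exactly: with `delta_i` the change in mean processed expression of feature
`i`, the contribution `coef_i * delta_i` sums to the prediction difference
between mean profiles — an identity, not an approximation, and the package
enforces it to `1e-9` in tests. Substituting externally estimated logFC
values (e.g. from the paired DE model) is supported behind a flag but
breaks exactness; the conservation-exact variant is the default.

Differential expression uses a paired linear model on
`log2` counts-per-million (CPM after RLE factors, pseudo-count 0.5):
`log2CPM ~ stage + donor` per gene. The published analysis used a
negative-binomial count framework for this step; that machinery is out of
scope here, and the paired linear model targets the same scientific
quantity (the within-donor stage effect on the log scale). The ranking
metric for downstream enrichment is `-log(p) * sgn(lfc)` with natural log
by default (the base is configurable, as the published form does not state
it).

The tissue-age-dynamics screen regresses expression on the donor-level
tAge change. Because that change is constant within donor, it is collinear
with donor fixed effects if entered directly; the identifiable encoding
used here is `dtage * 1[stage == after]`, i.e. the covariate acts on After
samples, alongside stage and donor terms. Genes at BH q < 0.05 form the
significant set, ordered deterministically by q, then |estimate|, then
gene ID. Pathway over-representation uses the one-sided hypergeometric
tail (Fisher's exact test for enrichment), run separately for positively
and negatively associated genes.

## Histology quantification

The classification rules are applied exactly as printed: lipid droplets
are segmented objects with mean RGB at least 190 on all channels and area
strictly greater than 10,000 px²; objects with any pixel within 20 px of
an image edge are excluded (interpreted as 0-based index < 20 or >=
dimension − 20); overlapping survivors are resolved greedily by descending
area with object ID as the deterministic tie-break. Nuclei require mean
R <= 150, G <= 150, B <= 200 and area strictly below 5,000 px². Collagen
pixels satisfy R in [170, 220], G in [190, 240], B in [210, 255]; the
collagen fraction divides by tissue area after excluding white space,
which this package defines as all channels >= 235 (the published text says
only "white spaces"; the threshold is configurable and recorded).
Droplet-size statistics use natural-log areas (mean, sd as the
heterogeneity score, and their standard errors, with
`sem(sd) = sqrt(sd^2 / (2(n-1)))`), after a seeded subsample of at most
200 droplets per sample.

The default segmentation backend is classical (brightness threshold, hole
filling, watershed on the distance transform); externally produced masks
— label TIFFs or run-length JSON, e.g. from a neural segmenter — are
accepted as input and pass through the same classification rules.

For 3D morphometry, volume is voxel count times voxel volume and
sphericity is `pi^(1/3) * (6V)^(2/3) / A`. No installed package provides
an isosurface mesh, so the surface area `A` comes from a
marching-tetrahedra extraction (Kuhn 6-tetrahedra cube decomposition) of
the 0.5 level set of the Gaussian-smoothed object indicator (sigma 1
voxel). Smoothing matters: on the raw binary field the staircase boundary
overestimates sphere areas by ~8%, while the smoothed mesh lands within
~2% (a digitized radius-10 ball measures sphericity 1.018, inside the
[0.95, 1.05] acceptance band; elongated rods score well below balls).
Vertex coordinates are scaled by the voxel dimensions, so anisotropic
stacks (e.g. 0.2 x 0.2 x 0.3 µm) are measured in physical units directly
rather than flagged and ignored. Sphericity is clamped at 1.05 to absorb
residual discretization overshoot. Mitochondrial density divides object
count by the cytoplasmic volume — a caller-supplied mask (the published
analysis excludes perinuclear regions by segmentation, which is a mask
input here, never an invented distance rule) or the full stack volume.

## What the synthetic generator emulates — and what it does not

The generator produces the full study: sample sheets for the 4 + sham
design, sparse linear clocks, count matrices with planted clock signal,
beta matrices with planted signal and detection-p failures, rendered
H&E-like sections, and labeled 3D volumes. Design conditions are fixed at
the modeled study's values (ages 4/18 months, 10-week follow-up, graft
mass fraction 0.01); noise uses the standard bulk RNA-seq negative
binomial, `Var = mu + phi * mu^2`, with `phi = 0` degenerating to
deterministic (rounded) means.

Planting clock signal under data-driven standardization requires care:
z-scaling forces every clock-gene row to zero mean and unit variance, so
arbitrary per-gene effect sizes cannot survive preprocessing. The
generator therefore works on the standardized scale directly: it builds an
orthonormal basis on the sample axis (the standardized target signal plus
two auxiliary directions), gives each clock gene a unit-norm combination
of the three, and solves a small closed-form system (a signed greedy
allocation plus a three-bin closed-polygon construction for the auxiliary
mass) so that the coefficient-weighted sum of rows equals the target
exactly. Counts are then obtained by inverting `log2(x/factor + 1)`, with
library-size factors normalized to unit geometric mean and the majority of
genes held constant so RLE recovers the factors exactly. The result: at
zero dispersion, pipeline predictions equal the recorded truth to
numerical precision (1e-6 and better), and planted Before-to-After group
shifts are exact in absolute clock units. Because standardization removes
absolute location, the truth's overall level is pinned to the clock
intercept; all downstream contrasts measure differences, which are
unaffected. Integer rounding of counts adds a quantization perturbation of
order `1/(mu * ln 2)` per gene; clock genes are simulated well-expressed
(log2 baseline 8–11) so recovery stays within 0.1 clock units, and the
exact-identity tests disable rounding.

Chosen-once generator conditions not fixed by the modeled study: clock
gene log2 amplitude 2 per unit standardized signal (elastic-net-selected
clock genes are, by construction, strong age covariates), 40-feature
clocks over a 300-gene transcriptome, donor-level tAge-change spread sd 2
clock units for the screen, and droplet radii log-normal around 65 px so
rendered droplets sit above the 10,000 px² threshold.

What passing these tests does *not* show about real data: the generator's
background genes are constant (real transcriptomes have correlated,
heteroskedastic expression, so real RLE factors are estimates, not exact);
rendered sections have flat class colors with no staining gradients,
texture, or out-of-focus blur, so classification is exact by construction
rather than approximately correct; immune infiltration, probe chemistry,
and array normalization are not simulated. The tests validate the
*analysis machinery* — filters, algebra, statistics, classification rules
— under known truth, not the biology.

## Problem sizes and numerical choices

The bundled verification experiments use 8 donors per group with
negative-binomial dispersion 0.1 over 100 simulation seeds for
planted-shift recovery, 1,000 null simulations for type-I calibration,
50 seeds of a 1,000-gene/50-planted screen, 50 rendered 560-px sections
for the classification oracle, and radius-10-voxel calibration balls —
sizes at which every run completes in seconds to a few minutes on one
core while keeping Monte-Carlo error well below the decision margins.
Degenerate inputs fail loudly by policy: empty matrices, confounded
designs, single-donor groups, constant groups (unless explicitly allowed),
droplet packings that cannot be placed within 10,000 rejection-sampling
attempts, and beta values outside [0, 1] are all errors, never silent
NaNs.
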