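---
title: "Morphometric classification of reactive astrocytes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric classification of reactive astrocytes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astromorph)
```

astromorph quantifies how cortical astrocytes change shape after a traumatic
brain injury (TBI) and classifies the intensity of their reactive response
from morphology alone. The pipeline takes per-cell skeleton traces (SWC) and
binary masks, derives ten morphometric parameters, screens their
variability, selects the most informative ones with a multimodal index,
clusters the cells, and organizes the clusters into an interpretable
decision tree of response categories ("moderate", "strong", "very strong").
This vignette documents the models, the tunable parameters, the synthetic
data the package is validated on, and the numerical choices made where the
design was genuinely open.

## The ten morphometric parameters

2D size and shape, measured on the cell mask:

* **area** (µm²), **perimeter** (µm), **convex hull area** (µm²);
* **circularity** = 4π·area / perimeter², 1 for a disk;
* **solidity** = area / convex hull area, 1 for convex shapes; lower values
  indicate more irregular, spongiform territories.

3D size and branching, measured on the traced skeleton:

* **length** (µm): summed Euclidean length of all parent–child segments,
  excluding intra-soma (type 1 to type 1) edges;
* **branches12**: primary branches (maximal unbranched paths leaving the
  soma) plus secondary branches (paths leaving a primary branch point);
* **thickness** (µm³): in stack mode, the volume of voxels above 5% of the
  stack maximum; without a stack, a conical-frustum fallback
  π·h·(r₁² + r₁r₂ + r₂²)/3 over the traced radii, flagged in provenance;
* **intersections** and **radius**: from the Sholl profile (below).

### Mask measurement and its bias

Masks are measured on the marching-squares boundary polygon at the 0.5
level (`grDevices::contourLines` on the zero-padded grid): area is the
shoelace area of that polygon, perimeter its length, and the convex hull is
taken over its vertices. Counting pixel edges instead would overestimate
perimeter by up to ~27% and push circularity far above 1; the polygon
estimator keeps solidity ≤ 1 exactly and circularity ≤ 1 for convex
shapes. The residual staircase bias of a binary contour inflates the
perimeter of a disk by about 5%: measured over rasterized disks of radius
20–100 px, disk circularity falls in **[0.88, 0.92]** while area stays
within 0.6% of πr². Exact values (π/4 for a square, solidity 1) hold on
the exact-polygon path (`polygon_shape_features()`), which is also the
oracle used in the tests against rasterized shapes.

### Sholl profile and its three segments

`sholl_profile()` counts, for concentric spheres centred on the soma
centroid (mean of the type-1 nodes; root as fallback) and spaced `step` µm
apart (default 2 µm — fine enough to resolve segment boundaries a few µm
wide), the number of segments crossing each shell. A segment is counted
once per shell it touches, tangentially or not, and an endpoint lying
exactly on a shell counts as a crossing (ties break toward counting; the
brute-force segment–sphere quadratic oracle in the tests applies the same
rule, and the two agree exactly, integer for integer). Shells run out to
the first multiple of `step` at or beyond the farthest node.

The summary takes **intersections** := the maximum count, the **critical
radius** := the smallest shell attaining it, and **radius** := the
enclosing radius (largest shell with a nonzero count). The profile is
split into three segments: the **peak** is the maximal contiguous run of
shells with counts ≥ 0.9 × maximum that contains the critical radius; the
**growth** segment precedes it from the first nonzero shell, the
**decline** segment follows it through the enclosing radius. The 0.9
fraction operationalizes the descriptive near-peak plateau; it is a
config-exposed choice, and the three segments always partition the nonzero
range.

## Lesion zoning

GFAP immunofluorescence rises sharply in the contusion core. The zoning
stage bins pixel intensity by distance from the injury point (default
1000 µm range, 10 µm bins) and detects where the elevation ends:

* baseline = median intensity over the distal half; scale = MAD;
* a bin is *elevated* when its 3-bin moving mean exceeds baseline + k·MAD
  (k = 2);
* the A1/A2 boundary sits at the left edge of the first run of r = 3
  consecutive non-elevated bins — equivalently the midpoint between the
  last elevated and first non-elevated bin centres.

Defining the boundary by the end of elevation (rather than the first
sub-threshold bin) makes the noiseless 250 µm step resolve to 260 µm, one
bin from the design value, and makes a flat profile return an explicit
"no A1" outcome instead of a spurious boundary. The rule is equivariant to
affine intensity rescaling. Cells at distance ≤ boundary are A1, within
the profile range A2, beyond it "none"; a manual boundary override is a
config key, since the original delineation may well have been drawn by
eye.

For the noisy validation regime the generator uses an exponential decay
h·e^(−d/λ) + b. The detection jitter near the analytic crossing of
baseline + 2·MAD is ≈ 0.29·λ (smoothed noise sd divided by the crossing
slope 2σ/λ, independent of the noise level), so the Monte-Carlo check runs
at λ = 10 µm — a sharp gliosis border, one bin wide — where the predicted
error is well inside the two-bin tolerance. At λ ≳ 30 µm the crossing is
too shallow for any detector of this form to localize within two bins.

## Variability screening and group tests

Coefficients of variation (100·sd/mean, sample sd) are banded `low`
(< 10%), `acceptable` (10–35%) and `high` (> 35%) per (subpopulation,
condition, parameter) stratum. Group comparisons use the equal-variance
(Student) unpaired t test, df = n₁ + n₂ − 2; Welch's correction is a flag.
The default tail is two-sided: directional one-tailed tests are supported
per config, but choosing the tail after seeing the sign would invalidate
the level, so an unspecified direction falls back to two-sided. One-way
ANOVA with Tukey HSD serves three-group comparisons (control/A1/A2), and
Sholl profiles are compared with a two-way ANOVA (group × radius) with
per-radius contrasts on the pooled residual variance, Bonferroni-adjusted
by the number of radii. Significance stars follow the conventional bands
(\*\*\*\* ≤ 0.0001 … \* ≤ 0.05).

The per-subpopulation significance screen compares control cells against
*reactive* cells. Where a subpopulation's TBI cells carry zone labels, the
reactive group is restricted to the contusion core (A1): reactivity is
defined at the core, and pooling A1 with the GFAP-normal pericontusional
cells (whose morphology matches controls) would dilute a core-restricted
effect of d = 2 to roughly d ≈ 0.6 and make the designed 9-of-10 recovery
pattern undetectable at the study's sample sizes. Subpopulations without
zone resolution use all TBI cells. The mouse is not modelled as a random
effect — cells are pooled within strata, a known limitation shared with
the study design.

## Multimodal index feature selection

The multimodal index of a parameter is

MMI = (m₃² + 1) / (m₄ + 3(n−1)²/((n−2)(n−3)))

with m₃ the adjusted Fisher–Pearson sample skewness and m₄ the
bias-corrected sample **excess** kurtosis. The excess-kurtosis reading is
forced by the correction term: 3(n−1)²/((n−2)(n−3)) is exactly the
normal-sample expectation that re-centres that estimator, identifying the
index as Sarle's bimodality coefficient. Its large-sample benchmarks are
1/3 (normal), 5/9 ≈ 0.556 (uniform) and → 1 (symmetric two-point mixture),
which is why the 0.55 threshold sits just below the uniform benchmark: a
parameter must look *at least* as flat as uniform to be selected. Raw (non
excess) kurtosis would put the normal benchmark at 1/6 and make 0.55
incoherent. Selection is strict (`> 0.55`), computed on the TBI cells (the
clustering population; a config flag includes controls), and an empty
selection falls back to all ten parameters with a warning because
clustering needs at least two features.

## Clustering and embedding

Selected parameters are z-scored (the "Z-score method" is read as centre
*and* scale; a centring-only mode exists behind a flag, since dividing by
the sd is what makes a single Euclidean threshold meaningful across
parameters). Zero-variance columns are dropped, never divided by zero.

* **Hierarchical clustering**: Euclidean distance, complete linkage by
  default — the cut height then stays in z-score distance units, so the
  2.3 threshold is interpretable as a cluster diameter in z-space (Ward
  would distort the scale). Ward/average are config options, and a
  "cut to k = 8" mode mirrors the eight-cluster partition. Labels A, B,
  C, … are assigned by descending cluster size.
* **PCA** on the z-scores (correlation-matrix PCA of the raw features),
  with orthonormal loadings and explained-variance fractions.
* **t-SNE** (exact, theta = 0) at perplexity 5, seeded and fully
  deterministic; duplicate rows are collapsed before embedding and mapped
  back to identical coordinates.
* **HDBSCAN** with minimum cluster size 10 runs on the 2D t-SNE embedding
  (raw-space mode by flag). The implementation is in-package: core
  distances at min_samples = min_cluster_size neighbours, mutual
  reachability, single-linkage hierarchy, condensed tree, and
  excess-of-mass cluster selection with the root excluded — so a dataset
  with no density split comes back all noise rather than one forced
  cluster. It is cross-checked in the tests against scikit-learn's
  HDBSCAN on well-separated data.

## The response-category logical tree

Per cluster and parameter, 95% confidence intervals are t-based
(mean ± t₀.₉₇₅,ₙ₋₁·sd/√n). The tree is built by CI overlap:

1. The **first level** orders clusters by their mean *response score* —
   the per-cell mean z-score of perimeter, intersections and radius, the
   three parameters that jointly define the top of the tree — and merges
   adjacent clusters whose 95% CIs overlap (chained). Cut-offs sit at the
   midpoints of the CI gaps between the resulting groups. Merging is what
   produces composite nodes such as A+B and C+D.
2. Each first-level group carries a category: with eight clusters A–H the
   conventional map (C+D moderate, A+B strong, E–H very strong) applies;
   otherwise categories follow ascending score terciles. The map is an
   input, not an inference — how the original cluster-to-category
   assignment was first made is not recoverable, so the package treats it
   as data.
3. Within each group the same CI rule splits on convex hull area, then
   length, then thickness, attaching ordered sub-labels
   (medium/large on convex hull and thickness, short/medium/long on
   length) by cut-off interval order.

Classification routes a cell's z-scores through the cut-offs; a value
exactly at a cut-off goes to the upper branch (documented tie rule), so
the leaf regions partition feature space and classification is total and
deterministic. On the designed eight-cluster reference structure the tree
recovers the three first-level groups and routes ≥ 90% of the training
cells to their cluster's category.

## Clonal analysis

Sibling cells share a 12-entry binary barcode: presence of each of six
fluorophores in cytoplasm and nucleus. Grouping is exact binary match;
all-zero (unlabelled) cells are excluded with a warning. Per clone the
package reports size and spatial **dispersion**, defined as the mean
Euclidean distance of members to the clone centroid (0 for singletons);
the undefined original metric motivates also emitting the maximum pairwise
distance as an alternative. For members scattered N(centre, σ²I) the mean
dispersion approaches σ√(π/2), which the tests verify. Per subpopulation
(majority vote over members) it reports clone counts, percentages and mean
sizes.

## The synthetic study

The generator reproduces the study's structure so every stage is testable
without raw images:

* **Design**: 118 TBI cells — pial 15, protoplasmic upper 19 (A1) + 15
  (A2), protoplasmic lower 13 (A1) + 22 (A2), juxtavascular 19, fibrous
  15 — and 10 controls per subpopulation.
* **Baselines**: lognormal for sizes and counts (area median 300 µm²,
  convex hull 2000 µm², perimeter 150 µm, length 900 µm, thickness
  3000 µm³, 12 branches, 14 intersections, radius 60 µm; log-sds
  0.20–0.35, i.e. CVs of 20–35%, inside the observed low-to-acceptable
  variability range) and logit-normal for circularity (0.25) and solidity
  (0.15), which keeps ratios in (0, 1] by construction.
* **Effects** (preset `"significance"`): standardized shifts of d = 2
  baseline sds on the raw scale in lower-layer A1 cells for 9 of the 10
  parameters (all but thickness; circularity and solidity shift downward
  on the logit scale), and on radius only in upper-layer TBI cells.
* **Bimodality** (preset `"bimodal"`): an equal-weight two-component
  mixture in the six multimodal parameters across TBI cells, with a
  separation of 6 within-component sds on the raw scale. The component is
  a *per-cell* latent morphotype shared across parameters — a
  hypertrophic cell is large throughout — which is what gives the TBI
  population coherent cluster structure rather than scattering cells over
  independent per-parameter corners.
* Preset `"paper"` combines both; `"null"` has neither and calibrates
  type-I behaviour.
* **GFAP profile**: plateau of +5 over baseline 1 within 250 µm of the
  injury over a 1000 µm range, Gaussian bin noise; decay mode as above.
* **Clones**: 35 distinct barcodes over 281 cells, members scattered with
  σ = 50 µm, protoplasmic lineages most prevalent.

What passing tests show — and what they do not: the synthetic data are
idealized (independent cells, exactly lognormal margins, a clean latent
dichotomy, schematic skeleton geometry). Real reconstructions carry
correlated parameters, tracing noise, within-mouse correlation and
partial-volume effects that the generator does not emulate, so green tests
validate the *machinery* (estimators, rules, thresholds, determinism), not
the biology of any particular dataset.

## Problem sizes and runtime choices

The validation suite runs the Sholl oracle on 100 seeded trees at three
step sizes, statistical calibration on 1000 null replicates per test,
recovery experiments on 50 seeds at the study's stratum counts, clustering
recovery on 20 seeds of three 30-cell blobs, zoning on 500 noisy decay
seeds, and the full pipeline twice for byte-identical reports. These sizes
keep every Monte-Carlo bound at least three binomial standard errors from
its pass threshold while the whole suite stays under two minutes on one
CPU. Within the calibration block each sub-experiment is seeded
independently, so no check inherits another's random-stream position.

## Known limitations

* The "intersections"/"radius" feature mapping (maximum count / enclosing
  radius) is one reading of an ambiguous description; both candidates are
  computed and the mapping is configurable.
* The linkage behind the 2.3 threshold is not recoverable; complete
  linkage plus the k = 8 mode bracket the plausible intents.
* HDBSCAN labels depend on the t-SNE embedding's arbitrary scale; only
  partition structure, not coordinates, should be interpreted.
* The screen's A1 restriction, the 0.9 peak fraction, and the
  CI-gap-midpoint cut-off rule are documented operationalizations of
  descriptive statements; each is exposed in the configuration.
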