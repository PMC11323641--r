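# astromorph

Morphometric classification of reactive astrocytes after traumatic brain
injury (TBI).

Astrocytes react to brain damage with shape changes — hypertrophy, denser
branching, loss of territorial regularity — that differ across the cortical
subpopulations (pial, protoplasmic upper/lower layers, juxtavascular,
fibrous) and with distance from the lesion. astromorph implements, as a
tested and reusable R pipeline, a morphology-based method to quantify and
classify those responses from single-cell reconstructions. It is aimed at
glia biologists and image analysts who have per-cell skeleton traces and
masks and want a reproducible route from raw morphometry to an
interpretable intensity-of-response category per cell.

## What it computes

1. **Morphometry** — ten per-cell parameters from a binary mask and an SWC
   skeleton: area, convex hull area, perimeter, circularity
   (4π·area/perimeter²), solidity (area/hull), total process length,
   primary + secondary branch count, thickness (volume above a 5% relative
   intensity threshold, µm³), and the Sholl maximum-intersection count and
   enclosing radius, with the full Sholl profile split into growth / peak /
   decline segments.
2. **Variability screening** — coefficient-of-variation tables banded at
   <10% / ≤35% / >35%, Student t comparisons, one-way ANOVA + Tukey,
   two-way ANOVA + Bonferroni on Sholl profiles, and the proportion of
   significantly changed parameters per subpopulation.
3. **Lesion zoning** — GFAP intensity profiles versus distance from the
   injury (1000 µm range), with automatic delineation of the contusion
   core (A1, elevated GFAP, ≈250 µm) from pericontusional tissue (A2).
4. **Feature selection** — the multimodal index
   MMI = (m₃² + 1) / (m₄ + 3(n−1)²/((n−2)(n−3))), a Sarle-type bimodality
   coefficient on bias-corrected sample skewness m₃ and excess kurtosis
   m₄; parameters with MMI > 0.55 enter clustering.
5. **Clustering** — z-scoring, hierarchical clustering (Euclidean,
   complete linkage, 2.3 distance threshold; alternative cut to k = 8),
   PCA, t-SNE (perplexity 5, deterministic per seed) and an in-package
   HDBSCAN (minimum cluster size 10) on the embedding.
6. **Response taxonomy** — per-cluster 95% confidence intervals feed a
   logical tree: clusters merge when CIs overlap, cut-offs sit at CI-gap
   midpoints, and leaves carry the categories *moderate*, *strong*, *very
   strong* with size/length/thickness sub-labels; cells are routed
   deterministically through the cut-offs.
7. **Clonal analysis** — cells sharing a 12-bit fluorophore barcode
   (6 fluorophores × cytoplasm/nucleus) form clones; per clone size and
   spatial dispersion, per lineage clone frequencies.
8. **Synthetic study generator** — feature tables with the study's stratum
   counts (118 TBI + 50 control cells), designed effect sizes, a latent
   bimodal morphotype, branched skeletons, rasterized masks with exact
   generating polygons, GFAP profiles and a 35-clone / 281-cell barcode
   set, all deterministic per seed.

## Worked example

```r
library(astromorph)

cfg <- load_config(overrides = list(seed = 42))
rep <- run_pipeline(cfg)
rep
#> <pipeline_report>
#>   cells: 168  ( 118 TBI )
#>   selected parameters: convex_hull_area, perimeter, thickness, intersections, radius
#>   HC clusters: 3 ; PC1+PC2 explained: 93.9%
#>   report hash: f408e7ebe8f72e37

rep$mmi[, c("parameter", "mmi", "selected")]
#>           parameter   mmi selected
#> 1              area 0.456    FALSE
#> 2  convex_hull_area 0.706     TRUE
#> 3         perimeter 0.612     TRUE
#> 4       circularity 0.421    FALSE
#> 5          solidity 0.387    FALSE
#> 6            length 0.480    FALSE
#> 7        branches12 0.408    FALSE
#> 8         thickness 0.678     TRUE
#> 9     intersections 0.644     TRUE
#> 10           radius 0.600     TRUE

table(rep$assignments$hc_label, rep$assignments$category)
#>     moderate strong very_strong
#>   A       61      0           0
#>   B        0     42           7
#>   C        0      0           8

rep$boundary$boundary_distance
#> [1] 260
```

Reading the output: on this synthetic study the multimodal index flags
five of the ten parameters as bimodal (values above 0.55 — the uniform
distribution's benchmark 5/9 marks the flatness a parameter must exceed),
the 118 TBI cells fall into three morphotype clusters whose
confidence-interval tree maps them to *moderate*, *strong* and *very
strong* responses, and the GFAP profile places the contusion-core boundary
at 260 µm, one bin from the generator's designed 250 µm. Because every
stage draws from one master seed, rerunning with the same config
reproduces the report hash byte for byte.

Individual stages are plain functions (`extract_features()`,
`sholl_profile()`, `delineate_areas()`, `select_parameters()`,
`hierarchical_cluster()`, `build_response_tree()`, `group_clones()`, …)
and can be used on real data frames and SWC/mask/CSV files directly; see
the methods vignette (`vignettes/astromorph-methods.Rmd`) for the models,
defaults and design rationale.

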