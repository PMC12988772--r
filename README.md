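# spatmosaic

Hierarchical, multi-sample data containers and analysis for single-cell
spatial omics in R.

Imaging-based spatial transcriptomics and proteomics runs produce, per
tissue section, a bundle of modalities — microscopy images with a
physical pixel size, per-molecule transcript locations, per-cell count
matrices with segmentation boundaries, spot/compartment measurements,
and pathology polygons — and modern experiments carry many sections or
a tissue microarray at once. spatmosaic is for analysts who need to
handle such cohorts end to end: it provides

* a **sample container** (`spat_sample`) with six data categories
  (`images`, `transcripts`, `cells`, `units`, `annotations`, `regions`)
  in one shared micrometre coordinate frame, with polygon cropping;
* an **experiment container** (`spat_experiment`) joining samples to a
  metadata table by UID, with `query()`, `iterate()`, `concat()` and
  three assembly routes (per-sample, region splitting, config file);
* an **on-disk project format** separating *static* data (raw images,
  transcripts; SHA-256-checksummed, written once) from *variable* data
  (tables, annotations; rewritten by fast incremental saves), with lazy
  image/transcript loading and a flat keyed export
  (`to_flat()`/`from_flat()`);
* **automated registration** of post-run histology onto the run's
  nuclear fluorescence image: scale-invariant keypoints (SIFT
  construction), ratio-test matching, RANSAC affine/perspective fitting
  with QC metrics (`register_pair()`);
* **tile-streamed per-cell quantification** of immunofluorescence
  signal that never materializes the full image
  (`quantify_intensity()`);
* **multi-sample analyses**: cellular composition, cell-type density
  (cells/mm²), rank-sum differential expression with
  Benjamini–Hochberg correction, and pseudobulk aggregation — all
  tibble-in/tibble-out with `tidy()`, `glance()` and `autoplot()`
  methods;
* a **synthetic-data generator** with full ground truth
  (`generate_sample()`, `generate_experiment()`,
  `generate_registration_pair()`), so every component is testable
  without downloading an accession.

## The statistics at the core

Differential expression between cell groups A and B: counts are
normalized per cell to the median total of the pooled groups
(x̃ᵢⱼ = xᵢⱼ · m/Σⱼxᵢⱼ, m the pooled median total); each gene gets a
two-sided Wilcoxon rank-sum test via the normal approximation with tie
correction, z = (U − n₁n₂/2)/σ_ties; the effect size is
lfc = log₂((x̄_A + ε)/(x̄_B + ε)) with ε = 10⁻⁹ on normalized means;
q-values are Benjamini–Hochberg over the tested genes. Cell-type
density is the count of centroids inside a polygon divided by its
shoelace area (µm² → mm²). Registration solves
**p**_fixed ≃ T **p**_moving for a 3×3 affine (or perspective) T by
RANSAC over ratio-test descriptor matches, reporting inlier counts and
mean reprojection error.

## Worked example

A four-sample synthetic cohort with planted effects: treated samples
get +0.15 on the type-1 fraction and a 4× fold change on genes 91–100.

```r
library(spatmosaic)
set.seed(1)

ge  <- generate_experiment(n_samples = 4, seed = 42,
                           n_cells = 300, image_px = 384)
exp <- ge$experiment

cell_composition(exp, group_key = "condition")
#> # A tibble: 2 × 4
#>   group   type_1 type_2 type_3
#>   <chr>    <dbl>  <dbl>  <dbl>
#> 1 control  0.503  0.317  0.18
#> 2 treated  0.663  0.218  0.118

treated <- query(exp, condition == "treated")
control <- query(exp, condition == "control")
pool <- function(e) do.call(rbind, lapply(e$samples,
                                          function(s) s$cells$default$matrix))
dge <- differential_expression(pool(treated), pool(control))
head(dplyr::arrange(tidy(dge), q_value), 3)
#> # A tibble: 3 × 7
#>   feature  mean_a mean_b   lfc statistic   p_value   q_value
#>   <chr>     <dbl>  <dbl> <dbl>     <dbl>     <dbl>     <dbl>
#> 1 gene_091  11.3   3.13   1.85      29.2 2.05e-187 2.05e-185
#> 2 gene_097   7.90  2.31   1.78      28.0 4.46e-172 2.23e-170
#> 3 gene_099   3.88  1.09   1.83      24.2 1.25e-129 4.16e-128
```

The recovered compositions sit near the planted (0.65, 0.21, 0.14) and
(0.5, 0.3, 0.2), and the top genes by q-value are exactly the planted
set (lfc ≈ 1.8–2.2: a 4× profile shift, damped by renormalization,
recovered on the log₂ scale). Cell-type markers also reach
significance here — the composition shift changes pooled expression
too, which is the expected behaviour of a group-level comparison.
`autoplot(dge)` draws the volcano, `autoplot(cell_composition(...))`
the stacked composition bars.

Registration on a planted transform:

```r
pr  <- generate_registration_pair(seed = 3, rotation_deg = 10,
                                  scale = 1.1, shift_px = c(30, -20))
res <- register_pair(pr$fixed, pr$moving)
glance(res)   # keypoint/match/inlier counts, mean reprojection error (px)
```

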