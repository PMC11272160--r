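# amniowave

Temporal wave classification and single-cell atlas projection for
BMP4-driven time-course bulk RNA-seq.

## The problem

When human pluripotent stem cells are exposed to BMP4 they differentiate
into amniotic ectoderm over roughly 48 hours. Bulk RNA-seq sampled densely
along that window (0, 0.5, 1, 3, 6, 12, 24, 48 hr, triplicates) captures a
cascade of transcriptional activation, and two questions follow:

1. **When does each gene turn on?** Genes are classified into temporal
   activation waves — *immediate* (significantly upregulated by 0.5–1 hr),
   *early* (3–6 hr), *intermediate-1* (12 hr), *intermediate-2* (24 hr) and
   *late* (48 hr) — by testing each timepoint against the previous one and
   taking the earliest contrast with significant upregulation
   (BH FDR < 0.05 and fold change > 2).
2. **Where along the embryonic differentiation trajectory does each bulk
   sample sit?** Each bulk profile is downsampled into 100 pseudo-single-cells
   (multinomial draws at single-cell depth), projected into a TF-IDF/LSI
   latent space fitted on an annotated single-cell reference, transferred
   into the reference's 2-D embedding by inverse-distance-weighted k-nearest
   neighbours, represented by the **medoid** of its pseudo-cells, and
   assigned the identity of the nearest reference cell by Euclidean distance
   in embedding space.

The package implements the full pipeline — count I/O, detection filters
(a gene needs ≥ 10 reads in some sample and a maximum > 30), median-of-ratios
size factors (sf_j = median_g c_gj / (∏_k c_gk)^(1/n) over all-positive
genes), moderated-t differential expression on log2(normalized + 1), wave
assignment, row Z-score profiles, PCA, and the atlas projection — plus a
synthetic-data module that generates both the time course (negative-binomial
counts, variance μ + αμ², with planted waves) and an annotated reference
atlas with known ground truth, so every stage is testable offline. The real
study data are controlled-access; the synthetic module is the test bed.

## Worked example

```r
library(amniowave)

# simulate the default BMP4 time course: 8 timepoints x 3 replicates
sim <- generate_time_course(sim_config(seed = 42))
sim$counts
#> count_matrix: 2000 genes x 24 samples
#> timepoints (hr): 0, 0.5, 1, 3, 6, 12, 24, 48

counts <- filter_low_expression(sim$counts)
norm <- normalize_counts(counts, size_factors_median_ratio(counts))
waves <- assign_stages(consecutive_contrasts(norm))
table(waves$stage)
#>          early      immediate intermediate-1 intermediate-2           late
#>            101            100            101             99            101
#>     unassigned
#>           1436

# project cluster-derived bulk samples onto a synthetic annotated atlas
gen <- generate_reference_atlas(atlas_config(seed = 42))
bulk <- generate_bulk_from_cluster(gen$atlas, "Amnion", n_samples = 3,
                                   depth = 1e6, seed = 42)
proj <- map_samples_to_atlas(gen$atlas, bulk, seed = 42)
proj[, c("sample_id", "medoid_x", "medoid_y", "transferred_label", "distance")]
#>       sample_id medoid_x    medoid_y transferred_label   distance
#> 1 Amnion_bulk01 30.09268 -0.06182901            Amnion 0.02524597
#> 2 Amnion_bulk02 30.08072 -0.05576629            Amnion 0.01870543
#> 3 Amnion_bulk03 30.08905 -0.04911001            Amnion 0.02921826
```

The simulation plants 100 genes per wave among 2000; the wave table shows the
classifier recovers them almost exactly (the 1436 unassigned genes are the
1500 flat background genes minus filter losses, plus a handful of misses).
The projection places all three Amnion-derived bulks at the Amnion cluster
center (x = 30 on the synthetic trajectory axis, cluster spacing 10) with the
correct transferred label and a medoid-to-cell distance two orders of
magnitude below the cluster spacing.

A JSON-configured orchestration (`run_pipeline()`) and a CLI wrapper
(`inst/scripts/amniowave.R` with subcommands `simulate`, `normalize`, `de`,
`cascade`, `project`, `run-all`) run the same stages end to end and write a
manifest with content hashes for reproducibility.

## Vignette

`vignettes/amniowave-methods.Rmd` describes the statistical model, every
tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, and known limitations.
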