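---
title: "amniowave: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{amniowave: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amniowave)
```

## Overview

`amniowave` analyses a dense BMP4 time course of bulk RNA-seq from
differentiating hPSC-amnion: it classifies genes into temporal activation
waves from consecutive-timepoint differential expression, and places bulk
samples onto an annotated single-cell reference by pseudo-single-cell
downsampling and latent-space projection. Because the motivating study's
sequencing data are controlled-access, the package ships a first-class
synthetic-data module whose defaults reproduce the study design (8
timepoints at 0, 0.5, 1, 3, 6, 12, 24, 48 hr; triplicates), with planted
ground truth for every claim the tests make.

## Counts, filters, normalization

Counts are a gene × sample integer matrix with per-sample metadata
(timepoint in hours, condition, replicate). Two detection filters are
applied in order and logged separately: a gene is kept only if (1) at least
one sample has ≥ 10 reads and (2) its maximum count exceeds 30. The first
rule reads "fewer than N reads in all samples" in its per-sample sense
(no sample reaches N); the alternative total-count reading is subsumed by
the second rule anyway. A protein-coding biotype filter is deliberately out
of scope — it needs an annotation database, and the gene universe is
whatever the input provides.

Size factors are classical median-of-ratios: the reference for each gene is
its geometric mean across samples (computed in log space for stability, and
only over genes positive in every sample, the DESeq2 convention), and

$$ sf_j = \mathrm{median}_g \; \frac{c_{gj}}{(\prod_k c_{gk})^{1/n}} . $$

Normalized values are exact elementwise divisions `count / sf`; log2 views
use a pseudocount of 1 so zeros stay at 0. Note that such factors are only
defined up to a common scale: rescaling one sample by *c* moves the
recomputed geometric-mean reference too, so individual factors shift by
$c^{1 \pm 1/n}$ while factor *ratios* shift by exactly *c*. Tests assert the
ratio form.

Variable genes are ranked by variance of log2 values (ties broken by gene ID
so the ranking is total), and sample PCA runs on gene-centered log2 values
with a fixed sign convention (the largest-magnitude loading of each
component is positive), making coordinates reproducible across BLAS builds.

## Differential expression

Per gene, on $y = \log_2(\text{normalized} + 1)$, the statistic is

$$ z_g = \frac{\bar y_{gB} - \bar y_{gA}}
        {\sqrt{\tilde s_g^2 / n_A + \tilde s_g^2 / n_B + \varepsilon}} $$

with $\varepsilon = 10^{-8}$ guarding zero-variance genes. The default
method moderates the pooled gene-wise variance $s_g^2$ with empirical Bayes
shrinkage toward a mean-expression trend (limma's `squeezeVar`), and refers
$z_g$ to a t distribution on prior + pooled degrees of freedom. The choice
is deliberate: at triplicate scale a gene-wise normal reference is badly
anti-conservative (empirical null type-I ≈ 0.12 at α = 0.05 in our
negative-binomial simulations), while an unmoderated Welch t is calibrated
but lacks the power to clear a BH threshold when only ~5% of genes are
signal. Variance moderation — the field's standard answer for n = 3 — gives
both: empirical null type-I ≈ 0.045 and essentially full power on fold-8
effects. The unmoderated Welch form remains available as `method = "z_log2"`.
No claim is made of re-implementing any particular commercial pipeline's
test; selection thresholds (FDR < 0.05, |fold| > 2) follow the study and are
applied strictly (`<`, `>`).

BH FDR is computed per contrast over the filtered gene universe, matching
per-comparison selection; the volcano classification deliberately uses raw
p-values, mirroring the corresponding figure convention.

## Temporal wave assignment

`consecutive_contrasts()` tests each timepoint against the previous one
(later group = B, so upregulation is positive). `assign_stages()` finds each
gene's earliest contrast with significant upregulation and maps that
contrast's later timepoint through a configurable `stage_map()`. The default
map — immediate {0.5, 1}, early {3, 6}, intermediate-1 {12},
intermediate-2 {24}, late {48} — follows the study's textual wave
enumeration; a variant that groups 6 hr with 12 hr is one config edit. Only
upregulation defines a wave; downregulated dynamics are reported in the
contrast tables but never staged. Genes first significant at the 0 → 0.5 hr
contrast map to *immediate*.

The published gene lists were additionally pruned by a stringent filter
whose procedure was not specified. `stringent_filter()` offers an explicit,
optional stand-in: mode `"sustained"` demotes a staged gene unless its mean
log2 expression at every timepoint from first activation onward stays more
than 1 (i.e. twofold) above its pre-activation baseline mean — removing
transient spikes. It is never applied silently; the mode is recorded in the
output's attributes and the pipeline manifest.

## Atlas projection

The reference is an annotated single-cell atlas: counts, per-cell cluster
labels, and per-cell 2-D embedding coordinates *consumed as given* — the
package never fits an embedding. The latent model is log-scaled TF-IDF plus
truncated SVD (LSI): TF is count over column total, IDF is
$\log(1 + N/(1 + n_g))$ with $n_g$ the number of cells expressing gene *g*,
$X = \log(1 + \mathrm{TF} \cdot \mathrm{IDF} \cdot 10^4)$, and the SVD of
$X^\top$ supplies orthonormal gene components. Queries are projected with
the *model's* IDF and scale, so coordinates are invariant to rescaling a
query column. The chromatin-analysis convention of dropping the first
component is off by default and exposed as a flag; in these RNA simulations
the first component carries cluster signal, not depth.

Per bulk sample: 100 pseudo-single-cells are drawn as independent
multinomials over the bulk proportions at a depth defaulting to the median
reference per-cell total (making pseudo-cells statistically comparable to
reference cells); each is projected to LSI space and transferred into the
reference embedding as the inverse-distance-weighted average of its 15
nearest reference cells (an exact match copies that cell's coordinates);
the medoid — the member minimizing summed Euclidean distance, ties to the
lowest index — represents the sample; and the nearest reference cell in
embedding space supplies the transferred label and distance. Gene universes
are reconciled by intersection with zero-fill, and the dropped/zero-filled
counts are reported, since silent gene mismatch is the main practical
failure mode of projection methods.

Randomness sits behind one integer seed; pseudo-cell *i* of sample *j* uses
stream `seed + (j-1)·n_cells + i`, so results are bitwise reproducible and
individual pseudo-cells are independently re-derivable.

## The synthetic-data module

`generate_time_course()` plants, by default, 100 genes per wave among 2000,
with onsets immediate = 1, early = 3, intermediate-1 = 12,
intermediate-2 = 24, late = 48 hr. Baseline means are log-normal
(median 100 counts, log-SD 1 — a realistic bulk dynamic range); activation
multiplies the mean by 8 from onset onward as a step (a logistic ramp with
half-activation at onset is available, but the step matches the
first-significant-upregulation semantics the classifier tests). Noise is
negative binomial with variance $\mu + \alpha\mu^2$, $\alpha = 0.05$, the
standard bulk RNA-seq parameterization; per-sample library sizes are
log-normal with mean 0 in log space (log-SD 0.15), so the expected
geometric mean is 1 and median-ratio estimates are comparable to truth.

`generate_reference_atlas()` lays its default five clusters (Epiblast,
PrimitiveStreak, TBXTlow, Amnion, NascentMesoderm — the trajectory the
projection is meant to resolve) on a line with spacing 10 and Gaussian
jitter 0.5 in a latent 2-D embedding; expression programs are a shared
log-normal baseline plus 50 cluster-exclusive markers per cluster, and
per-cell counts are NB around the depth-scaled program. Exclusive markers
make cluster identity recoverable and give the multinomial bulk generator
exact zero-probability categories, which the tests exploit.

What the generator does **not** emulate: isoforms, batch effects,
cell-cycle structure, doublets, ambient RNA, gradual expression gradients
between adjacent clusters, or read-level artifacts. Passing tests therefore
demonstrate the pipeline's correctness and its statistical behaviour under
a clean NB world — not robustness to every failure mode of real sequencing.
The study's real data have no published noise model; NB with config-level
dispersion is this package's stand-in, not a claim about the study.

## Numerical choices and degenerate inputs

- Geometric means in log space; genes with any zero excluded from the
  normalization reference set.
- Zero-variance genes: variance floor ε in the DE statistic (null genes get
  z = 0, p = 1); all-zero rows flagged and zeroed in Z-score profiles.
- Tie-breaks are total and documented: variable genes by gene ID, medoid
  and nearest-cell by lowest index, PCA signs by largest-magnitude loading.
- Empty filter results warn rather than error; disjoint gene universes and
  zero-total query columns are hard errors naming the offender.
- Problem sizes in the shipped tests and acceptance script (2000 genes,
  24 samples, 1500 reference cells, 20 projected bulks) were chosen as the
  smallest scales at which the statistical properties under test are
  comfortably estimable.

## Known limitations

- The DE module handles exactly two groups; no covariates, shrinkage of
  fold changes, or multi-factor designs.
- Wave assignment keys on consecutive contrasts only; a gene rising slowly
  but never significantly between adjacent timepoints stays unassigned even
  if its 0 → 48 hr change is large.
- The sustained-mode stringent filter is a documented heuristic, not a
  reconstruction of the original (unspecified) procedure.
- The projection consumes the reference embedding as given; distortions in
  that embedding propagate to transferred labels.
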