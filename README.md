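# centroscreen

Analysis of arrayed, imaging-based CRISPR knockout screens that read out the
**spatial organization of centromeres** in the interphase nucleus. Each
CENP-C-stained centromere appears as one fluorescent spot; per cell, the
package measures how many spots there are and how strongly they cluster, and
per screen it turns those measurements into a per-gene hit list.

It is aimed at high-content-imaging analysts who need a tested, reproducible
path from multi-channel fields (or pre-extracted per-cell tables) to hit
calls, and at methodologists who want a spatial-statistics score for point
patterns inside arbitrary segmentation masks.

## What it computes

**Per-cell clustering score.** For `N >= 2` spots in a nucleus mask of area
`A`, the empirical Ripley K function

    K(r) = A / (N (N − 1)) · Σ_{i≠j} 1[d_ij ≤ r]

is evaluated on a radii grid of fixed fractions of the equivalent nuclear
radius `R_eq = sqrt(A/π)` (size normalisation). `K` is standardised per
radius against a Monte-Carlo complete-spatial-randomness (CSR) baseline
sampled *inside the same mask* for the same `N` (this absorbs boundary
effects for any mask shape and makes the score robust to spot count), and
the radius-averaged deviation is rescaled to unit null SD. Positive =
clustered, negative = dispersed; under CSR the score is ~N(0, 1) regardless
of nuclear size or spot number.

**Imaging stages.** Otsu + watershed nuclear segmentation (synthetic-grade),
multi-scale Laplacian-of-Gaussian spot detection with sub-pixel centroids,
morphology QC (solidity ≥ 0.85, area ≥ 30 µm², no border contact), and
normalized radial spot positions.

**Cell-cycle gating.** Two-component Gaussian mixture on log2 integrated
DAPI locates the 2N/4N modes; EdU-positive cells are S-phase regardless of
DNA content; subG1 and >4N cells are excluded at mode ± 3 SD.

**Hit calling.** Per-well means over QC-passing cells → per-plate robust Z
(median / 1.4826·MAD of the library wells) → replicate-level
re-standardisation → replicate averaging. After dysmorphic, cytotoxic
(cell-number Z < −2.5) and replicate-consistency exclusions, a gene is a hit
iff |mean Z| > 2.5 on clustering score or spot count. Includes phenotype
categorisation, two-cell-line concordance, and ANOVA/Tukey or pairwise
t/Bonferroni group comparisons with the usual star convention.

**Synthetic screens.** A first-class generator produces elliptical nuclei,
CSR / Thomas / radially biased spot patterns, rendered 16-bit fields, DAPI/
EdU mixtures, and whole 384-well screens (7 control wells each of scrambled,
PLK1, OR10A5, NCAPH2 per plate; 2 replicates; known per-gene effects), so
every stage is validated against ground truth.

## Worked example

```r
library(centroscreen)
library(dplyr)

# a 96-gene screen with 8 genes spiked at ±4 well-SD on the clustering score
design <- screen_design(n_genes = 96, seed = 1) |>
  spike_effects(n_spike = 8, effect = 4, seed = 2)
sim <- generate_screen_dataset(design)

calls <- analyze_screen(sim$cells, sim$layout)
filter(calls, hit, role == "library") |> classify_phenotype() |>
  select(gene, mean_z_clust = mean_z_mean_clustering_score, phenotype)
#> # A tibble: 8 × 3
#>   gene     mean_z_clust phenotype
#>   <chr>           <dbl> <chr>
#> 1 GENE0006        -4.02 clustering-only (unclustered)
#> 2 GENE0008        -2.51 clustering-only (unclustered)
#> 3 GENE0017         3.99 clustering-only (clustered)
#> 4 GENE0032         3.71 clustering-only (clustered)
#> 5 GENE0070         3.42 clustering-only (clustered)
#> 6 GENE0079        -3.41 clustering-only (unclustered)
#> 7 GENE0081        -5.37 clustering-only (unclustered)
#> 8 GENE0085         3.64 clustering-only (clustered)
```

All eight spiked genes (and nothing else from the library) are recovered,
each in the planted direction. Cell-cycle gating on 5000 simulated cells
(true fractions G1/S/G2M = 0.50/0.30/0.20):

```r
cc <- simulate_cellcycle_intensities(5000, seed = 4)
gate <- fit_phase_gate(cc$dapi_total, cc$edu_total)
gate
#> Cell-cycle phase gate (5000 cells)
#>   log2 DAPI G1 mode: 10.000   G2/M mode: 10.999
#>   cuts: subG1 < 9.648 | G1/G2 10.500 | >4N > 11.368
#>   EdU-positive cut (log2): 7.293
phase_fractions(assign_phase(cc, gate))
#> # A tibble: 4 × 2
#>   phase    fraction
#> 1 G1         0.504
#> 2 S          0.290
#> 3 G2M        0.206
#> 4 excluded   0.0352
```

`autoplot()` methods exist for K curves, gene-call tables and phase gates;
`tidy()`/`glance()` methods for gates and concordance reports. A thin CLI
(`inst/cli/centroscreen.R`) exposes `simulate`, `detect`, `score`, `gate`,
`screen` and `report` subcommands, and `run_pipeline()` executes the whole
chain deterministically with a run manifest.

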