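---
title: "Scoring spatial centromere organization in imaging CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring spatial centromere organization in imaging CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centroscreen)
library(dplyr)
```

## The problem

Centromeres — one CENP-C focus per chromosome — occupy non-random positions in
the interphase nucleus, and their degree of spatial clustering is a convenient
single-cell surrogate for higher-order genome organization. An arrayed
high-throughput imaging CRISPR knockout screen perturbs one gene per well of a
384-well plate, images DAPI-stained nuclei and CENP-C foci, and asks which
knockouts change either the number of centromere spots per nucleus or their
spatial arrangement. `centroscreen` implements the full image-to-hit-list
path: spot detection, a Ripley's-K-derived per-cell clustering score,
DAPI/EdU cell-cycle gating, and plate-normalised hit calling — together with a
synthetic-data generator that emulates the statistical structure of such a
screen so every stage can be validated against known ground truth.

## The clustering score

For a nucleus with mask area $A$ (in µm²) containing $N \ge 2$ spots, the
empirical Ripley K function is

$$\hat K(r) = \frac{A}{N(N-1)} \sum_{i \neq j} \mathbf{1}[d_{ij} \le r],$$

the (density-scaled) expected number of neighbours within distance $r$ of a
typical spot. Under complete spatial randomness (CSR) in an unbounded window
$\hat K(r) \approx \pi r^2$; clustering pushes $\hat K$ above that, dispersion
below.

Three design choices turn $\hat K$ into a per-cell score that is comparable
across nuclei of different size, shape, and spot count:

1. **Size normalisation.** The radii grid is a fixed set of fractions
   (default $0.05, 0.10, \dots, 0.50$) of the equivalent nuclear radius
   $R_{eq} = \sqrt{A/\pi}$, so the same sub-nuclear scales are probed in
   small and large nuclei. Fractions above 0.5 would saturate $\hat K$ near
   the mask diameter and add no information.
2. **Monte-Carlo CSR baseline instead of analytic edge correction.** For each
   (mask, $N$) pair, `n_mc` (default 100) patterns of $N$ uniform points are
   sampled inside the actual mask and scored with the same $\hat K$. Observed
   values are standardised per radius by the baseline mean and SD. Because the
   baseline suffers exactly the same boundary effects as the data — for any
   mask shape, convex or not — no translation or isotropic edge correction is
   needed. (The uncorrected $\hat K$ alone has a boundary deficit of order
   $4r/(3\pi R)$ in a disk; the standardisation absorbs it.) Baselines are
   memoised on a hash of (mask, $N$, radii, `n_mc`, seed), which is what makes
   screen-scale scoring tractable.
3. **Unit-variance standardisation.** The per-radius standardised deviations
   are averaged over the radii grid; because deviations at neighbouring radii
   are strongly correlated, that average has a null SD well below 1 (~0.75).
   The score divides by the Monte-Carlo SD of the same radius-average across
   the baseline replicates, so the final score has approximately zero mean
   and unit SD under CSR for any nucleus size and any spot count. Positive
   scores mean clustering, negative scores dispersion.

Cells with fewer than two spots have no defined score; they are excluded from
clustering-score aggregation but kept for spot-count aggregation.

The score is *defined* by this package in these terms; its contracts — zero
mean under a uniform null, robustness to nuclear size and spot count,
monotone response to true clustering strength — are enforced by the test
suite rather than assumed.

## Spot detection and nucleus QC

Nuclei are segmented from the DAPI channel by Otsu thresholding, hole
filling, and distance-transform watershed splitting of touching objects —
adequate for the well-separated synthetic fields the package generates
(dense tissue would need a learned segmenter, which is out of scope). Per
nucleus, area (µm²), solidity (area / convex hull area), and border contact
are measured; a nucleus passes QC iff solidity $\ge 0.85$, area $\ge 30$ µm²
(micronuclei fail), and it does not touch the field border. The inequalities
are strict on the failing side: a nucleus at exactly 30 µm² passes.

Spots are detected with a multi-scale Laplacian-of-Gaussian filter (five
scales spanning 1–3 px by default, matching diffraction-limited foci at
0.108 µm/pixel). Scale-space local maxima above `k` robust noise units
(default `k = 8`, noise estimated as the MAD of the finest-scale response)
are kept, duplicates within one scale unit are merged, each focus is
segmented as the above-threshold response region nearest its peak, and the
reported coordinate is the response-weighted centroid — sub-pixel accurate to
about 0.01 px on noiseless spots and 0.15 px RMS at SNR 10. Spots are
assigned to nuclei strictly by mask membership; orphans are dropped.

## Cell-cycle gating

Integrated per-nucleus DAPI and EdU intensities are gated as follows. The
EdU-positive cut is the valley of the bimodal log2 EdU distribution; when no
valley is resolvable (e.g. no S-phase population), a conservative fallback cut
at the 99.5th percentile plus two robust SDs of the pooled values is used, so
a background-only population produces zero S-phase calls. A two-component
Gaussian mixture is then fitted to log2 DAPI on the EdU-negative cells
(S-phase cells lie between the 2N and 4N modes and would bias the fit). The
EM is deterministic; it is anchored on the two kernel-density modes separated
by roughly one doubling (0.6–1.3 log2 units), with values beyond ±0.45 of the
anchors trimmed before fitting and a 3-component-SD trim-and-refit loop
afterwards, so subG1 debris and 8N doublets cannot hijack a component. Cells
below `G1 mode − 3 SD` or above `G2 mode + 3 SD` are excluded; among the
rest, EdU-positive cells are S regardless of DNA content, and the remainder
split into G1/G2M at the midpoint of the modes. A mode separation below 0.5
log2 units raises an error rather than returning a meaningless gate.

## Hit calling

Per-cell features are averaged per well over QC-passing cells; wells with
fewer than 20 usable cells are dropped. Each feature is normalised per plate
with a robust Z score — centre and scale (median, 1.4826·MAD) are estimated
from the *library* wells only, so control wells are scored against the
library but never influence it. Plate-level Z values are pooled within each
biological replicate and re-standardised the same way, then averaged across
replicates per gene. Exclusions are applied in fixed precedence: *dysmorphic*
(more than half of a gene's nuclei fail QC), *cytotoxic* (cell-number mean
Z < −2.5), *inconsistent* (|mean Z| smaller than the across-replicate SD, for
the feature(s) that would otherwise qualify the gene). Remaining genes are
hits iff |mean Z| > 2.5 — strictly — on the clustering score or the spot
count. Hits are categorised by the sign pattern of the two read-outs (e.g.
clustering up + count down = "higher clustering"; both down = "fewer larger
clusters"), and two screens are compared by the Pearson correlation of their
clustering mean Z over genes excluded in neither, plus the intersection and
direction concordance of the hit sets.

The robust-Z convention is the package default; a plain mean/SD variant is
available via `robust = FALSE` for sensitivity analysis.

## The synthetic screen

The generator emulates the screen's statistical structure at the feature
level (the default, fast path) and renders image fields for a handful of
wells as a smoke path for the imaging stages.

* **Geometry**: elliptical nuclei at 0.108 µm/pixel, optionally perturbed by
  a low-order Fourier boundary noise that produces connected but lobed,
  low-solidity shapes for QC testing; 16-bit rendering with Poisson plus
  Gaussian sensor noise.
* **Point processes**: CSR (uniform over mask pixels with sub-pixel jitter,
  optionally with a hard-core minimum separation for detection benchmarks),
  Thomas clusters (parents uniform in the mask, offspring Gaussian with
  dispersion σ, resampled until inside — for σ much larger than the nucleus a
  uniform-envelope sampler draws from the identical conditional law), and a
  radially biased variant. Spot counts are exact by construction.
* **Plates**: one gene per well, 384-well plates, 7 wells each of scrambled,
  PLK1, OR10A5 and NCAPH2 controls per plate, two biological replicates.
  PLK1-like wells get a cell-number multiplier of 0.1 (cytotoxic positive
  control); NCAPH2-like wells a strong positive clustering shift.
* **Effect scale**: per-gene shifts on clustering score and spot count are
  expressed in units of the null SD of a *well mean* — the scale on which
  screen Z-scores live — so a shift of 4 corresponds to an expected mean
  Z-score of about 4 and spike-in recovery exercises the pipeline near its
  decision boundary rather than trivially far from it. Null per-cell scores
  are drawn from the empirical distribution of scored CSR simulations, which
  keeps the generator and the scorer self-consistent.
* **Population sizes**: 300 cells per well on average (negative-binomially
  overdispersed, size 10), ~46 spots per cell (a near-diploid human
  karyotype; configurable, since per-cell counts vary with ploidy), baseline
  5% QC-failure rate, and a DAPI/EdU population with G1/S/G2M fractions
  0.5/0.3/0.2 and 2% each of subG1 and >4N contaminants.

What the generator deliberately does **not** emulate: optical aberrations,
illumination gradients, chromatic shifts, segmentation errors of crowded or
mitotic cells, gene-gene correlation structure, or biology-driven covariance
between read-outs. Passing tests therefore demonstrate the correctness and
calibration of the *analysis*, not robustness to every real-data artifact.

## Numerical choices and problem sizes

* Coordinates are (row, col), 0-based, pixel centres at integers; physical
  units enter only through `pixel_size`.
* Default `n_mc = 100` per (mask, N) baseline. In calibration experiments
  where hundreds of nuclei share one cached baseline, the baseline's own
  Monte-Carlo error is common to all of them, so those experiments use
  `n_mc` of 2000–4000; at screen scale, distinct masks decorrelate this term
  naturally.
* The validation suite uses 500 CSR nuclei per (R_eq, N) stratum for null
  calibration, 200 nuclei per Thomas-σ level for the monotonicity trend, 50
  rendered fields at SNR 10 for detection fidelity, 5000 cells for gating
  recovery, and 1000-gene screens (50 spiked genes at ±4 well-SD) for hit
  recovery — all chosen to keep each property's sampling error small
  relative to its acceptance band while remaining desk-scale.
* Degenerate inputs are contracts, not crashes: blank images give empty
  tables, `N < 2` gives missing scores, zero-spread plates fall back from
  MAD to SD to all-zero Z with a warning, unresolvable DAPI mixtures raise
  errors.

## Known limitations

The clustering score's exact published formulation lives in the high-content
tooling it originates from; this package's score is its own declared
definition with the same contracted properties, so absolute score values
should not be compared across implementations — Z-scores within a screen are
the comparable currency. Thresholded segmentation is synthetic-grade.
Radial-distance boundary distances are ray-marched at 0.1 px resolution,
adequate for per-cell means but not for single-spot boundary claims below
~0.5% relative error. The two-screen concordance assumes a shared gene
universe and does not model between-screen batch structure.

## A worked example

```{r example, eval = FALSE}
library(centroscreen)

design <- screen_design(n_genes = 96, seed = 1) |>
  spike_effects(n_spike = 8, effect = 4, seed = 2)
sim <- generate_screen_dataset(design)

calls <- analyze_screen(sim$cells, sim$layout)
dplyr::filter(calls, hit) |> classify_phenotype() |>
  dplyr::select(gene, mean_z_mean_clustering_score, phenotype)

autoplot(calls)
```
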