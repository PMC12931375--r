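---
title: "Methods: spot-level scoring of inflamed skin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot-level scoring of inflamed skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `spotscore`, the
choices we made where the design was genuinely open, what the synthetic
generator does and does not emulate, and the package's known limitations.

## Positivity model

The central primitive is spot positivity for a gene panel. A Visium spot
is a 55-µm capture area containing several cells; its column in the count
matrix holds raw unique-molecular-identifier (UMI) counts. We call a spot
positive for panel $G$ (with rule parameters $k$, $c$) when at least $k$
genes of $G$ each have a raw count $\ge c$; defaults are $k = 1$, $c = 1$.

Positivity is deliberately evaluated on **raw post-QC counts**, not on
normalized values. "A spot expresses gene $g$" has no threshold-free
reading on a continuous normalized scale, whereas a nonzero UMI is direct
molecular evidence of the transcript; this also keeps per-sample
percentages independent of other samples in the set. The cost is
sensitivity to sequencing depth: a shallow sample will call fewer
positives. `min_count` is configurable for users who want a stricter rule.

Quality control removes spots with fewer than 200 detected genes
(count $\ge 1$); "below 200" means a spot with exactly 200 detected genes
is retained. Genes are never removed by QC.

All percentages are reported with numerator and denominator, and an empty
scope yields a missing-value record rather than a silent zero — a 0/0 and
a 0/500 are very different observations.

## Conditional statistics

Polarization within anchor-positive spots classifies each CD68⁺ spot as
M1-only, M2-only or both. The default denominator is the CD68⁺ spots that
express **at least one** polarization marker, so the three fractions sum
to exactly 100 (the natural reading of a stacked-bar display); dividing by
all CD68⁺ spots instead is available via `denominator = "all_anchor"`.
The M1/M2 marker orientation follows the immunohistochemistry convention
(CD16 = FCGR3A as M1, CD163 as M2). Published text sometimes swaps the two
pairs, so `load_panels(m_orientation = "swapped")` provides the opposite
assignment; the choice affects only the labels, not the arithmetic.

Co-occurrence reports the outcome-panel positivity separately inside and
outside a conditioning stratum (e.g. apoptosis-marker positivity within
IFN-I-inflamed versus non-inflamed spots), again with both denominators
exposed.

## Normalization, embedding and clustering stand-ins

Downstream spot statistics in this package depend only on (i) raw-count
positivity and (ii) cluster labels. We therefore use deliberately simple,
deterministic stand-ins for the heavyweight single-cell machinery:

* `normalize_counts()` offers log CP10K, $\ln(1 + 10^4 c/\text{colsum})$,
  and analytic Pearson residuals under a negative-binomial null with
  $\hat\mu_{gs} = \text{rowsum}_g \cdot \text{colsum}_s / \text{total}$
  and fixed dispersion $\theta = 100$, clipped at $\pm\sqrt{n}$. These are
  variance-stabilizing transforms, not a regularized regression fit.
* `reduce_and_correct()` is PCA on the top 2,000 variance-ranked genes
  followed by per-batch mean-centering in PC space. This removes additive
  batch offsets only; it is not an iterative mixture-model integration.
  The SVD sign is fixed (largest-magnitude loading positive) so embeddings
  are bit-reproducible.
* `cluster_spots()` is seeded k-means (`nstart = 10`). Graph-based
  community detection with a resolution parameter is out of scope; users
  supply `k`. On the synthetic data the planted epidermis/dermis
  compartments separate on PC1 (AUC > 0.9 in tests) and are recovered
  exactly by k-means with `k = 2`.

These simplifications are visible in the API and should be kept in mind
when comparing cluster-level output against analyses using other toolchains.

## Marker detection

`find_markers()` is one-vs-rest per cluster: genes detected in at least
25% of either group are tested with a two-sided Wilcoxon rank-sum test on
the normalized values — exact enumeration when both groups have at most 10
tie-free observations, otherwise the tie-corrected normal approximation
(the two agree within 0.02 for group sizes 10–30 in tests). Fold change is
computed on de-logged means with pseudo-count $10^{-9}$, and BH adjustment
runs across the full tested set (all clusters jointly). Only upregulated
markers (log2FC ≥ 0.25, adjusted p ≤ 0.05) are returned, ordered by
cluster, then decreasing fold change, then gene symbol — the same ordering
used to take the top-300 marker sets for MIA.

## MIA and over-representation

The MIA score between a spatial cluster (marker set size $m$) and a
reference single-cell cluster (size $n$) in a shared universe of $N$ genes
with overlap $k$ is $-\log_{10} P(X \ge k)$ under the hypergeometric null
when $k$ is at or above its expectation $mn/N$, and the negative
$\log_{10} P(X \le k)$ otherwise (depletion); p values are floored at
$10^{-300}$. Ties at expectation break toward enrichment. The universe
defaults to genes detected in at least one spot of the merged spatial data
intersected with the reference genes, shared across all cluster pairs (a
per-pair universe is possible by calling `mia_enrichment()` per pair).
`enrich_gene_sets()` applies the same tail, one-sided, against any GMT
library, with BH across sets — a local replacement for web-service
enrichment so analyses run offline.

## Deconvolution

`score_spots()` solves, per spot, a non-negative least-squares problem
regressing the spot's CP10K profile onto L1-normalized reference cell-type
mean profiles (Lawson–Hanson NNLS), then rescales the coefficients to sum
to one. Unlike anchor-transfer prediction scores, these rows sum to 1 by
construction; for *threshold* summaries ("% of spots with myeloid score
above 0.5") this difference is immaterial, but absolute score values are
not comparable across methods. The threshold comparison is strict (`>`),
matching the reading of "above 0.5"; `strict = FALSE` gives `≥`. Scores
are invariant to global rescaling of a spot's counts, and on two-signature
synthetic mixtures the recovery RMSE is below 0.05 at realistic NB noise
(and exact to $10^{-6}$ without noise).

## Group comparisons

Per-sample percentages are compared with a pooled-variance two-tailed
Student t test by default — matching the spreadsheet/Prism convention used
for small-sample biopsy comparisons — with Welch and permutation
alternatives. The permutation test enumerates all
$\binom{n_1+n_2}{n_1}$ relabelings when that count fits the permutation
budget (exact p, a multiple of $1/\binom{n_1+n_2}{n_1}$), and otherwise
samples with the add-one correction $p = (1 + \#\{|T| \ge |T_{obs}|\}) /
(1 + B)$. With three samples per group the exact test's smallest
attainable p is 0.1, so the t test is the only route to conventional
significance at this design size — a limitation of the study design, not
of the software. No cross-panel multiplicity correction is applied
(`bh_adjust()` is available when one is wanted).

## The synthetic generator

`generate_dataset()` emulates the structure of a six-biopsy skin study:
per sample, a hexagonal grid (even array rows offset by one column, array
coordinates mirroring the Visium convention, pixel coordinates an affine
map) with the top rows labelled epidermis and the rest dermis. Counts are
negative binomial with variance $\mu + \mu^2/\theta$ — the standard UMI
overdispersion model — at $\theta = 2$ and baseline mean 0.05 per gene.

Defaults are the study conditions: 3 control + 3 lesion samples, 2,000
spots each, planted any-of-six ISG fractions
$(0.05, 0.05, 0.05, 0.90, 0.61, 0.90)$, anchor (CD68) fraction 0.25, and
anchor-conditional polarization probabilities $(0.15, 0.55, 0.15)$ for
M1-only / M2-only / both, biased toward M2 as in homeostatic skin.
Apoptosis flags are drawn at 0.6 given ISG-positive and 0.2 given
ISG-negative, planting the co-occurrence signal. Spots carrying a flag
have the corresponding panel genes' mean multiplied by 50 (to 2.5),
making positivity calls statistical but near-certain
($P(\text{all six ISGs zero}) \approx 6\times10^{-5}$).

One numerical subtlety motivated a deviation from the obvious "uniform
baseline" design: with every gene at baseline mean 0.05, an any-of-six
panel would have a ~26% *background* positivity rate
($1 - (1 - p_1)^6$ with $p_1 \approx 0.048$ per gene), swamping a planted
5% control fraction and making planted fractions unrecoverable by
construction. Flag-driven panel genes therefore sit at
`panel_off_mean = 0.001` in unflagged spots, keeping the background
any-of-six rate near 0.6% so that empirical fractions converge to the
planted values at binomial precision — the generator's defining invariant.

What the generator does **not** emulate: spatial autocorrelation beyond
the compartment bands, per-spot cell-type mixtures beyond two-signature
mixing, sample-to-sample depth variation, zero-inflation beyond NB, or
image-derived features. Passing recovery tests therefore demonstrates
correctness of the scoring arithmetic and its statistical calibration
under the planted model — not robustness to segmentation errors, spatial
bleed-through, or the biological ambiguity of 55-µm multi-cell spots in
real tissue.

`generate_scrna_reference()` plants disjoint marker sets (default fold 8
over baseline) in a shared gene universe; marker recovery under the stated
filters reaches ≥ 90% sensitivity at ≤ 10% observed FDR in tests.
`generate_label_mask()` renders non-overlapping disks with known areas;
rendered pixel areas match targets within 5% at the default 2 µm pixel
size. All generator draws derive from a single integer seed and are
bit-reproducible.

## In vitro quantifications

ΔΔCT assumes amplification efficiency 2 (no efficiency-corrected variant):
$\Delta CT = CT_{target} - CT_{housekeeping}$, referenced to the mean
$\Delta CT$ of the reference group, $RQ = 2^{-\Delta\Delta CT}$. RQ is
invariant to any constant shift of all CT values.

Cell areas from labelled masks are pixel counts times the squared pixel
size; the fraction of cells above 5,000 µm² (strict `>`, matching "area
of > 5,000 µm²") is the EMT summary. Border-touching cells are excluded by
default because clipped cells bias areas downward; disable with
`exclude_border = FALSE` when masks are known to be interior crops.

## Problem sizes and determinism

Tests and the acceptance script run at the study scale (6 × 2,000 spots,
~340 genes; reference of 240 cells over ~340 genes; 100 deconvolution
mixtures; 200-cell masks), which we consider representative for the
statistics involved — every quantity is a per-spot count or a rank test,
so gene-universe size affects runtime, not calibration. Every random draw
flows from an explicit integer seed; k-means uses a fixed `nstart`, the
SVD sign is pinned, and pipeline reruns with the same config and seed
produce byte-identical CSV output.

## Known limitations

* Cluster-level results use k-means on a linear embedding; fine-grained
  sub-populations found by graph clustering on real data will not be
  reproduced.
* NNLS scores are signature-regression weights, not calibrated
  probabilities; compare thresholded summaries, not raw scores, across
  methods.
* Positivity at `min_count = 1` is depth-sensitive; consider per-sample
  depth matching or a higher `min_count` for uneven libraries.
* The permutation test is exact but coarse for 3-vs-3 designs (minimum
  p = 0.1).
* PNG masks carry at most 255 labels (8-bit); use TIFF (16-bit) beyond
  that.
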