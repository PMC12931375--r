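# spotscore

Spot-level gene-set scoring for 10x Visium spatial transcriptomics of
inflamed skin, with a seeded synthetic-data generator so every stage is
testable without downloads.

## The problem

Type I interferonopathies such as ISG15 deficiency produce fibrotic skin
lesions whose pathology is driven by chronic type I interferon (IFN-I)
signalling. Spatial transcriptomics of skin biopsies lets us ask *where*
that signal lives: which fraction of capture spots express
interferon-stimulated genes (ISGs), whether inflammation is confined to the
epidermis or pervades the dermis, how macrophages inside CD68⁺ spots are
polarized (M1 vs M2), and whether apoptosis markers co-occur with the ISG
signature. `spotscore` implements these spot-level statistics as a reusable,
tested pipeline for anyone analysing Visium skin (or other tissue) data with
gene-panel positivity questions, together with the companion in vitro
quantifications (ΔΔCT relative expression, cell-area thresholds for
epithelial-to-mesenchymal transition).

## What it computes

* **Panel positivity.** A spot is positive for a panel
  $G = \{g_1,\dots,g_n\}$ when at least $k$ panel genes each have raw UMI
  count ≥ 1 (a *k-of-n* rule; $k=1$ for the six-gene ISG panel, $k=2$ or
  $5$ for apoptosis marker combinations). Per-sample percentages are
  reported per scope (total biopsy, epidermis, dermis, cluster) with
  numerators and denominators.
* **Conditional co-expression.** Within anchor-positive (CD68⁺) spots:
  the M1-only / M2-only / both polarization split (fractions sum to 100%),
  and conditional percentages such as cytokine or TGFB1 positivity.
* **Marker detection.** One-vs-rest two-sided Wilcoxon rank-sum tests with
  min-detection 25%, log2 fold-change cutoff 0.25 and Benjamini–Hochberg
  adjustment.
* **MIA.** Multimodal intersection analysis: hypergeometric enrichment
  between spatial-cluster and single-cell-cluster marker sets
  ($-\log_{10} P(X \ge k)$ for overlap $k$, top 300 markers per cluster).
* **Deconvolution.** Non-negative least-squares regression of each spot's
  CP10K profile onto reference cell-type signatures, with
  percent-of-spots-above-threshold summaries (e.g. myeloid score > 0.5).
* **Group comparisons.** Two-tailed Student/Welch t tests or exact
  permutation tests on per-sample percentages.
* **In vitro readouts.** ΔΔCT relative quantification
  ($RQ = 2^{-\Delta\Delta CT}$) and labelled-mask cell-area fractions
  (e.g. % of cells larger than 5,000 µm²).

The synthetic generator plants all of these quantities (per-sample inflamed
fractions, anchor-conditional polarization, apoptosis–ISG dependence,
cluster markers, mask cell areas) with recorded ground truth, so parameter
recovery is verifiable end to end.

## Worked example

```r
library(spotscore)

cfg    <- sim_config(seed = 7)        # 3 control + 3 lesion, 2000 spots each
d      <- generate_dataset(cfg)
panels <- load_panels()

report <- geneset_percent(d$samples, panels$isg, d$annotation, scope = "total")
report[, c("sample_id", "group", "percent", "numerator", "denominator")]
#>   sample_id   group percent numerator denominator
#> 1 control_1 control    5.55       111        2000
#> 2 control_2 control    4.80        96        2000
#> 3 control_3 control    5.75       115        2000
#> 4  lesion_1  lesion   89.95      1799        2000
#> 5  lesion_2  lesion   61.70      1234        2000
#> 6  lesion_3  lesion   90.60      1812        2000

compare_groups(report$percent[report$group == "control"],
               report$percent[report$group == "lesion"])
#> <group_comparison> student: control 5.37 vs lesion 80.75, p = 0.001383

conditional_polarization(d$samples$samples[["lesion_1"]],
                         panels$anchor_cd68, panels$m1_markers,
                         panels$m2_markers)
#>   sample_id category  percent numerator denominator
#> 1  lesion_1   A_only 20.13652        59         293
#> 2  lesion_1   B_only 64.16382       188         293
#> 3  lesion_1     both 15.69966        46         293
```

The ISG percentages recover the planted per-sample fractions (5%, 5%, 5%,
90%, 61%, 90%) to binomial precision; the polarization rows give the
M1-only / M2-only / both split among CD68⁺ spots that express at least one
polarization marker (A = M1, B = M2), summing to 100%. `run_pipeline()`
chains all stages (QC → merge → normalize → embed → cluster → markers →
MIA → deconvolution → scores → comparisons) into a directory of CSV
reports with a manifest and log; reruns with the same config and seed are
bit-identical.

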