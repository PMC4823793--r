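---
title: "Quantifying copy-number status and tumour heterogeneity in bright-field ISH images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying copy-number status and tumour heterogeneity in bright-field ISH images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dual-colour chromogenic/silver in situ hybridization (DISH) visualizes a gene
locus as near-black silver dots and the matching chromosome enumeration probe
(CEP) as red dots on hematoxylin-counterstained, bright-field tissue.
Copy-number status of the locus — deletion or amplification — is classically
scored by counting dots inside individual nuclei, which demands accurate
nucleus segmentation and suffers from sectioning artifacts that truncate
nuclei and delete dots from the section plane.

`dishquant` implements a region-based alternative: detect every dot-like
signal in a tissue region, classify each one, and score the region by the
ratio of all gene signals to all CEP signals. Because sectioning loss hits
the gene and CEP channels equally, the ratio is robust to it, and no
single-cell recognition is needed. On top of the global score, the package
quantifies spatial heterogeneity of the ratio through randomized local
statistics.

## The workflow

1. **Preprocess** — images are resized by bicubic interpolation into a
   4096 × 4096 working frame (whole slides are instead processed as native
   4096-pixel tiles, preserving the per-unit scale). A tissue mask is
   computed by thresholding luminance and saturation with a morphological
   clean-up.
2. **Detect** — a two-stage, gradient-voting circular Hough transform finds
   dot signals of radius 3–12 px. Edge pixels vote along their gradient
   direction over the radius range; accumulator peaks above
   `vote_floor / sensitivity` become detections after non-maximum
   suppression; each detection's radius is then estimated from the gradient
   support in its annulus. Two passes are run — one on the inverted-luminance
   channel (dark silver dots) and one on the red-chroma channel (red CEP
   dots) — and merged by non-maximum suppression.
3. **Classify** — each detection yields a 14-dimensional appearance vector
   (RGB means and SDs in the signal disk, CIELAB a*/b*, radius, ring–disk
   contrast, luminance, boundary gradient, saturation, luminance SD). An
   RBF-kernel SVM with inverse-frequency class weights assigns one of five
   classes: `GENE`, `CEP`, `GENE_CEP_MIXED` (colocalized pair), `NOISE`,
   `CELL_STAIN`. Hyperparameters come from a grid search
   (cost ∈ {0.1, 1, 10, 100}; kernel width 2⁻⁴…2² × the median heuristic)
   inside stratified 5-fold cross-validation.
4. **Score** — the global ratio is all gene signals divided by all CEP
   signals; colocalized mixed signals contribute one to each side under the
   default `count_both` policy (a colocalized pair contains one of each;
   `exclude` is available for sensitivity analysis). A ratio at or below
   0.60 calls `DELETION` (boundary inclusive); at or above 2.0, in
   amplification assays, `AMPLIFICATION`. Data-driven thresholds come from
   ROC analysis (rank-statistic AUC, percentile bootstrap CI over 1,000
   case-resampled replicates, Youden-optimal operating point by default with
   closest-to-(0,1) as an alternative).
5. **Heterogeneity** — for each core, 300 points are drawn uniformly over
   the tissue mask and snapped to their nearest *unused* CEP signal (each
   CEP anchors at most one neighbourhood — our reading of sampling "without
   replacement"). All gene and CEP signals within 60 px of each anchor give
   a local ratio (genes/CEPs, the anchor included in the CEP count) and a
   local density (their sum). Each core is summarized by mean, median and
   SEM of the two distributions (6 features), the cohort is z-scored and
   embedded by PCA into two dimensions, a three-component Gaussian mixture
   recovers the homogeneous-deletion / homogeneous-non-deletion /
   heterogeneous classes, and each core's Mahalanobis distance to the
   homogeneous-deletion component (the component whose members have the
   lowest mean local ratio) grades its heterogeneity. Robustness is probed
   by 100 perturbation repetitions varying the number of random points from
   201 to 300; each core's repetition cloud is drawn as a 95% confidence
   ellipse (covariance eigen-axes scaled by the χ²₂ 0.95 quantile — we read
   the ellipse as the repetition cloud's spread, not the CI of its mean,
   since the point of the experiment is to visualize sensitivity to the
   randomization).

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `target_size` | 4096 px | working frame side; 2¹² for efficient tiling |
| `radius_min`, `radius_max` | 3, 12 px | Hough radius range (≈0.3–1.3 µm at 0.11 µm/px) |
| `sensitivity` | 0.5 | detection threshold = `vote_floor`/sensitivity; monotone in count |
| `vote_floor` | 0.35 | accumulator floor at sensitivity 1, calibrated on planted-disk scenes |
| `min_separation` | 2 × `radius_min` | non-maximum suppression radius |
| `deletion_threshold` | 0.60 | ratio at/below calls deletion (inclusive) |
| `amplification_threshold` | 2.0 | ratio at/above calls amplification |
| `n_random` | 300 | anchors per core |
| `radius` (local) | 60 px | neighbourhood radius; holds several adjacent cells |
| `k_max` | 5 | AIC scan range for the mixture size |

The exact Hough tuning of the original workflow is not published, so the
detection defaults are engineering choices, deliberately exposed in
`detection_params()`.

## The synthetic-data generator

Ground-truthed validation data are generated, not downloaded. A core is a
disk of tissue on a 4096-px canvas holding ~420 cells placed by a hard-core
process inside Thomas-like tumour nests (nest scatter SD 70 px, within-nest
spacing 40 px) — dense nests are what makes a 60-px neighbourhood contain
several adjacent cells, the stated rationale for the 60-px default. Each
cell emits Binomial(copies, 1 − loss) gene dots and Binomial(2, 1 − loss)
CEP dots (loss 0.15, equal in both channels, so the expected ratio is
loss-invariant); gene/CEP pairs colocalize into mixed signals with
probability 0.05. Background noise dots and large diffuse cell stains are
added so that a core carries 1,000–5,000 signals of which roughly 30% are
gene/CEP — the realistic regime in which most detections are *not* probe
signals. Six prototypes cover homozygous deletion (with a benign rim
retaining two copies), hemizygous deletion, non-deletion, cellular
heterogeneity with homogeneous or heterogeneous genotype (hypercellular,
two-population nest layouts), and spatially organized ITH (half-plane
split). `cohort_specs()` assembles study cohorts in which purity, loss and
cellularity jitter per core, so cohorts form the ratio continuum real
tissue shows rather than six point clusters.

What the generator does *not* emulate: real chromogen texture, nuclear
morphology, overlapping signal clusters inside single nuclei, focus
gradients, or scanner-specific colour response. Passing tests therefore
demonstrate correctness of the algorithms against a controlled model of the
imagery, not clinical-grade performance on scanner output.

## Numerical choices

* **EM for the Gaussian mixture** uses k-means initialization, 10 seeded
  restarts and full covariances. Because the mixture likelihood is unbounded
  at collapsing components — and best-of-restarts would systematically find
  those degenerate optima — the M-step shrinks covariances toward
  pooled-covariance/k with prior weight ν = 4 (MAP-EM, as model-based
  clustering software applies). AIC = 2p − 2 log L with p = 6k − 1 free
  parameters in 2-D.
* **AIC on null data** retains its well-known liberality: on a single
  Gaussian it still selects k = 1 in ~80% of draws (and k = 1 is always the
  modal choice); on well-separated three-cluster data it selects k = 3
  essentially always.
* **PCA signs** are fixed by making each component's largest-magnitude
  loading positive, so embeddings are reproducible across runs.
* **Ties** in non-maximum suppression and deduplication break by
  (strength desc, x asc, y asc), making merged detections independent of
  tile enumeration order.
* **Degenerate inputs**: a zero CEP denominator yields an undefined ratio
  and no status call; constant feature columns are dropped from the PCA
  with a warning; singular component covariances refuse a Mahalanobis
  distance.
* **Seeds**: every randomized operation takes an explicit seed and restores
  the caller's RNG state (`withr::with_seed`), so seeded outputs are
  byte-stable.

## Design choices where the method description is open

* **Mixed signals** enter both the numerator and denominator by default: a
  colocalized pair contains one gene and one CEP signal. The alternative
  (`exclude`) is exposed because the original description is silent.
* **Anchor sampling "without replacement"** is read as: uniform spatial
  draws snap to the nearest CEP not already used as an anchor.
* **The subclass analysis** fixes k = 3 components (deletion,
  non-deletion, heterogeneous), with AIC selection over k = 1…5 available
  as `select_k_by_aic()` for determining the count from data.
* **ROC optimality** defaults to Youden's J — the equal-cost special case
  of the slope criterion — with `closest_topleft` as an alternative.
* **Mahalanobis covariance** is the reference component's own covariance
  (not pooled), matching the "distance in SDs from that class" reading.

## Problem sizes used in the validation suite

Unit tests run on 512–1024-px cores; the end-to-end validation uses ten
full 4096-px cores for detection recovery, twenty for ratio recovery, ten
72-core cohorts for the heterogeneity ordering, one-hundred 71-point draws
for mixture selection, and one 16,384² sixteen-core mosaic for the
whole-slide path. These sizes were chosen to exercise the study's operating
conditions while keeping the suite comfortably reproducible on a laptop.

## Known limitations

* Parity with the original implementation's tuned parameters is not
  claimed; only the method is reproduced.
* The classifier is trained on synthetic renderings; applying it to real
  scanner output requires retraining on annotated real crops
  (`train_classifier()` accepts any annotation table).
* Colour deconvolution, nucleus segmentation and proprietary slide formats
  are out of scope.
* At default densities the local neighbourhoods hold ~5–10 signals, so
  single-core local ratios are noisy; the randomized statistics are meant
  to be interpreted at the distribution level, as done here.
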