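# dishquant

Region-based quantification of gene copy-number status and multi-level
tumour heterogeneity in bright-field dual-colour in situ hybridization
(DISH) images.

## What it does, and for whom

In a DISH assay a gene probe (e.g. *PTEN*, 19q12, *HER2*) appears as
near-black silver dots and the matching chromosome enumeration probe (CEP)
as red dots on hematoxylin-counterstained tissue. Pathology labs
traditionally score copy number by counting dots inside individual nuclei —
slow, subjective, and sensitive to sectioning artifacts that truncate
nuclei. `dishquant` is for computational pathology groups who want the
region-based alternative:

* **Detection** — a gradient-voting circular Hough transform finds every
  dot-like signal (1,000–5,000 per tissue core; millions per whole slide)
  without any nucleus segmentation.
* **Classification** — an RBF-kernel SVM labels each detection `GENE`,
  `CEP`, `GENE_CEP_MIXED` (colocalized pair), `NOISE` or `CELL_STAIN` from
  14 colour/intensity/shape features.
* **Scoring** — the *global ratio* of a region is

  `R = (#GENE + #MIXED) / (#CEP + #MIXED)`

  and status is called against thresholds: `R <= 0.60` → deletion
  (boundary inclusive), `R >= 2.0` → amplification. Because sectioning
  loss hits both channels equally, `R` is robust to it. ROC analysis with a
  1,000-replicate percentile bootstrap optimizes data-driven thresholds.
* **Heterogeneity** — the *randomized local ratio* (RLR) and *density*
  (RLD): 300 random points per core snap to their nearest unused CEP
  signal; each 60-px neighbourhood yields a local gene/CEP ratio and a
  local signal count. The per-core 6-feature summary (mean, median, SEM of
  both) is embedded by PCA into two dimensions, clustered by a Gaussian
  mixture (AIC-selected over k = 1…5, or the fixed 3-class subclass model),
  and graded by Mahalanobis distance to the homogeneous-deletion component.
  Perturbation ellipses (100 reruns varying the number of random points
  from 201 to 300) visualize the robustness of each core's position.
* **Synthetic truth** — a generator plants fully ground-truthed cores for
  six heterogeneity prototypes (homozygous/hemizygous deletion,
  non-deletion, two cellular-heterogeneity variants, spatial ITH), whole
  slide mosaics, and balanced training sets, so every stage is validated
  against known truth.

## Worked example

```r
library(dishquant)

# a synthetic hemizygous-deletion core with full ground truth
spec  <- core_spec("HEMIZYGOUS_DELETION", seed = 7)
truth <- generate_point_set(spec)
img   <- render_core(truth, spec)

# classifier trained on synthetic annotated signals
clf <- train_classifier(generate_training_set(crops_per_class = 150, seed = 42),
                        seed = 42)

pts   <- detect_signals(img, truth$mask)
pts   <- classify_signals(clf, img, pts)
score <- call_status(global_ratio(pts), threshold_config())
score[, c("gene_count", "cep_count", "mixed_count", "global_ratio", "status")]
#> # A tibble: 1 x 5
#>   gene_count cep_count mixed_count global_ratio status
#>        <int>     <int>       <int>        <dbl> <chr>
#> 1        332       685          21         0.50 DELETION
```

The core was planted with one gene copy and two CEP copies per cell, so the
true ratio is 0.5; the pipeline recovers 0.500 ((332 + 21)/(685 + 21)) from
the rendered image and calls `DELETION` at the 0.60 threshold. Heterogeneity statistics chain the
same way:

```r
hp      <- heterogeneity_params(seed = 1)        # n_random = 300, radius = 60
anchors <- sample_anchor_points(pts, truth$mask, hp)
feats   <- summarize_features(compute_rlr_rld(pts, anchors, hp))
round(as.data.frame(feats), 3)
#>   rlr_mean rlr_median rlr_sem rld_mean rld_median rld_sem
#> 1    0.524        0.5   0.018    6.827          7   0.172
```

The local-ratio distribution of this spatially homogeneous core sits
tightly around the planted 0.5 (SEM 0.018 over 300 neighbourhoods); an ITH
core of the same global ratio would show a strongly dispersed, bimodal RLR
instead.

For a cohort, `cohort_specs()` builds 72 mixed-prototype cores;
`embed_pca()`, `fit_gmm(k = 3)`, `identify_reference_component()` and
`mahalanobis_distances()` reproduce the subclass analysis, and
`render_embedding()` / `autoplot()` draw the figures. A thin command-line
interface covering simulate/train/detect/classify/score/heterogeneity/
render/pipeline is installed at
`system.file("cli", "dishquant", package = "dishquant")`.

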