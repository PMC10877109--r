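# histoclust

Weakly supervised classification of primary liver cancers from
routine-stained biopsy whole-slide images.

Distinguishing hepatocellular carcinoma (HCC), intrahepatic
cholangiocarcinoma (iCCA) and combined cHCC-CCA tumours — and quantifying
the *contingents* (the share of each differentiation type within one
lesion) — normally requires expert review and immunohistochemistry.
`histoclust` implements a pipeline that needs only coarse tumour/non-tumour
outlines:

1. **Tile** annotated slides into fixed-size patches at a fixed physical
   scale (125 µm → 256 px by default), masking the blank background and
   labelling border patches by the majority of their pixels.
2. **Augment** training tiles with a plausibility-restricted family
   (±2% hue, −80%…+60% saturation, ±20% brightness, flips, ±90° rotations,
   3×3 Gaussian blur, 1.0–1.2 scale jitter), with patient-level separation
   of training and validation slides.
3. **Learn** a convolutional tumour/non-tumour classifier from the weak
   labels (Adam, exponential learning-rate decay, optionally frozen early
   layers) and pool its last convolutional layer into one feature vector
   per tumour tile.
4. **Cluster** the tumour tiles: PCA halves the feature dimension, a
   K-component Gaussian mixture fitted by expectation-maximization groups
   the tiles, and clusters are mapped to tumour types by majority vote on
   slides with an unambiguous diagnosis.
5. **Report** per-slide cluster proportions, the predicted major
   contingent, diagnostic agreement per pathology group (half-up rounded
   percentages), and Pearson correlations against quantitative IHC
   contingents (hepatocellular contingent = max of glypican-3 and
   anti-hepatocyte positive-cell ratios; cholangiocellular = CK7 ratio).

A seeded phantom-biopsy simulator with exact per-pixel ground truth
(`generate_slide()`, `generate_cohort()`) makes the whole pipeline testable
end-to-end without any real slide: curved tissue strips carry two
procedurally generated tumour textures (eosinophilic cell sheets vs.
ring/gland motifs in saffron stroma) at controllable mixing fractions.

## Worked example

```r
library(histoclust)

study <- run_phantom_study(n_A_pure = 10, n_B_pure = 10, n_mixed = 10, seed = 1)
study
#> <phantom_study> 30 slides, 504 tumour tiles, K = 2
#>   weak classifier validation accuracy: 0.958
#>   pure-slide major-contingent accuracy: 1.00
#>   mixed-slide correlation with true contingent: 0.962

study$cluster_map
#> Cluster 0 -> HCC (96% of reference tiles)
#> Cluster 1 -> iCCA (100% of reference tiles)

study$metrics$agreement_table
#> # A tibble: 3 x 5
#>   pathology_diagnosis n_cases n_concordant agreement_fraction agreement_pct
#>   <chr>                 <int>        <int>              <dbl>         <dbl>
#> 1 HCC                      10           10                1             100
#> 2 cHCC-CCA                 10            9                0.9            90
#> 3 iCCA                     10           10                1             100
```

Reading the output: the weak classifier separated tumour from non-tumour
tissue on held-out slides at 0.958 tile accuracy; the two mixture clusters
were 96% and 100% pure with respect to the reference tumour types; every
pure slide's predicted major contingent matched its diagnosis; and on the
ten mixed slides the predicted hepatocellular share tracked the generator's
true contingent fraction with r = 0.96. `autoplot(study$model)` shows the
training curves, `plot_slide_composition(study$reports)` the per-slide
cluster pies, and `reconstruct_label_map()` paints cluster labels back onto
a slide.

Individual stages are ordinary functions over tibbles — `extract_patches()`,
`build_training_set()`, `train_weak_classifier()`, `extract_features()`,
`reduce_pca()`, `fit_gmm()`, `assign_clusters()`, `diagnostic_agreement()` —
so each can be used, inspected and tested on its own. A thin command-line
front end over the same functions lives at `inst/cli/histoclust.R`
(`simulate`, `tile`, `run` subcommands).

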