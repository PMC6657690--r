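# fibreseg

Semi-automatic detection and measurement of muscle fibres in
fluorescence-stained cross-section images (WGA or antibody membrane
stains), for muscle physiology labs quantifying fibre cross-sectional area
(CSA) distributions and for methodologists comparing segmentation
strategies.

Real slides defeat purely intensity-based border detectors: membranes have
holes, fibres carry speckle of varying distribution, interstitial (gap)
regions are noisy, and slide stitching introduces brightness steps.
`fibreseg` implements a combined supervised-learning / computer-vision
pipeline:

1. **Pixel classification** — a 100-tree random forest over a 13-channel
   feature stack (Gaussian-smoothed intensity at σ = 0.3, 0.7, 1.0, 1.6,
   3.5 px; Hessian-of-Gaussian eigenvalue pairs at σ = 1.6, 3.5, 5.0,
   10.0 px), trained from sparse brush annotations over four texture
   classes (border / gap / big fibre / small fibre). The *border* class
   defines the initial clusters: connected regions fully enclosed by
   border pixels.
2. **Watershed separation** — borders are dilated to seal small holes;
   each cluster interior is distance-transformed and thresholded at
   `d ≥ τ · max(d)` (τ = 0.3 is a good working value, maximum taken per
   cluster); the surviving components seed a marker-based watershed that
   separates touching fibres.
3. **Geodesic active contour (GAC) reconstruction** — each separated
   cluster re-inflates to the membrane under the morphological GAC with
   attraction field `g(I) = 1/sqrt(1 + α|∇G_σ ⊗ I|)` (α = 2000, σ = 2,
   balloon ν = +1, smoothing μ = 3, gate θ = 0.3), and the resulting
   fibres are measured (CSA, Feret diameter, perimeter, centroid).

The package also provides the classical CV-only reference pipeline
(single-scale Hessian ridge likelihood at σ\* = 0.7, Otsu binarisation,
closing/dilation/inversion cluster extraction, iterative 8×8 elliptical
erosion below 5000 px²), an evaluation framework (reference clusters,
separation sensitivity `a/(a+d)` with paired bootstrap tests, Dice
similarity, KL divergence of area distributions), and a deterministic
synthetic cross-section generator with exact groundtruth so everything is
testable without microscopy data.

## Worked example

Generate a noisy synthetic section, train a classifier from sparse
annotations on two further sections, and run both pipelines:

```r
library(fibreseg)

cfg   <- run_config(preprocess = preprocess_config(30))
train <- generate_benchmark(2, "moderate", seed = 900)
clf   <- train_on_samples(train, cfg, seed = 1)

sample <- generate_cross_section(synthetic_config(
  border_hole_rate = 0.12, speckle_sd = 8, gap_noise_sd = 6, seed = 11))
out <- run_slcv(sample$image, clf, cfg)
nrow(out$table)          # number of reconstructed fibres
head(out$table, 3)
```

```
[1] 20
# A tibble: 3 × 6
  fibre_id  area feret centroid_row centroid_col perimeter
     <int> <dbl> <dbl>        <dbl>        <dbl>     <dbl>
1        1   607  33.5         39.6         57.4      95.2
2        2  2316  72.9         50.7        213.      194. 
3        3  1274  51.2         42.6        114.      141. 
```

Each row is one reconstructed fibre: `area` is its CSA in px², `feret`
the maximum caliper diameter, and the centroid locates it in the image
(1-based row/col). The sample contains 21 groundtruth fibres; matching
the detections against the groundtruth:

```r
m <- match_detections(out$labels, sample$groundtruth)
nrow(m$pairs); mean(m$pairs$dice)
```

```
[1] 20
[1] 0.8993864
```

20 of 21 cells are recovered one-to-one with a mean Dice similarity of
0.90 (one cell of a pair merged by a membrane hole stays unseparated in
this image). The three-way comparison on a 20-image benchmark —
`run_compare(generate_benchmark(20, "moderate", seed = 7), clf, cfg)` —
reports mean separation sensitivity per reference-cluster size, paired
bootstrap p-values, Dice summaries and KL-divergence curves;
`plot_sensitivity()` and `plot_kl_curves()` draw them.

A thin command-line wrapper over these functions is installed at
`inst/cli/fibreseg.R` with subcommands `synth`, `train`, `segment`,
`reference`, `evaluate` and `compare`.

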