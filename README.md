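# spgdetect

Detection of **spatially predictive genes (SPGs)** in spatial transcriptomic
data.

Most spatial statistics ask whether a gene's expression *varies* across a
tissue (spatially variable genes, SVGs). `spgdetect` asks a different
question: which genes' expression, taken together, *predicts where a spot
is*? A gene need not be regionally restricted to carry positional
information — broadly expressed genes can jointly encode a coordinate
system. SPGs are found by training a model to map expression to position
and then asking which input genes the trained model relies on.

## Method

For each slide (a spots × genes count matrix with per-spot (x, y)
coordinates), the pipeline:

1. **Filters and normalizes.** Spots with < 200 detected genes are removed,
   as are genes with < 10 total reads or detection in < 2 spots; counts are
   log1p-CPM transformed (library size 10,000) with optional per-gene
   standardization, and genes with expression variance < 0.05 are dropped
   before training.
2. **Trains a coordinate-regression network.** A dense feedforward network
   (each hidden block: fully connected layer → batch normalization → ReLU;
   He-normal initialization; Adam) maps a spot's expression to its (x, y)
   position. Hidden widths halve layer to layer and total ≈ half the input
   size. The loss and evaluation metric is the mean distance error

   MDE = (1/N) Σₙ √((x′ₙ − xₙ)² + (y′ₙ − yₙ)²),

   the average Euclidean distance between predicted and true positions in
   slide units. Hidden-layer count {1, 3, 5} and learning rate
   {0.1, 0.01, 0.001} are tuned by 10-fold cross-validation (8 folds train,
   1 validates for early stopping, 1 tests), and the winning grid point's
   within-fold models are kept.
3. **Attributes predictions to genes.** DeepLIFT (Rescale rule, all-zero
   reference) assigns each gene g a signed contribution C₉ˢ to each spot
   s's prediction, satisfying summation-to-delta: Σ₉ C₉ˢ = t − t₀. Every
   spot is attributed by the model that held it out (its test-fold model),
   so importance is never measured on training data. Importance is the
   magnitude Imp₉ˢ = |C₉ˢ|.
4. **Aggregates and calls SPGs.** Per slide: MeanImp₉ (mean over spots),
   MNI₉ (mean over spots with nonzero importance), PNI₉ (% spots with
   nonzero importance). Across a patient's slides these average to CSMI,
   CSMNI and CSPNI. SPGs are genes with CSMI > 0.15 (seed set), plus genes
   rescued by CSMNI ≥ min(seed CSMNI) and CSPNI > 20 — regionally strong
   genes a slide-wide mean would miss.

A seeded negative-binomial simulator (`simulate_patient()`) generates
grid-slide "patients" with planted coordinate-encoding, patch-restricted
and noise genes, so the full pipeline can be benchmarked against known
ground truth (`evaluate_recovery()`).

## Worked example

```r
library(spgdetect)

sim <- simulate_patient(n_slides = 3, seed = 1)   # 225 spots, 60 genes/slide
res <- run_spg_pipeline(sim$slides, min_genes = 30,
                        layers = 1, learning_rates = 0.01, k = 10, seed = 1)
#> [slide1] 225 spots x 60 genes (counts)
#> [slide1] after filters: 225 spots x 60 genes (0 removed by variance filter)
#> [slide1] CV-MDE 4.538 (best: 1 layer(s), lr 0.01; null 11.46)
#> [slide2] CV-MDE 4.825 (best: 1 layer(s), lr 0.01; null 11.46)
#> [slide3] CV-MDE 5.111 (best: 1 layer(s), lr 0.01; null 11.46)
#> SPGs called: 60 of 60 genes (60 seed, 0 rescued)
```

Each slide's cross-validated MDE (≈ 4.5–5.1 coordinate units; spots are 2
units apart) is well below the centroid-null baseline of 11.46 — the
expression encodes position. The top of the score table recovers the
planted signal:

```r
head(res$table[order(-res$table$csmi),
               c("gene_id", "csmi", "csmni", "cspni", "spg_reason")], 8)
#>     gene_id  csmi csmni cspni spg_reason
#>  g005_coord 1.898 1.898   100  csmi_seed
#>  g006_coord 1.847 1.847   100  csmi_seed
#>  g001_coord 1.804 1.804   100  csmi_seed
#>  g004_coord 1.742 1.742   100  csmi_seed
#>  g002_coord 1.732 1.732   100  csmi_seed
#>  g012_patch 1.551 1.551   100  csmi_seed
#>  g007_patch 1.109 1.109   100  csmi_seed
#>  g011_patch 0.702 0.702   100  csmi_seed

evaluate_recovery(sim$truth, res$table)$median_rank
#> coordinate_encoding               noise           patch_svg
#>                 3.5                35.5                11.5
```

Planted coordinate-encoding genes occupy the top CSMI ranks (median 3.5 of
60), patch genes rank next, noise genes last. On this synthetic panel the
absolute CSMI scale sits far above the default 0.15 cutoff, so the seed
stage alone calls all genes; the cutoff is a user parameter meant to be
placed on the data's own importance scale (see the methods vignette).

Real slides are read with `read_slide()` (MatrixMarket triplet or dense
TSV, plus a `spot_id / x / y` coordinate table), and `cross_slide_validate()`
checks a patient's model across serial sections after center alignment.
`inst/scripts/spg-pipeline.R` wraps the pipeline for shell use with a YAML
config.

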