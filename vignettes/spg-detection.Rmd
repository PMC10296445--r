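---
title: "Detecting spatially predictive genes: model, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spatially predictive genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spgdetect` identifies genes whose joint expression predicts where a spot
sits on a spatial-transcriptomic slide. This vignette is the package's own
account of the method: the model and its assumptions, the parameters that
matter, the numerical conventions, and what the synthetic benchmark does
and does not demonstrate.

## The model

Each slide is a spots × genes matrix with per-spot coordinates (x, y) in
the platform's native units (we treat the units as opaque; on Visium-style
grids neighbouring spots are about two units apart). A dense feedforward
network maps one spot's normalized expression vector to its coordinates:

* hidden block = fully connected layer → batch normalization → ReLU
  (`max(0, x)`);
* output = a linear 2-node layer for (x, y);
* He-normal weight initialization, Adam optimization;
* loss = mean distance error (MDE), the average Euclidean distance between
  predicted and actual positions. MDE is in coordinate units, which keeps
  the reported error physically interpretable (e.g. "2.3 spot spacings").

The core assumption is that positional information is present in
expression *jointly*: no single gene needs to trace a coordinate, but the
trained network can only predict position if some set of genes encodes it.
Prediction skill is always judged against the **centroid null** — the
predictor that puts every spot at the mean coordinate — whose MDE sets the
scale of "no information".

### Architecture rule

Hidden widths halve from layer to layer and their **total** is as close as
possible to half the input size: with L layers and S = Σⱼ 2⁻ʲ
(j = 0..L−1), the first width is n/(2S) and layer j is that (unrounded)
base divided by 2ʲ⁻¹, rounded half-even. So `plan_architecture(1000, 3)`
gives 286, 143, 71 (total 500). An alternative reading — first hidden layer
= n/2, then halving — is available via `first_layer_half = TRUE`; we default
to the total-≈-half reading because it keeps total capacity constant while
the depth is tuned, which makes the depth grid a fair comparison. Widths
below 2 or non-decreasing sequences are an error rather than being clamped
silently.

### Training controls

| parameter | default | notes |
|---|---|---|
| batch size | 32 | minibatch SGD granularity |
| max epochs | 100 | cap per fold |
| early-stopping patience | 10 epochs | monitors validation MDE; best-validation weights (including batch-norm running statistics) are restored |
| learning-rate grid | 0.1, 0.01, 0.001 | Adam step size |
| hidden-layer grid | 1, 3, 5 | model depth |
| k (folds) | 10 | 8 train / 1 validation / 1 test |

The patience value is a package choice (the stopping criterion itself is
fixed: no validation improvement). For test fold i the validation fold is
(i+1) mod k — a deterministic pairing so that a seeded run is exactly
reproducible. Grid ties are broken toward fewer layers, then the smaller
learning rate (prefer the simpler model). Coordinates are trained in raw
slide units; no target standardization is applied, so the loss curve is
directly comparable to the reported MDE.

Everything is seeded: fold assignment, weight initialization and batch
shuffling all derive from the run seed, and training is single-threaded
base-R matrix arithmetic, so two runs with the same seed agree bitwise.

## Attribution

After cross-validation, DeepLIFT (Rescale rule) is applied to each spot
using the model **for which that spot was in the test fold** — importance
is never computed by a model that trained on the spot. The reference input
is the all-zeros vector, i.e. the zero point of the normalized expression
scale. Numerical conventions:

* batch-norm layers are attributed in inference mode, where they are plain
  affine maps;
* the ReLU multiplier is the rescale slope (a − a₀)/(z − z₀), falling back
  to the local gradient when |z − z₀| < 1e−7;
* under these rules summation-to-delta, Σ₉ C₉ˢ = t − t₀, holds to float
  precision for every spot (the test suite checks a 1e−3 relative bound
  and observes ~1e−14).

The network has two outputs, so a scalar attribution target must be
chosen. The default target is t = x′ + y′ (the sum of both outputs);
`per_axis_x` / `per_axis_y` modes are available and the mode is recorded on
the result, since the choice is a genuine convention rather than something
the method dictates.

## Gene scores and the SPG call

With Imp₉ˢ = |C₉ˢ|:

* **MeanImp₉** — mean importance over all spots of a slide;
* **MNI₉** — mean over spots with importance > 0 (0 when there are none);
* **PNI₉** — percentage of spots with importance > 0;
* **CSMI / CSMNI / CSPNI** — unweighted means of the above across a
  patient's slides.

The "non-zero" cutoff is exactly 0 by default (`zero_tol` is exposed for
float-noise robustness). The slide-wide mean and the non-zero pair answer
different questions: MeanImp rewards genes that matter everywhere; MNI and
PNI surface genes that matter strongly in a subset of spots.

SPGs are called in two stages: genes with CSMI > 0.15 seed the set; then
genes with CSMNI ≥ the minimum seed CSMNI *and* CSPNI > 20 are rescued.
Both comparisons at the seed threshold are strict (a gene at exactly 0.15
is excluded); the rescue comparison is inclusive (≥), which is the reading
that keeps the seed set itself self-consistent under its own rule. If no
gene passes the seed stage the call is empty, with a warning, rather than
rescuing against an undefined minimum.

**The CSMI cutoff is a user parameter, not a constant of nature.**
Importance is measured in coordinate units per gene, so its scale depends
on the slide's coordinate range and the number of genes sharing the
attribution budget. On a transcriptome-wide panel, 0.15 lands in the upper
percentiles of the importance distribution; on the 60-gene synthetic panel
below, nearly every gene clears it. Users should place the cutoff on their
own data's importance scale (e.g. at a chosen percentile).

A mean-vs-median switch (`agg = "median"`) recomputes every aggregation
with medians; the package reports, but does not assert, the correlation
between the two scoring schemes.

## Cross-slide validation

To check that a model generalizes across serial sections, three slides are
rotated through train/validation/test roles in the fixed order 1-2-3,
2-3-1, 3-1-2. Before each rotation the validation and test slides are
translated so their coordinate centers (mean x, mean y) coincide with the
training slide's — a pure translation, so within-slide geometry is
untouched. Gene sets are intersected across slides (with a warning) when
per-slide filtering disagrees, and the model is retrained on the full
training slide at the hyperparameters chosen by that slide's
cross-validation.

## The synthetic benchmark

`make_ground_truth()` / `simulate_patient()` generate a square grid of
spots (spacing 2 units, centered on the origin — slide origins are
arbitrary on real platforms, and centering makes the raw-unit regression
well-posed) with three planted gene classes:

* **coordinate-encoding** — log-link mean surfaces: the log mean is linear
  in a coordinate functional (linear in x, linear in y, radial, or an
  x·y product term), spanning a stated dynamic range across the slide;
* **patch** — flat mean elevated by a fold change inside a random disc
  (the classic spatially *variable* pattern);
* **noise** — constant mean, with per-gene abundances drawn lognormal.

Counts are negative binomial (variance = μ + φμ², φ = 0.5 by default) on
per-spot library sizes drawn lognormal around 5,000 — Visium-like
overdispersion. Slides of one "patient" share the ground truth and differ
only in count noise.

**Calibration of the dynamic range.** At φ = 0.5 the per-gene
log-expression noise floor is √log(1+φ) ≈ 0.64 independent of the mean, so
the positional information of a coordinate gene is governed by
(log fold)/0.64 and by how many genes share each axis. With six coordinate
genes, an 8-fold range leaves every estimator — the network, but equally a
cross-validated linear model or random forest fit to the same matrices —
unable to beat the centroid null by better than ~0.6×. The default range
is therefore 50-fold (log ≈ 3.9, within what dominant spatial markers show
in real tissue), at which the trained network reaches ~0.42–0.48 of the
null MDE on 15×15-spot slides. This default was fixed once, from that
information argument; it is not a per-run tuning knob.

**What the benchmark does not show.** The simulator draws independent NB
counts per spot on smooth mean surfaces. It has no cell-type mixtures, no
spatial autocorrelation beyond the mean surface, no histology, no
segmentation artifacts, and a 60-gene panel rather than a transcriptome.
Passing it demonstrates that the pipeline recovers planted signal through
the full train → attribute → score path under realistic count noise — not
that any particular biological dataset will behave the same way. The
benchmark sizes (three 225-spot slides, 60 genes, single grid point
1 layer × lr 0.01) are the package's standard demonstration conditions;
`evaluate_recovery()` reports median CSMI rank per class and
precision/recall of the SPG call against the planted genes.

## Preprocessing conventions and degenerate inputs

* Filter order: spots → genes → normalize → variance filter. The spot and
  gene filters are defined on counts and refuse normalized input.
* The spot filter's default (200 detected genes) presumes a
  transcriptome-scale panel; for targeted or synthetic panels it should be
  set relative to panel size (the examples use half the panel).
* Variance is always the population estimator (divide by n), both in the
  variance filter and in per-gene scaling; the filter is strict (<), so a
  gene at exactly the threshold is kept. With per-gene standardization on,
  every surviving gene has unit variance and the variance filter reduces
  to dropping constant genes; without it the 0.05 threshold is active.
* Zero-variance genes standardize to all-zeros rather than dividing by
  zero; all-zero spots stay all-zero through CPM.
* A filter that would empty the slide raises an error naming the cause.
* Batch norm uses ε = 1e−5 and running-statistic momentum 0.9; a size-1
  minibatch degenerates gracefully (normalized activation 0, zero
  gradient).
* The distance-loss gradient at an exactly-correct prediction (distance 0)
  uses a 1e−12 floor to avoid 0/0.

## Limitations

* Importance is attribution-based; correlated genes can share or trade
  credit, so per-gene scores should be read as membership in a predictive
  set, not marginal effects.
* The absolute CSMI threshold does not transfer across panels or
  coordinate scales (see above).
* The MLP treats spots independently; it cannot exploit neighbourhood
  smoothness the way Gaussian-process SVG detectors do — by design, since
  the question is what a single spot's expression encodes.
* Networks are trained in plain R matrix code: ample for the tens of
  genes × hundreds of spots regime demonstrated here, but transcriptome-
  wide inputs (thousands of genes) will be slow compared to GPU-backed
  frameworks.
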