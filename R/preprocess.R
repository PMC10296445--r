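#' Remove low-coverage spots
#'
#' Keeps spots in which at least `min_genes` genes are detected (count > 0).
#' Defined on raw counts; refuses normalized slides.
#'
#' @param slide A count-scale [spatial_slide()].
#' @param min_genes Minimum number of detected genes per spot; spots with
#'   fewer are removed. Default 200, the standard Visium quality cutoff.
#' @return The filtered slide (gene set unchanged, spot order preserved).
#' @export
filter_spots <- function(slide, min_genes = 200) {
  validate_slide(slide)
  if (slide$normalized)
    stop("filter_spots is defined on counts; slide is already normalized")
  detected <- rowSums(slide$expression > 0)
  keep <- which(detected >= min_genes)
  if (!length(keep))
    stop("no spots pass the min_genes filter (", min_genes,
         "); slide would be empty")
  subset_slide(slide, spots = keep)
}

#' Remove weakly observed genes
#'
#' Keeps genes with at least `min_reads` total reads and detection (count
#' > 0) in at least `min_spots` spots. Defined on raw counts.
#'
#' @param slide A count-scale [spatial_slide()].
#' @param min_reads Minimum total reads per gene (default 10).
#' @param min_spots Minimum number of spots with nonzero count (default 2).
#' @return The filtered slide (spot set unchanged, gene order preserved).
#' @export
filter_genes <- function(slide, min_reads = 10, min_spots = 2) {
  validate_slide(slide)
  if (slide$normalized)
    stop("filter_genes is defined on counts; slide is already normalized")
  total <- colSums(slide$expression)
  nspots <- colSums(slide$expression > 0)
  keep <- which(total >= min_reads & nspots >= min_spots)
  subset_slide(slide, genes = keep)
}

#' Normalize a count slide for model input
#'
#' `log1p_cpm` rescales each spot to a fixed library size of 10,000, applies
#' log(1 + x), and (optionally) centers and scales each gene to unit
#' variance. This is a standard stabilizing transform for count matrices; it
#' gives the network an input representation on a common scale. Genes with
#' zero variance are mapped to all zeros rather than dividing by zero.
#'
#' @param slide A count-scale [spatial_slide()].
#' @param method `"log1p_cpm"` (default) or `"none"` (flag the slide
#'   normalized without transforming; for pre-normalized inputs).
#' @param scale_per_gene Center/scale each gene after the log transform
#'   (default `TRUE`). Scaling uses the population (divide-by-n) standard
#'   deviation, the same estimator as [variance_filter()].
#' @return The slide with `normalized = TRUE`.
#' @export
normalize_slide <- function(slide, method = c("log1p_cpm", "none"),
                            scale_per_gene = TRUE) {
  validate_slide(slide)
  method <- match.arg(method)
  x <- slide$expression
  if (method == "log1p_cpm") {
    lib <- rowSums(x)
    lib[lib == 0] <- 1                        # all-zero spot stays all-zero
    x <- log1p(x / lib * 1e4)
    if (scale_per_gene) {
      mu <- colMeans(x)
      sdv <- sqrt(colMeans(sweep(x, 2, mu)^2)) # population sd
      x <- sweep(x, 2, mu)
      nz <- sdv > 0
      x[, nz] <- sweep(x[, nz, drop = FALSE], 2, sdv[nz], "/")
      x[, !nz] <- 0
    }
  }
  slide$expression <- x
  slide$normalized <- TRUE
  slide
}

#' Remove near-constant genes before training
#'
#' Drops genes whose across-spot expression variance is strictly below
#' `min_variance`, applied to the normalized model-input representation.
#' The variance estimator is the population variance (divide by n).
#'
#' @param slide A normalized [spatial_slide()].
#' @param min_variance Strict lower variance bound (default 0.05).
#' @return A list with elements `slide` (filtered) and `removed_gene_ids`.
#' @export
variance_filter <- function(slide, min_variance = 0.05) {
  validate_slide(slide)
  if (nrow(slide$expression) < 2)
    stop("variance undefined with fewer than 2 spots")
  v <- colMeans(slide$expression^2) - colMeans(slide$expression)^2
  v <- pmax(v, 0)
  keep <- which(v >= min_variance)
  list(slide = subset_slide(slide, genes = keep),
       removed_gene_ids = slide$gene_ids[v < min_variance])
}

#' Full preprocessing chain: spot filter, gene filter, normalize, variance filter
#'
#' Applies the four steps in order with one call; each threshold is
#' forwarded to the corresponding function.
#'
#' @inheritParams filter_spots
#' @inheritParams filter_genes
#' @inheritParams variance_filter
#' @param normalize_method,scale_per_gene Passed to [normalize_slide()].
#' @return A list with `slide` (ready for training) and `removed_gene_ids`
#'   from the variance filter.
#' @export
preprocess_slide <- function(slide, min_genes = 200, min_reads = 10,
                             min_spots = 2,
                             normalize_method = "log1p_cpm",
                             scale_per_gene = TRUE, min_variance = 0.05) {
  s <- filter_spots(slide, min_genes = min_genes)
  s <- filter_genes(s, min_reads = min_reads, min_spots = min_spots)
  s <- normalize_slide(s, method = normalize_method,
                       scale_per_gene = scale_per_gene)
  variance_filter(s, min_variance = min_variance)
}
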