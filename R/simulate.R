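# Seeded synthetic spatial expression: an n_side x n_side grid of spots
# (2 coordinate units apart, centered on the origin) with three planted gene
# classes — coordinate-encoding genes whose mean is a smooth function of
# position, patch genes elevated inside a disc (the classic spatially
# variable pattern), and spatially uninformative noise genes. Counts are
# negative binomial on a log-link multiplicative mean with lognormal
# per-spot library sizes, mimicking Visium-like overdispersion.

#' Define the ground truth for a synthetic tissue
#'
#' Fixes gene classes, per-gene mean surfaces and count-noise parameters
#' once; slides drawn from the same ground truth share biology and differ
#' only in count noise (and library sizes), emulating serial sections.
#'
#' @param n_side Grid side length (>= 4); the slide has `n_side^2` spots.
#' @param n_coord_genes,n_patch_genes,n_noise_genes Genes per class.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); default 0.5.
#' @param library_size_mean Mean spot library size (default 5000).
#' @param library_size_sdlog Lognormal sdlog of library-size variation
#'   (default 0.2).
#' @param coord_fold Dynamic range of coordinate-encoding surfaces across
#'   the slide (default 50; see the methods vignette for the calibration).
#' @param patch_fold Fold elevation of patch genes inside their disc
#'   (default 50).
#' @param patch_radius_frac Patch disc radius as a fraction of the slide
#'   span (default 0.25; must leave the disc inside the slide).
#' @param seed Integer seed.
#' @return An object of class `synthetic_ground_truth`.
#' @export
make_ground_truth <- function(n_side = 15, n_coord_genes = 6,
                              n_patch_genes = 6, n_noise_genes = 48,
                              nb_dispersion = 0.5, library_size_mean = 5000,
                              library_size_sdlog = 0.2, coord_fold = 50,
                              patch_fold = 50, patch_radius_frac = 0.25,
                              seed = 1) {
  if (n_side < 4) stop("n_side must be at least 4")
  stopifnot(n_coord_genes >= 0, n_patch_genes >= 0, n_noise_genes >= 0,
            nb_dispersion > 0, library_size_mean > 0, coord_fold >= 1,
            patch_fold >= 1)
  span <- 2 * (n_side - 1)                   # spots 2 units apart
  radius <- patch_radius_frac * span
  if (radius > span / 2)
    stop("patch radius (", radius, ") exceeds the slide half-span (",
         span / 2, ")")
  set.seed(seed)
  gene_class <- c(rep("coordinate_encoding", n_coord_genes),
                  rep("patch_svg", n_patch_genes),
                  rep("noise", n_noise_genes))
  gene_ids <- sprintf("g%03d_%s", seq_along(gene_class),
                      c(coordinate_encoding = "coord", patch_svg = "patch",
                        noise = "noise")[gene_class])
  names(gene_class) <- gene_ids

  forms <- c("linear_x", "linear_y", "radial", "product")
  encoding_spec <- NULL
  if (n_coord_genes > 0) {
    encoding_spec <- lapply(seq_len(n_coord_genes), function(i)
      list(form = forms[(i - 1) %% length(forms) + 1], fold = coord_fold))
    names(encoding_spec) <- gene_ids[gene_class == "coordinate_encoding"]
  }
  patch_spec <- NULL
  if (n_patch_genes > 0) {
    half <- span / 2
    lo <- -half + radius; hi <- half - radius
    if (lo > hi) stop("patch radius too large for the slide interior")
    patch_spec <- lapply(seq_len(n_patch_genes), function(i)
      list(center = stats::runif(2, lo, hi), radius = radius,
           fold = patch_fold))
    names(patch_spec) <- gene_ids[gene_class == "patch_svg"]
  }
  base <- stats::rlnorm(length(gene_class), meanlog = 0, sdlog = 1)
  base[gene_class != "noise"] <- 1           # signal genes share a unit base
  names(base) <- gene_ids

  structure(list(n_side = as.integer(n_side), gene_class = gene_class,
                 encoding_spec = encoding_spec, patch_spec = patch_spec,
                 base_abundance = base, nb_dispersion = nb_dispersion,
                 library_size_mean = library_size_mean,
                 library_size_sdlog = library_size_sdlog, seed = seed),
            class = "synthetic_ground_truth")
}

# spot grid centered on the origin, spacing 2 units
truth_grid <- function(truth) {
  p <- 2 * (seq_len(truth$n_side) - 1)
  p <- p - mean(p)
  g <- expand.grid(x = p, y = p, KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

# relative mean surface of one gene over the grid (vector over spots)
truth_surface <- function(truth, gene, coords) {
  cls <- truth$gene_class[[gene]]
  span <- 2 * (truth$n_side - 1)
  ux <- (coords[, "x"] - min(coords[, "x"])) / span
  uy <- (coords[, "y"] - min(coords[, "y"])) / span
  base <- truth$base_abundance[[gene]]
  if (cls == "noise") return(rep(base, nrow(coords)))
  if (cls == "coordinate_encoding") {
    es <- truth$encoding_spec[[gene]]
    u <- switch(es$form,
                linear_x = ux,
                linear_y = uy,
                radial = {
                  d <- sqrt(coords[, "x"]^2 + coords[, "y"]^2)
                  1 - d / max(d)
                },
                product = ux * uy)
    return(base * es$fold^u)           # log-link: log-mean linear in u
  }
  ps <- truth$patch_spec[[gene]]
  d <- sqrt((coords[, "x"] - ps$center[1])^2 +
            (coords[, "y"] - ps$center[2])^2)
  base * ifelse(d <= ps$radius, ps$fold, 1)
}

#' Generate one synthetic slide
#'
#' Draws negative-binomial counts on the ground truth's mean surfaces with
#' lognormal per-spot library sizes. Fully reproducible: the same truth and
#' seed give identical matrices.
#'
#' @param truth A [make_ground_truth()] object, or `NULL` to build one from
#'   the `...` arguments (forwarded to [make_ground_truth()] with the same
#'   seed).
#' @param seed Integer seed for the count draw.
#' @param slide_id,patient_id Provenance labels.
#' @param ... Arguments for [make_ground_truth()] when `truth` is `NULL`.
#' @return A list: `slide` (a count-scale [spatial_slide()]) and `truth`.
#' @export
generate_slide <- function(truth = NULL, seed = 1, slide_id = "sim_slide",
                           patient_id = "sim_patient", ...) {
  if (is.null(truth)) truth <- make_ground_truth(seed = seed, ...)
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  coords <- truth_grid(truth)
  n <- nrow(coords)
  genes <- names(truth$gene_class)
  W <- vapply(genes, function(g) truth_surface(truth, g, coords), numeric(n))
  P <- W / rowSums(W)                        # per-spot expected proportions
  set.seed(seed)
  lib <- stats::rlnorm(n, meanlog = log(truth$library_size_mean) -
                            truth$library_size_sdlog^2 / 2,
                       sdlog = truth$library_size_sdlog)
  mu <- P * lib
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / truth$nb_dispersion),
                   n, length(genes))
  spot_ids <- sprintf("spot_%04d", seq_len(n))
  slide <- spatial_slide(counts, coords, gene_ids = genes,
                         spot_ids = spot_ids, patient_id = patient_id,
                         slide_id = slide_id)
  list(slide = slide, truth = truth)
}

#' Simulate a synthetic patient: several slides from one ground truth
#'
#' @param n_slides Number of serial-section slides (default 3).
#' @param seed Master seed; the ground truth uses it directly and slide
#'   `i` draws counts with `seed + i`.
#' @param patient_id Label applied to all slides.
#' @param ... Arguments for [make_ground_truth()].
#' @return A list: `slides` (list of count-scale [spatial_slide()]s) and
#'   `truth`.
#' @export
simulate_patient <- function(n_slides = 3, seed = 1,
                             patient_id = "sim_patient", ...) {
  truth <- make_ground_truth(seed = seed, ...)
  slides <- lapply(seq_len(n_slides), function(i)
    generate_slide(truth, seed = seed + i,
                   slide_id = paste0("slide", i),
                   patient_id = patient_id)$slide)
  list(slides = slides, truth = truth)
}

#' Score recovery of planted genes by the SPG call
#'
#' Compares a scored gene table against the simulator's ground truth:
#' median CSMI rank per gene class (rank 1 = highest CSMI), precision and
#' recall of the SPG call against the planted signal genes
#' (coordinate-encoding plus patch), and the fraction of called SPGs that
#' are noise genes.
#'
#' @param truth A `synthetic_ground_truth`.
#' @param scores A `gene_score_table` with the SPG call filled in
#'   ([select_spgs()]).
#' @return A list: `median_rank` (per class), `precision` (`NA` with
#'   `no_spgs_called = TRUE` when nothing was called), `recall`,
#'   `noise_fraction`, `n_spgs`.
#' @export
evaluate_recovery <- function(truth, scores) {
  stopifnot(inherits(truth, "synthetic_ground_truth"),
            inherits(scores, "gene_score_table"))
  if (!setequal(names(truth$gene_class), scores$gene_id))
    stop("gene sets of truth and score table differ")
  cls <- truth$gene_class[scores$gene_id]
  rk <- rank(-scores$csmi, ties.method = "average")
  median_rank <- tapply(rk, cls, stats::median)
  planted <- scores$gene_id[cls != "noise"]
  called <- scores$gene_id[scores$is_spg]
  hit <- length(intersect(called, planted))
  no_called <- length(called) == 0
  list(median_rank = median_rank,
       precision = if (no_called) NA_real_ else hit / length(called),
       no_spgs_called = no_called,
       recall = if (length(planted)) hit / length(planted) else NA_real_,
       noise_fraction = if (no_called) NA_real_
                        else 1 - hit / length(called),
       n_spgs = length(called))
}
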