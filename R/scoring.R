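#' Per-gene mean importance over a slide
#'
#' `MeanImp_g` is the importance of gene g averaged over all spots of a
#' slide. Alternative aggregations (median, sum) are exposed for
#' sensitivity checks; the mean is the default used by the SPG statistics.
#'
#' @param imp An `importance_matrix`.
#' @param agg `"mean"` (default), `"median"`, or `"sum"`.
#' @return Named numeric vector, one value per gene.
#' @export
mean_importance <- function(imp, agg = c("mean", "median", "sum")) {
  stopifnot(inherits(imp, "importance_matrix"))
  agg <- match.arg(agg)
  if (nrow(imp$values) < 1) stop("importance matrix has no spots")
  out <- switch(agg,
                mean = colMeans(imp$values),
                median = apply(imp$values, 2, stats::median),
                sum = colSums(imp$values))
  names(out) <- imp$gene_ids
  out
}

#' Mean non-zero importance (MNI) and percentage of non-zero spots (PNI)
#'
#' With `n0` the number of spots whose importance for gene g exceeds
#' `zero_tol`: MNI is the mean importance over those spots (0 when
#' `n0 = 0`), and PNI is `100 * n0 / n`, the percentage of spots in which
#' the gene carries importance. These statistics surface genes whose
#' contribution is strong but regional, which the slide-wide mean
#' deprioritizes.
#'
#' @param imp An `importance_matrix`.
#' @param zero_tol Importance values must strictly exceed this to count as
#'   non-zero (default 0).
#' @param agg Aggregator for MNI: `"mean"` (default) or `"median"`.
#' @return A list with named vectors `mni` and `pni` (PNI in [0, 100]).
#' @export
mni_pni <- function(imp, zero_tol = 0, agg = c("mean", "median")) {
  stopifnot(inherits(imp, "importance_matrix"))
  agg <- match.arg(agg)
  v <- imp$values
  if (nrow(v) < 1) stop("importance matrix has no spots")
  nz <- v > zero_tol
  n0 <- colSums(nz)
  mni <- vapply(seq_len(ncol(v)), function(j) {
    if (n0[j] == 0) return(0)
    vals <- v[nz[, j], j]
    if (agg == "mean") mean(vals) else stats::median(vals)
  }, numeric(1))
  pni <- 100 * n0 / nrow(v)
  names(mni) <- names(pni) <- imp$gene_ids
  list(mni = mni, pni = pni)
}

#' Cross-slide gene scores (CSMI, CSMNI, CSPNI)
#'
#' Unweighted per-gene means across slides of MeanImp, MNI and PNI. Slides
#' whose gene sets differ are intersected with a warning.
#'
#' @param per_slide A list with one element per slide, each a list with
#'   named vectors `mean_imp`, `mni`, `pni` (as produced by
#'   [mean_importance()] and [mni_pni()]).
#' @param agg Cross-slide aggregator: `"mean"` (default) or `"median"`.
#' @return A data frame with columns `gene_id`, `csmi`, `csmni`, `cspni`.
#' @export
cross_slide_scores <- function(per_slide, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  stopifnot(length(per_slide) >= 1)
  gene_sets <- lapply(per_slide, function(s) names(s$mean_imp))
  genes <- Reduce(intersect, gene_sets)
  if (!length(genes)) stop("no genes common to all slides")
  if (any(vapply(gene_sets, length, integer(1)) != length(genes)))
    warning("slides have differing gene sets; using the ",
            length(genes), "-gene intersection")
  rowagg <- if (agg == "mean") rowMeans else function(m) apply(m, 1, stats::median)
  pull <- function(field) {
    m <- matrix(vapply(per_slide, function(s) s[[field]][genes],
                       numeric(length(genes))),
                nrow = length(genes))
    rowagg(m)
  }
  data.frame(gene_id = genes,
             csmi = pull("mean_imp"),
             csmni = pull("mni"),
             cspni = pull("pni"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble a gene score table from per-slide importance matrices
#'
#' Computes MeanImp, MNI and PNI per slide, their cross-slide means (CSMI,
#' CSMNI, CSPNI), and returns one table with per-slide and cross-slide
#' columns. The SPG call columns are initialized empty; fill them with
#' [select_spgs()].
#'
#' @param imps List of `importance_matrix` objects, one per slide (same
#'   patient).
#' @param slide_names Optional names for the per-slide columns (default
#'   `slide1`, `slide2`, ...).
#' @param zero_tol Passed to [mni_pni()].
#' @param agg Aggregator for Eqs. over spots and slides: `"mean"` (default)
#'   or `"median"`.
#' @return A data frame of class `gene_score_table`.
#' @export
gene_score_table <- function(imps, slide_names = NULL, zero_tol = 0,
                             agg = c("mean", "median")) {
  agg <- match.arg(agg)
  stopifnot(length(imps) >= 1)
  if (is.null(slide_names)) slide_names <- paste0("slide", seq_along(imps))
  stopifnot(length(slide_names) == length(imps))
  spot_agg <- if (agg == "median") "median" else "mean"
  per_slide <- lapply(imps, function(im) {
    mp <- mni_pni(im, zero_tol = zero_tol,
                  agg = if (agg == "median") "median" else "mean")
    list(mean_imp = mean_importance(im, agg = spot_agg),
         mni = mp$mni, pni = mp$pni)
  })
  tab <- cross_slide_scores(per_slide, agg = agg)
  tab$is_spg <- NA
  tab$spg_reason <- "none"
  for (i in seq_along(per_slide)) {
    g <- tab$gene_id
    tab[[paste0("meanimp_", slide_names[i])]] <- per_slide[[i]]$mean_imp[g]
    tab[[paste0("mni_", slide_names[i])]] <- per_slide[[i]]$mni[g]
    tab[[paste0("pni_", slide_names[i])]] <- per_slide[[i]]$pni[g]
  }
  class(tab) <- c("gene_score_table", "data.frame")
  tab
}

#' Call spatially predictive genes (SPGs)
#'
#' Two-stage rule. Seed stage: genes with `CSMI > csmi_threshold` are SPGs
#' (reason `csmi_seed`). Rescue stage: with `m` the minimum CSMNI among the
#' seed genes, non-seed genes with `CSMNI >= m` and `CSPNI >
#' cspni_threshold` are added (reason `mni_rescue`) — these are genes whose
#' importance is strong in a reasonably sized subset of spots even though
#' their slide-wide mean is modest. If no gene passes the seed stage, no
#' rescue occurs and a warning is emitted.
#'
#' @param table A `gene_score_table` with `csmi`, `csmni`, `cspni`
#'   populated.
#' @param csmi_threshold Seed cutoff on CSMI (default 0.15; strictly
#'   greater-than). A user parameter by design — the appropriate cutoff
#'   depends on the data's importance scale.
#' @param cspni_threshold Rescue cutoff on CSPNI (default 20; strictly
#'   greater-than).
#' @return The table with `is_spg` and `spg_reason` filled.
#' @export
select_spgs <- function(table, csmi_threshold = 0.15, cspni_threshold = 20) {
  stopifnot(inherits(table, "gene_score_table"))
  seed <- table$csmi > csmi_threshold
  reason <- rep("none", nrow(table))
  reason[seed] <- "csmi_seed"
  if (!any(seed)) {
    warning("no gene exceeds the CSMI threshold (", csmi_threshold,
            "); no SPGs called")
  } else {
    m <- min(table$csmni[seed])
    rescue <- !seed & table$csmni >= m & table$cspni > cspni_threshold
    reason[rescue] <- "mni_rescue"
  }
  table$spg_reason <- reason
  table$is_spg <- reason != "none"
  table
}

#' Importance-derived cluster markers
#'
#' Ranks genes within each spot cluster by their mean importance over that
#' cluster's spots; the top-ranked genes are the cluster's
#' importance-derived markers.
#'
#' @param imp An `importance_matrix`.
#' @param cluster_labels Cluster label per spot: either a vector named by
#'   spot id covering every spot, or an unnamed vector in spot order.
#' @param top_n Number of markers to return per cluster.
#' @return A named list (one element per cluster) of data frames with
#'   columns `gene_id` and `mean_importance`, ranked decreasing.
#' @export
importance_cluster_markers <- function(imp, cluster_labels, top_n = 10) {
  stopifnot(inherits(imp, "importance_matrix"))
  n <- nrow(imp$values)
  if (!is.null(names(cluster_labels))) {
    missing <- setdiff(imp$spot_ids, names(cluster_labels))
    if (length(missing))
      stop("unlabeled spot(s): ", paste(missing, collapse = ", "))
    cluster_labels <- cluster_labels[imp$spot_ids]
  } else if (length(cluster_labels) != n) {
    stop("cluster_labels must cover every spot (need ", n, " labels)")
  }
  if (anyNA(cluster_labels)) stop("NA cluster label")
  out <- lapply(split(seq_len(n), cluster_labels), function(rows) {
    sc <- colMeans(imp$values[rows, , drop = FALSE])
    ord <- order(sc, decreasing = TRUE)[seq_len(min(top_n, length(sc)))]
    data.frame(gene_id = imp$gene_ids[ord], mean_importance = sc[ord],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out
}

#' Contingency of SPG and SVG calls over a gene universe
#'
#' Cross-tabulates spatially predictive genes against an externally
#' supplied list of spatially variable genes.
#'
#' @param spgs,svgs Character vectors of gene ids; must be subsets of
#'   `universe`.
#' @param universe Character vector of all genes considered.
#' @return A 2 x 2 integer matrix (rows: SPG no/yes; columns: SVG no/yes)
#'   whose entries sum to `length(universe)`.
#' @export
spg_svg_contingency <- function(spgs, svgs, universe) {
  if (anyDuplicated(universe)) stop("duplicate genes in universe")
  if (length(setdiff(spgs, universe)))
    stop("spgs contains genes outside the universe")
  if (length(setdiff(svgs, universe)))
    stop("svgs contains genes outside the universe")
  is_spg <- factor(universe %in% spgs, levels = c(FALSE, TRUE))
  is_svg <- factor(universe %in% svgs, levels = c(FALSE, TRUE))
  tab <- table(SPG = is_spg, SVG = is_svg)
  dimnames(tab) <- list(SPG = c("no", "yes"), SVG = c("no", "yes"))
  m <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
  m
}
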