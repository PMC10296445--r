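#' Construct a spatial slide
#'
#' A `spatial_slide` bundles one tissue section's spot-by-gene expression
#' matrix with the (x, y) coordinates of its spots and provenance labels.
#' Spots are the unit of observation: row `i` of `expression` and row `i` of
#' `coords` always describe the same spot, joined by spot id.
#'
#' @param expression Numeric matrix, spots in rows, genes in columns. Row
#'   names are taken as spot ids and column names as gene ids when
#'   `spot_ids`/`gene_ids` are not given.
#' @param coords Numeric matrix or data frame with one row per spot and two
#'   columns (x, y), in the slide's native coordinate units.
#' @param gene_ids,spot_ids Character vectors of unique identifiers. Default:
#'   dimnames of `expression`.
#' @param patient_id,slide_id Provenance labels.
#' @param normalized Logical; `FALSE` for raw counts. Count-based filters
#'   refuse normalized input.
#'
#' @return An object of class `spatial_slide`.
#' @export
spatial_slide <- function(expression, coords, gene_ids = colnames(expression),
                          spot_ids = rownames(expression),
                          patient_id = "patient", slide_id = "slide",
                          normalized = FALSE) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  if (is.null(spot_ids)) stop("spot ids are required (rownames or spot_ids=)")
  if (is.null(gene_ids)) stop("gene ids are required (colnames or gene_ids=)")
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have exactly two columns (x, y)")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  rownames(coords) <- spot_ids
  dimnames(expression) <- list(spot_ids, gene_ids)
  obj <- structure(
    list(expression = expression, coords = coords,
         gene_ids = gene_ids, spot_ids = spot_ids,
         patient_id = as.character(patient_id),
         slide_id = as.character(slide_id),
         normalized = isTRUE(normalized)),
    class = "spatial_slide")
  validate_slide(obj)
  obj
}

validate_slide <- function(x) {
  stopifnot(inherits(x, "spatial_slide"))
  if (nrow(x$expression) != length(x$spot_ids))
    stop("expression rows (", nrow(x$expression), ") != number of spot ids (",
         length(x$spot_ids), ")")
  if (ncol(x$expression) != length(x$gene_ids))
    stop("expression columns != number of gene ids")
  if (nrow(x$coords) != length(x$spot_ids))
    stop("coords rows != number of spot ids")
  if (anyDuplicated(x$spot_ids))
    stop("duplicate spot ids: ",
         paste(unique(x$spot_ids[duplicated(x$spot_ids)]), collapse = ", "))
  if (anyDuplicated(x$gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(x$gene_ids[duplicated(x$gene_ids)]), collapse = ", "))
  if (!all(is.finite(x$coords)))
    stop("non-finite spot coordinates")
  if (!x$normalized && any(x$expression < 0))
    stop("negative entries in a count (non-normalized) expression matrix")
  invisible(x)
}

#' @export
print.spatial_slide <- function(x, ...) {
  cat(sprintf("spatial_slide: %d spots x %d genes (%s)\n",
              length(x$spot_ids), length(x$gene_ids),
              if (x$normalized) "normalized" else "counts"))
  cat(sprintf("  patient: %s  slide: %s\n", x$patient_id, x$slide_id))
  rx <- range(x$coords[, "x"]); ry <- range(x$coords[, "y"])
  cat(sprintf("  x range: [%g, %g]  y range: [%g, %g]\n",
              rx[1], rx[2], ry[1], ry[2]))
  invisible(x)
}

#' @export
dim.spatial_slide <- function(x) dim(x$expression)

#' Subset a slide by spots and/or genes
#'
#' Keeps expression, coordinates and ids in register (row `i` of both
#' matrices always describes the same spot).
#'
#' @param slide A [spatial_slide()].
#' @param spots,genes Index vectors (integer, logical or id-based via
#'   `match` beforehand); `NULL` keeps everything.
#' @return The subset [spatial_slide()].
#' @export
subset_slide <- function(slide, spots = NULL, genes = NULL) {
  if (is.null(spots)) spots <- seq_along(slide$spot_ids)
  if (is.null(genes)) genes <- seq_along(slide$gene_ids)
  spatial_slide(slide$expression[spots, genes, drop = FALSE],
                slide$coords[spots, , drop = FALSE],
                gene_ids = slide$gene_ids[genes],
                spot_ids = slide$spot_ids[spots],
                patient_id = slide$patient_id, slide_id = slide$slide_id,
                normalized = slide$normalized)
}
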