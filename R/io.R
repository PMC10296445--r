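#' Read a spatial slide from disk
#'
#' Reads an expression matrix plus a spot-coordinate table into a
#' [spatial_slide()]. Two matrix layouts are supported: MatrixMarket (`.mtx`)
#' with separate one-id-per-line gene and spot name files (the Visium-style
#' triplet), or a dense TSV whose header row holds gene ids and whose first
#' column holds spot ids.
#'
#' Spots are ordered as in the coordinate file; genes as in the gene file /
#' header. Every spot present in the matrix must appear in the coordinate
#' file (missing spots are an error naming the offenders); coordinate rows
#' for spots absent from the matrix are dropped.
#'
#' @param matrix_path Path to `.mtx` or dense TSV matrix.
#' @param genes_path,spots_path Paths to gene/spot id files (MTX only; one id
#'   per line, no header). Ignored for dense TSV.
#' @param coords_path Path to a TSV with header columns `spot_id`, `x`, `y`.
#' @param patient_id,slide_id Provenance labels stored on the slide.
#' @param orientation For MTX input: `"genes_x_spots"` (the Visium
#'   convention, default) or `"spots_x_genes"`.
#' @param normalized Logical flag recorded on the slide; default `FALSE`.
#'
#' @return A [spatial_slide()].
#' @export
read_slide <- function(matrix_path, genes_path = NULL, spots_path = NULL,
                       coords_path, patient_id = "patient", slide_id = "slide",
                       orientation = c("genes_x_spots", "spots_x_genes"),
                       normalized = FALSE) {
  orientation <- match.arg(orientation)
  is_mtx <- grepl("\\.mtx(\\.gz)?$", matrix_path, ignore.case = TRUE)
  if (is_mtx) {
    if (is.null(genes_path) || is.null(spots_path))
      stop("MTX input needs genes_path and spots_path id files")
    m <- as.matrix(Matrix::readMM(matrix_path))
    gene_ids <- readLines(genes_path)
    spot_ids <- readLines(spots_path)
    if (orientation == "genes_x_spots") m <- t(m)
    if (nrow(m) != length(spot_ids) || ncol(m) != length(gene_ids))
      stop(sprintf(
        "matrix is %d x %d after orienting spots x genes, but %d spot ids and %d gene ids were supplied",
        nrow(m), ncol(m), length(spot_ids), length(gene_ids)))
    dimnames(m) <- list(spot_ids, gene_ids)
  } else {
    df <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    spot_ids <- rownames(m)
    gene_ids <- colnames(m)
  }
  if (anyDuplicated(spot_ids)) stop("duplicate spot ids in matrix input")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in matrix input")

  co <- utils::read.table(coords_path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  need <- c("spot_id", "x", "y")
  if (!all(need %in% colnames(co)))
    stop("coordinate file must have header columns spot_id, x, y")
  if (anyDuplicated(co$spot_id)) stop("duplicate spot ids in coordinate file")
  xy <- suppressWarnings(cbind(x = as.numeric(co$x), y = as.numeric(co$y)))
  if (any(is.na(xy)))
    stop("non-numeric coordinates for spot(s): ",
         paste(co$spot_id[!stats::complete.cases(xy)], collapse = ", "))

  missing <- setdiff(spot_ids, co$spot_id)
  if (length(missing))
    stop("spot(s) missing from coordinate file: ",
         paste(missing, collapse = ", "))
  keep <- co$spot_id %in% spot_ids           # coord-file order drives spot order
  ord_ids <- co$spot_id[keep]
  spatial_slide(m[ord_ids, , drop = FALSE], xy[keep, , drop = FALSE],
                gene_ids = gene_ids, spot_ids = ord_ids,
                patient_id = patient_id, slide_id = slide_id,
                normalized = normalized)
}

#' Write a spatial slide as dense TSV + coordinate sidecar
#'
#' Inverse of [read_slide()] for the dense-TSV layout; round-trips
#' expression, coordinates and ids.
#'
#' @param slide A [spatial_slide()].
#' @param matrix_path,coords_path Output paths.
#' @export
write_slide <- function(slide, matrix_path, coords_path) {
  validate_slide(slide)
  df <- data.frame(spot_id = slide$spot_ids,
                   as.data.frame(slide$expression, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  co <- data.frame(spot_id = slide$spot_ids,
                   x = slide$coords[, "x"], y = slide$coords[, "y"])
  utils::write.table(co, coords_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(slide)
}

#' Write a slide as MatrixMarket triplet files
#'
#' @param slide A [spatial_slide()].
#' @param matrix_path Output `.mtx` path (written genes x spots, the Visium
#'   convention).
#' @param genes_path,spots_path Output id files, one id per line.
#' @export
write_slide_mtx <- function(slide, matrix_path, genes_path, spots_path) {
  validate_slide(slide)
  Matrix::writeMM(Matrix::Matrix(t(slide$expression), sparse = TRUE),
                  matrix_path)
  writeLines(slide$gene_ids, genes_path)
  writeLines(slide$spot_ids, spots_path)
  invisible(slide)
}

#' Write a gene score table as TSV
#'
#' One row per gene: `gene_id`, cross-slide scores (`csmi`, `csmni`,
#' `cspni`), the SPG call (`is_spg`, `spg_reason`), then per-slide
#' MeanImp/MNI/PNI columns. Round-trips through [read_gene_scores()] up to
#' float formatting.
#'
#' @param table A `gene_score_table` (see [gene_score_table()]).
#' @param path Output path.
#' @export
write_gene_scores <- function(table, path) {
  stopifnot(inherits(table, "gene_score_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}

#' Read back a gene score table written by [write_gene_scores()]
#'
#' @param path TSV path.
#' @return A data frame of class `gene_score_table`.
#' @export
read_gene_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df)) df$is_spg <- as.logical(df$is_spg)
  class(df) <- c("gene_score_table", "data.frame")
  df
}
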