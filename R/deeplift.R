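# DeepLIFT (Rescale rule) for the coord_mlp network. Attribution runs the
# network in inference mode, so batch-norm layers are plain affine maps and
# contributions propagate exactly: dense and batch-norm are linear; ReLU
# uses the rescale slope (a - a0) / (z - z0) relative to the reference
# activation, falling back to the local gradient when |z - z0| is tiny.
# Summation-to-delta (sum of input contributions = t - t0) then holds by
# construction up to float error.

#' DeepLIFT contributions of each gene to each spot's predicted position
#'
#' Computes signed input-layer contribution scores relative to a reference
#' input (all zeros by default, i.e. the zero point of the normalized
#' expression scale). The attributed scalar target is chosen by
#' `target_mode`: the sum of the x and y outputs (default), or a single
#' axis.
#'
#' @param model A trained `coord_mlp`.
#' @param expression Spots x genes matrix, preprocessed identically to
#'   training.
#' @param target_mode `"sum_xy"` (default), `"per_axis_x"` or
#'   `"per_axis_y"`.
#' @param reference Reference input vector of length `n_genes` (default all
#'   zeros).
#' @return An object of class `contribution_matrix`: `values` (spots x
#'   genes signed contributions), `t_delta` (per-spot target difference
#'   t - t0, which the rows sum to), `target_mode`, `reference`, ids.
#' @export
deeplift_contributions <- function(model, expression,
                                   target_mode = c("sum_xy", "per_axis_x",
                                                   "per_axis_y"),
                                   reference = NULL) {
  target_mode <- match.arg(target_mode)
  X <- if (inherits(expression, "spatial_slide")) expression$expression
       else as.matrix(expression)
  p <- model$spec$n_input
  if (ncol(X) != p)
    stop("expression has ", ncol(X), " genes; model expects ", p)
  if (is.null(reference)) reference <- numeric(p)
  if (length(reference) != p)
    stop("reference length ", length(reference), " != number of genes ", p)
  tw <- switch(target_mode, sum_xy = c(1, 1), per_axis_x = c(1, 0),
               per_axis_y = c(0, 1))
  n <- nrow(X)

  # inference-mode forward for input and reference, keeping pre-ReLU values
  fw_affine <- function(A) {
    pre <- post <- vector("list", length(model$layers))
    for (i in seq_along(model$layers)) {
      ly <- model$layers[[i]]
      Z <- A %*% ly$W + rep(ly$b, each = nrow(A))
      scl <- ly$gamma / sqrt(ly$rv + BN_EPS)
      Bn <- sweep(sweep(Z, 2, ly$rm), 2, scl, "*")
      Bn <- sweep(Bn, 2, ly$beta, "+")
      pre[[i]] <- Bn
      A <- relu(Bn)
      post[[i]] <- A
    }
    list(pre = pre, post = post,
         out = A %*% model$out$W + rep(model$out$b, each = nrow(A)))
  }
  fx <- fw_affine(X)
  f0 <- fw_affine(matrix(reference, 1, p))
  t_delta <- drop((fx$out - rep(f0$out, each = n)) %*% tw)

  # backward multiplier pass (per spot)
  M <- matrix(rep(drop(model$out$W %*% tw), each = n), n)
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    dz <- sweep(fx$pre[[i]], 2, f0$pre[[i]])
    da <- sweep(fx$post[[i]], 2, f0$post[[i]])
    slope <- ifelse(abs(dz) > 1e-7, da / dz, (fx$pre[[i]] > 0) * 1)
    M <- M * slope                                   # through ReLU (rescale)
    scl <- ly$gamma / sqrt(ly$rv + BN_EPS)
    M <- sweep(M, 2, scl, "*")                       # through BN affine
    M <- M %*% t(ly$W)                               # through dense
  }
  C <- sweep(X, 2, reference) * M
  dimnames(C) <- dimnames(X)
  structure(list(values = C, t_delta = t_delta, target_mode = target_mode,
                 reference = reference,
                 spot_ids = rownames(X), gene_ids = colnames(X)),
            class = "contribution_matrix")
}

#' Importance scores from signed contributions
#'
#' The importance of gene g for spot s is the magnitude of its contribution,
#' `|C_gs|`.
#'
#' @param contribs A `contribution_matrix`.
#' @return An object of class `importance_matrix` with non-negative
#'   `values` of the same shape and ids.
#' @export
importance_from_contributions <- function(contribs) {
  stopifnot(inherits(contribs, "contribution_matrix"))
  structure(list(values = abs(contribs$values),
                 spot_ids = contribs$spot_ids, gene_ids = contribs$gene_ids,
                 target_mode = contribs$target_mode, fold = NULL),
            class = "importance_matrix")
}

#' Test-fold importance matrix for a cross-validated slide
#'
#' For every spot, contributions are computed with the model for which that
#' spot was in the test fold, so no spot is attributed by a model that
#' trained on it. Rows are assembled into one full-slide importance matrix;
#' the fold that produced each row is kept as an audit trail.
#'
#' @param cv A `coord_cv` from [cv_coord_mlp()].
#' @param slide The normalized [spatial_slide()] the CV was run on.
#' @param target_mode,reference Passed to [deeplift_contributions()].
#' @return An `importance_matrix` whose `fold` element records, per spot,
#'   the fold (and hence model) that attributed it.
#' @export
testfold_importance <- function(cv, slide, target_mode = "sum_xy",
                                reference = NULL) {
  stopifnot(inherits(cv, "coord_cv"))
  validate_slide(slide)
  if (!identical(names(cv$fold_assignment), slide$spot_ids))
    stop("cv was not produced on this slide (spot ids differ)")
  if (!identical(cv$gene_ids, slide$gene_ids))
    stop("cv was not produced on this slide (gene ids differ)")
  n <- length(slide$spot_ids)
  vals <- matrix(NA_real_, n, length(slide$gene_ids),
                 dimnames = list(slide$spot_ids, slide$gene_ids))
  for (i in seq_len(cv$k)) {
    rows <- which(cv$fold_assignment == i)
    if (!length(rows)) next
    if (is.null(cv$models[[i]])) stop("missing model for fold ", i)
    co <- deeplift_contributions(cv$models[[i]],
                                 slide$expression[rows, , drop = FALSE],
                                 target_mode = target_mode,
                                 reference = reference)
    vals[rows, ] <- abs(co$values)
  }
  structure(list(values = vals, spot_ids = slide$spot_ids,
                 gene_ids = slide$gene_ids, target_mode = target_mode,
                 fold = unname(cv$fold_assignment)),
            class = "importance_matrix")
}

#' @export
print.contribution_matrix <- function(x, ...) {
  cat(sprintf("contribution_matrix: %d spots x %d genes (target %s)\n",
              nrow(x$values), ncol(x$values), x$target_mode))
  invisible(x)
}

#' @export
print.importance_matrix <- function(x, ...) {
  cat(sprintf("importance_matrix: %d spots x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
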