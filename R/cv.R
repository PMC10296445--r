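#' K-fold cross-validation of the coordinate-regression network
#'
#' Spots are randomized once (per seed) into `k` folds. Each fold serves
#' once as the test fold; the next fold, cyclically, is the validation fold
#' for early stopping; the remaining `k - 2` folds train the model. A grid
#' of hidden-layer counts and learning rates is evaluated; for each grid
#' point the CV error is the mean distance error over the aggregated
#' test-fold predictions, and the grid point with the lowest CV error wins
#' (ties broken toward fewer layers, then smaller learning rate). The
#' winner's within-fold models and test predictions are returned.
#'
#' @param slide A normalized [spatial_slide()] (model-input representation).
#' @param layers Hidden-layer counts to try (default `c(1, 3, 5)`).
#' @param learning_rates Adam learning rates to try (default
#'   `c(0.1, 0.01, 0.001)`).
#' @param k Number of folds (default 10; must be >= 3 so train, validation
#'   and test roles are distinct).
#' @param seed Integer seed for the fold split and all model training.
#' @param batch_size,max_epochs,patience Training controls forwarded to
#'   [arch_spec()].
#' @param first_layer_half Passed to [plan_architecture()].
#' @return An object of class `coord_cv`: fold assignment, per-test-fold
#'   validation fold, aggregated `test_predictions`, `cv_mde`, the winning
#'   fold models, the grid table, and the winning hyperparameters.
#' @export
cv_coord_mlp <- function(slide, layers = c(1, 3, 5),
                         learning_rates = c(0.1, 0.01, 0.001),
                         k = 10, seed = 1, batch_size = 32, max_epochs = 100,
                         patience = 10, first_layer_half = FALSE) {
  validate_slide(slide)
  n <- length(slide$spot_ids)
  k <- as.integer(k)
  if (k < 3) stop("k must be >= 3: train, validation and test folds must be distinct")
  if (n < k) stop("need at least k spots (", k, "), got ", n)
  n_genes <- length(slide$gene_ids)

  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))     # near-equal fold sizes
  names(fold) <- slide$spot_ids
  val_of_test <- (seq_len(k) %% k) + 1L      # test fold i -> validation fold i+1 (cyclic)

  grid <- expand.grid(n_layers = sort(layers),
                      lr = sort(learning_rates), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$n_layers, grid$lr), , drop = FALSE]

  best <- NULL
  grid_mde <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    widths <- plan_architecture(n_genes, grid$n_layers[g],
                                first_layer_half = first_layer_half)
    preds <- matrix(NA_real_, n, 2)
    models <- vector("list", k)
    for (i in seq_len(k)) {
      test_idx <- which(fold == i)
      val_idx <- which(fold == val_of_test[i])
      train_idx <- which(fold != i & fold != val_of_test[i])
      spec <- arch_spec(n_genes, widths, learning_rate = grid$lr[g],
                        batch_size = batch_size, max_epochs = max_epochs,
                        early_stopping_patience = patience,
                        seed = (seed + 1009L * g + i) %% .Machine$integer.max)
      fit <- coord_mlp(subset_slide(slide, spots = train_idx), spec,
                       val = subset_slide(slide, spots = val_idx))
      preds[test_idx, ] <- predict(fit, slide$expression[test_idx, , drop = FALSE])
      models[[i]] <- fit
    }
    grid_mde[g] <- mean_distance_error(preds, slide$coords)
    if (is.null(best) || grid_mde[g] < best$cv_mde) {
      best <- list(g = g, cv_mde = grid_mde[g], preds = preds,
                   models = models)
    }
  }
  grid$cv_mde <- grid_mde

  dimnames(best$preds) <- list(slide$spot_ids, c("x", "y"))
  structure(list(
    fold_assignment = fold,
    val_fold_of_test = val_of_test,
    test_predictions = best$preds,
    cv_mde = best$cv_mde,
    models = best$models,
    best_hyperparams = list(n_hidden_layers = grid$n_layers[best$g],
                            learning_rate = grid$lr[best$g]),
    grid = grid,
    k = k, seed = seed,
    slide_id = slide$slide_id, patient_id = slide$patient_id,
    gene_ids = slide$gene_ids,
    coords = slide$coords),
    class = "coord_cv")
}

#' @export
print.coord_cv <- function(x, ...) {
  cat(sprintf("coord_cv: %d spots, %d genes, k = %d (slide %s)\n",
              length(x$fold_assignment), length(x$gene_ids), x$k, x$slide_id))
  cat(sprintf("  best: %d hidden layer(s), lr %g; CV-MDE %.4g\n",
              x$best_hyperparams$n_hidden_layers,
              x$best_hyperparams$learning_rate, x$cv_mde))
  invisible(x)
}

#' @export
summary.coord_cv <- function(object, ...) {
  cat("Cross-validated coordinate regression\n")
  print(object)
  cat("\nGrid (CV mean distance error):\n")
  print(object$grid, row.names = FALSE)
  null_mde <- centroid_null_mde(object$coords)
  cat(sprintf("\nCentroid-null MDE: %.4g (model/null ratio %.3f)\n",
              null_mde, object$cv_mde / null_mde))
  invisible(object)
}

#' @export
fitted.coord_cv <- function(object, ...) object$test_predictions

#' @export
residuals.coord_cv <- function(object, ...)
  object$test_predictions - object$coords

#' Plot test-fold predicted vs. actual spot positions
#'
#' Draws each spot at its actual position with a segment to its test-fold
#' predicted position; segment length is the per-spot distance error.
#'
#' @param x A `coord_cv`.
#' @param ... Passed to `plot()`.
#' @export
plot.coord_cv <- function(x, ...) {
  a <- x$coords; p <- x$test_predictions
  plot(a, pch = 16, cex = 0.6, xlab = "x", ylab = "y",
       main = sprintf("CV-MDE %.3g (slide %s)", x$cv_mde, x$slide_id), ...)
  graphics::segments(a[, 1], a[, 2], p[, 1], p[, 2], col = "grey50")
  graphics::points(p, pch = 1, cex = 0.5, col = "red3")
  invisible(x)
}

#' Mean distance error of the centroid-null predictor
#'
#' The baseline that predicts every spot at the mean coordinate; its MDE is
#' the reference scale against which model skill is judged.
#'
#' @param coords An n x 2 coordinate matrix or a [spatial_slide()].
#' @return A single number.
#' @export
centroid_null_mde <- function(coords) {
  if (inherits(coords, "spatial_slide")) coords <- coords$coords
  coords <- as.matrix(coords)
  ctr <- colMeans(coords)
  mean_distance_error(matrix(ctr, nrow(coords), 2, byrow = TRUE), coords)
}
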