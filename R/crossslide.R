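#' Translate slides so their centers coincide with a training slide
#'
#' A slide's center is the mean of its spot x and y coordinates. Each other
#' slide is shifted by (train center - its center), so after translation all
#' centers coincide with the training slide's; within-slide geometry is
#' untouched (a pure translation).
#'
#' @param train The reference [spatial_slide()] (returned unchanged).
#' @param others A list of [spatial_slide()]s to translate.
#' @return A list: `train` (unchanged) and `others` (translated).
#' @export
align_slide_centers <- function(train, others) {
  validate_slide(train)
  if (!length(others)) stop("need at least one other slide to align")
  if (nrow(train$coords) == 0) stop("training slide has no spots")
  ctr <- colMeans(train$coords)
  others <- lapply(others, function(s) {
    validate_slide(s)
    if (nrow(s$coords) == 0) stop("cannot align an empty slide")
    shift <- ctr - colMeans(s$coords)
    s$coords <- sweep(s$coords, 2, shift, "+")
    s
  })
  list(train = train, others = others)
}

#' Cross-slide validation over the three slide rotations
#'
#' Checks that a model trained on one slide generalizes to the other slides
#' of the same tissue. For each of the three rotations (train = slide 1,
#' validation = slide 2, test = slide 3; then 2/3/1; then 3/1/2): the
#' validation and test slides are translated so their centers match the
#' training slide, a model is trained on the full training slide with the
#' validation slide driving early stopping, and the test slide's MDE is
#' reported. Gene sets are intersected (with a warning if they differ).
#'
#' @param slides A list of exactly 3 normalized [spatial_slide()]s.
#' @param spec An [arch_spec()] carrying the hyperparameters (typically the
#'   winners of per-slide cross-validation); `n_input` is recomputed from
#'   the gene intersection.
#' @return A data frame with one row per rotation: the slide ids used in
#'   each role and the test-slide MDE, plus the centroid-null MDE of each
#'   test slide for scale.
#' @export
cross_slide_validate <- function(slides, spec) {
  if (length(slides) != 3) stop("exactly 3 slides are required")
  lapply(slides, validate_slide)
  genes <- Reduce(intersect, lapply(slides, function(s) s$gene_ids))
  if (!length(genes)) stop("no genes common to all slides")
  if (any(vapply(slides, function(s) length(s$gene_ids),
                 integer(1)) != length(genes)))
    warning("slides have differing gene sets; using the ",
            length(genes), "-gene intersection")
  slides <- lapply(slides, function(s)
    subset_slide(s, genes = match(genes, s$gene_ids)))

  rotations <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  res <- lapply(rotations, function(r) {
    tr <- slides[[r[1]]]
    al <- align_slide_centers(tr, slides[r[2:3]])
    va <- al$others[[1]]; te <- al$others[[2]]
    sp <- arch_spec(length(genes), spec$hidden_widths,
                    learning_rate = spec$learning_rate,
                    batch_size = spec$batch_size,
                    max_epochs = spec$max_epochs,
                    early_stopping_patience = spec$early_stopping_patience,
                    seed = spec$seed + r[1])
    fit <- coord_mlp(tr, sp, val = va)
    data.frame(train_slide = tr$slide_id, val_slide = va$slide_id,
               test_slide = te$slide_id,
               test_mde = mean_distance_error(predict(fit, te), te$coords),
               null_mde = centroid_null_mde(te),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
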