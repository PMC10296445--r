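#' Run the full SPG pipeline on one patient's slides
#'
#' Chains the whole workflow per slide — quality filters, normalization,
#' variance filter, k-fold cross-validated training, test-fold DeepLIFT
#' importance — then aggregates importance across slides into CSMI/CSMNI/
#' CSPNI and calls SPGs. All randomness is governed by `seed` (slide `i`
#' trains with `seed + i`), so a rerun with the same inputs and seed
#' reproduces the SPG list exactly.
#'
#' @param slides A list of count-scale [spatial_slide()]s from one patient.
#' @param min_genes,min_reads,min_spots,normalize_method,scale_per_gene,min_variance
#'   Preprocessing controls; see [preprocess_slide()].
#' @param layers,learning_rates,k,batch_size,max_epochs,patience Training
#'   grid and controls; see [cv_coord_mlp()].
#' @param seed Master seed.
#' @param target_mode Attribution target; see [deeplift_contributions()].
#' @param csmi_threshold,cspni_threshold SPG thresholds; see
#'   [select_spgs()].
#' @param svg_list Optional character vector of externally detected
#'   spatially variable genes; adds an SPG-vs-SVG contingency table.
#' @param out_dir Optional directory; when given, the score table,
#'   per-slide test predictions and a JSON run manifest are written there.
#' @param verbose Print stage-by-stage progress with spot/gene counts.
#' @return An object of class `spg_pipeline`: per-slide `cv` and
#'   `importance`, the scored `table`, the `spg` ids, the `manifest`, and
#'   (if requested) the contingency table.
#' @export
run_spg_pipeline <- function(slides, min_genes = 200, min_reads = 10,
                             min_spots = 2, normalize_method = "log1p_cpm",
                             scale_per_gene = TRUE, min_variance = 0.05,
                             layers = c(1, 3, 5),
                             learning_rates = c(0.1, 0.01, 0.001),
                             k = 10, batch_size = 32, max_epochs = 100,
                             patience = 10, seed = 1,
                             target_mode = "sum_xy", csmi_threshold = 0.15,
                             cspni_threshold = 20, svg_list = NULL,
                             out_dir = NULL, verbose = TRUE) {
  stopifnot(length(slides) >= 1)
  lapply(slides, validate_slide)
  say <- function(...) if (verbose) message(sprintf(...))

  slide_names <- vapply(slides, function(s) s$slide_id, character(1))
  if (anyDuplicated(slide_names))
    slide_names <- make.unique(slide_names)

  cvs <- list(); imps <- list(); slide_meta <- list()
  for (i in seq_along(slides)) {
    s <- slides[[i]]
    say("[%s] %d spots x %d genes (counts)", slide_names[i],
        length(s$spot_ids), length(s$gene_ids))
    pp <- preprocess_slide(s, min_genes = min_genes, min_reads = min_reads,
                           min_spots = min_spots,
                           normalize_method = normalize_method,
                           scale_per_gene = scale_per_gene,
                           min_variance = min_variance)
    sn <- pp$slide
    say("[%s] after filters: %d spots x %d genes (%d removed by variance filter)",
        slide_names[i], length(sn$spot_ids), length(sn$gene_ids),
        length(pp$removed_gene_ids))
    cv <- cv_coord_mlp(sn, layers = layers, learning_rates = learning_rates,
                       k = k, seed = seed + i, batch_size = batch_size,
                       max_epochs = max_epochs, patience = patience)
    say("[%s] CV-MDE %.4g (best: %d layer(s), lr %g; null %.4g)",
        slide_names[i], cv$cv_mde, cv$best_hyperparams$n_hidden_layers,
        cv$best_hyperparams$learning_rate, centroid_null_mde(sn))
    imp <- testfold_importance(cv, sn, target_mode = target_mode)
    cvs[[slide_names[i]]] <- cv
    imps[[slide_names[i]]] <- imp
    slide_meta[[slide_names[i]]] <- list(
      patient_id = s$patient_id, slide_id = s$slide_id,
      n_spots_in = length(s$spot_ids), n_genes_in = length(s$gene_ids),
      n_spots = length(sn$spot_ids), n_genes = length(sn$gene_ids),
      variance_removed = length(pp$removed_gene_ids),
      cv_mde = cv$cv_mde, null_mde = centroid_null_mde(sn),
      best = cv$best_hyperparams)
  }

  tab <- gene_score_table(imps, slide_names = slide_names)
  tab <- select_spgs(tab, csmi_threshold = csmi_threshold,
                     cspni_threshold = cspni_threshold)
  spg <- tab$gene_id[tab$is_spg]
  say("SPGs called: %d of %d genes (%d seed, %d rescued)",
      length(spg), nrow(tab), sum(tab$spg_reason == "csmi_seed"),
      sum(tab$spg_reason == "mni_rescue"))

  contingency <- NULL
  if (!is.null(svg_list))
    contingency <- spg_svg_contingency(spg, intersect(svg_list, tab$gene_id),
                                       tab$gene_id)

  manifest <- list(
    package = "spgdetect",
    version = as.character(utils::packageVersion("spgdetect")),
    seed = seed,
    parameters = list(
      min_genes_per_spot = min_genes, min_reads_per_gene = min_reads,
      min_spots_per_gene = min_spots, normalize_method = normalize_method,
      scale_per_gene = scale_per_gene, min_variance = min_variance,
      layers = layers, learning_rates = learning_rates, k = k,
      batch_size = batch_size, max_epochs = max_epochs, patience = patience,
      target_mode = target_mode, csmi_threshold = csmi_threshold,
      cspni_threshold = cspni_threshold),
    slides = slide_meta,
    n_spgs = length(spg))

  res <- structure(list(cv = cvs, importance = imps, table = tab, spg = spg,
                        contingency = contingency, manifest = manifest),
                   class = "spg_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_scores(tab, file.path(out_dir, "gene_scores.tsv"))
    writeLines(spg, file.path(out_dir, "spg_list.txt"))
    for (nm in names(cvs)) {
      p <- cvs[[nm]]$test_predictions
      utils::write.table(
        data.frame(spot_id = rownames(p), pred_x = p[, 1], pred_y = p[, 2],
                   x = cvs[[nm]]$coords[, 1], y = cvs[[nm]]$coords[, 2]),
        file.path(out_dir, paste0("predictions_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.spg_pipeline <- function(x, ...) {
  cat(sprintf("spg_pipeline: %d slide(s), %d genes scored, %d SPGs\n",
              length(x$cv), nrow(x$table), length(x$spg)))
  for (nm in names(x$cv))
    cat(sprintf("  %s: CV-MDE %.4g (best %d layer(s), lr %g)\n", nm,
                x$cv[[nm]]$cv_mde, x$cv[[nm]]$best_hyperparams$n_hidden_layers,
                x$cv[[nm]]$best_hyperparams$learning_rate))
  invisible(x)
}

#' Run the pipeline from a YAML configuration file
#'
#' The config either lists slide input files (`slides:`, each with
#' `matrix`, `coords`, and for MTX input `genes`/`spots`) or requests a
#' simulation (`simulate:` with [make_ground_truth()] arguments plus
#' `n_slides`). Optional blocks `preprocess`, `train`, `scoring` override
#' the corresponding defaults; `seed` and `out` set the master seed and
#' output directory. The config is validated before any computation.
#'
#' @param config_path Path to the YAML file.
#' @param verbose Passed through to [run_spg_pipeline()].
#' @return The [run_spg_pipeline()] result.
#' @export
run_pipeline_config <- function(config_path, verbose = TRUE) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$slides) == is.null(cfg$simulate))
    stop("config must have exactly one of 'slides' or 'simulate'")
  if (!is.null(cfg$slides)) {
    for (i in seq_along(cfg$slides)) {
      sl <- cfg$slides[[i]]
      for (key in c("matrix", "coords"))
        if (is.null(sl[[key]]))
          stop("slide entry ", i, " is missing '", key, "'")
      if (!file.exists(sl$matrix)) stop("missing file: ", sl$matrix)
      if (!file.exists(sl$coords)) stop("missing file: ", sl$coords)
    }
  }
  seed <- cfg$seed %||% 1L
  slides <- if (!is.null(cfg$slides)) {
    lapply(cfg$slides, function(sl)
      read_slide(sl$matrix, genes_path = sl$genes, spots_path = sl$spots,
                 coords_path = sl$coords,
                 patient_id = sl$patient_id %||% "patient",
                 slide_id = sl$slide_id %||% basename(sl$matrix),
                 orientation = sl$orientation %||% "genes_x_spots"))
  } else {
    sim_args <- cfg$simulate
    n_slides <- sim_args$n_slides %||% 3L
    sim_args$n_slides <- NULL
    do.call(simulate_patient,
            c(list(n_slides = n_slides, seed = seed), sim_args))$slides
  }
  pp <- cfg$preprocess %||% list()
  tr <- cfg$train %||% list()
  sc <- cfg$scoring %||% list()
  run_spg_pipeline(
    slides,
    min_genes = pp$min_genes_per_spot %||% 200,
    min_reads = pp$min_reads_per_gene %||% 10,
    min_spots = pp$min_spots_per_gene %||% 2,
    normalize_method = pp$normalize$method %||% "log1p_cpm",
    scale_per_gene = pp$normalize$scale_per_gene %||% TRUE,
    min_variance = pp$min_variance %||% 0.05,
    layers = unlist(tr$layers %||% c(1, 3, 5)),
    learning_rates = unlist(tr$learning_rates %||% c(0.1, 0.01, 0.001)),
    k = tr$k %||% 10, batch_size = tr$batch_size %||% 32,
    max_epochs = tr$max_epochs %||% 100, patience = tr$patience %||% 10,
    seed = seed,
    target_mode = sc$target_mode %||% "sum_xy",
    csmi_threshold = sc$csmi_threshold %||% 0.15,
    cspni_threshold = sc$cspni_threshold %||% 20,
    svg_list = if (!is.null(sc$svg_list)) readLines(sc$svg_list),
    out_dir = cfg$out, verbose = verbose)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
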