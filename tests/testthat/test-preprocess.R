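# minimal public path to a 1-spot slide for the degenerate-variance case
subset_slide_public <- function(slide, spots) {
  spatial_slide(slide$expression[spots, , drop = FALSE],
                slide$coords[spots, , drop = FALSE],
                gene_ids = slide$gene_ids, spot_ids = slide$spot_ids[spots],
                normalized = slide$normalized)
}

# fixture with known per-spot detection counts: spot i detects exactly
# det[i] genes (count 1 each) out of n_genes
detection_slide <- function(det, n_genes) {
  counts <- t(vapply(det, function(d) c(rep(1, d), rep(0, n_genes - d)),
                     numeric(n_genes)))
  spatial_slide(counts, cbind(x = seq_along(det), y = seq_along(det)),
                gene_ids = paste0("g", seq_len(n_genes)),
                spot_ids = paste0("s", seq_along(det)))
}

test_that("spot filter keeps exactly the spots with enough detected genes", {
  sl <- detection_slide(c(250, 200, 199, 0), 300)
  kept <- filter_spots(sl, min_genes = 200)
  expect_identical(kept$spot_ids, c("s1", "s2"))
  expect_identical(kept$gene_ids, sl$gene_ids)

  expect_identical(filter_spots(sl, min_genes = 0)$spot_ids, sl$spot_ids)
  expect_error(filter_spots(sl, min_genes = 301), "empty")
  expect_error(filter_spots(normalize_slide(sl), min_genes = 1), "normalized")
})

test_that("gene filter applies the read-total and spot-count rules jointly", {
  # g1: 9 reads in 9 spots (out on reads); g2: 100 reads in 1 spot (out on
  # spots); g3: 10 reads across 2 spots (boundary, kept)
  counts <- cbind(g1 = c(rep(1, 9), 0),
                  g2 = c(100, rep(0, 9)),
                  g3 = c(5, 5, rep(0, 8)))
  sl <- spatial_slide(counts, cbind(1:10, 1:10),
                      spot_ids = paste0("s", 1:10))
  kept <- filter_genes(sl)
  expect_identical(kept$gene_ids, "g3")
  expect_identical(kept$spot_ids, sl$spot_ids)
})

test_that("filters are idempotent and match a brute-force oracle", {
  for (seed in 1:10) {
    sl <- toy_count_slide(n_spots = 10, n_genes = 10, seed = seed,
                          max_count = 3)
    min_genes <- 4; min_reads <- 12; min_spots <- 5
    # each filter is idempotent on its own output
    fs <- filter_spots(sl, min_genes)
    expect_identical(filter_spots(fs, min_genes)$expression, fs$expression)
    fg <- filter_genes(sl, min_reads, min_spots)
    expect_identical(filter_genes(fg, min_reads, min_spots)$expression,
                     fg$expression)
    once <- filter_genes(fs, min_reads, min_spots)

    # brute force: explicit double loop over the original matrix
    m <- sl$expression
    keep_spots <- c()
    for (i in seq_len(nrow(m)))
      if (sum(m[i, ] > 0) >= min_genes) keep_spots <- c(keep_spots, i)
    keep_genes <- c()
    for (j in seq_len(ncol(m))) {
      tot <- 0; nsp <- 0
      for (i in keep_spots) {
        tot <- tot + m[i, j]
        if (m[i, j] > 0) nsp <- nsp + 1
      }
      if (tot >= min_reads && nsp >= min_spots)
        keep_genes <- c(keep_genes, j)
    }
    expect_identical(once$expression,
                     m[keep_spots, keep_genes, drop = FALSE])
  }
})

test_that("log1p-CPM normalization handles degenerate spots and genes", {
  counts <- rbind(s1 = c(0, 0, 5), s2 = c(0, 0, 5), s3 = c(0, 0, 0))
  colnames(counts) <- paste0("g", 1:3)
  sl <- spatial_slide(counts, cbind(1:3, 1:3))

  raw <- normalize_slide(sl, scale_per_gene = FALSE)
  expect_true(raw$normalized)
  expect_true(all(raw$expression["s3", ] == 0))      # all-zero spot stays 0
  expect_identical(raw$expression["s1", ], raw$expression["s2", ]) # identical spots

  scaled <- normalize_slide(sl, scale_per_gene = TRUE)
  expect_true(all(scaled$expression[, c("g1", "g2")] == 0)) # zero-variance -> 0
  expect_equal(unname(colMeans(scaled$expression[, "g3", drop = FALSE])), 0)
})

test_that("variance filter uses a strict < rule on population variance", {
  # g1 constant (variance 0, removed); g2 has population variance exactly
  # 0.25 (boundary: kept when the threshold equals it)
  x <- cbind(g1 = rep(2, 4), g2 = c(0, 1, 0, 1), g3 = c(0, 10, 0, 10))
  sl <- spatial_slide(x, cbind(1:4, 1:4), spot_ids = paste0("s", 1:4),
                      normalized = TRUE)
  out <- variance_filter(sl, min_variance = 0.25)
  expect_identical(out$removed_gene_ids, "g1")
  expect_identical(out$slide$gene_ids, c("g2", "g3"))

  none <- variance_filter(sl, min_variance = 0)
  expect_identical(none$removed_gene_ids, character(0))

  expect_error(variance_filter(subset_slide_public(sl, 1), 0.05), "fewer than 2")
})
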