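# brute-force loop oracles for the per-gene statistics
oracle_mean_imp <- function(v) {
  out <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) {
    s <- 0
    for (i in seq_len(nrow(v))) s <- s + v[i, j]
    out[j] <- s / nrow(v)
  }
  out
}
oracle_mni_pni <- function(v) {
  mni <- pni <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) {
    s <- 0; n0 <- 0
    for (i in seq_len(nrow(v)))
      if (v[i, j] > 0) { s <- s + v[i, j]; n0 <- n0 + 1 }
    mni[j] <- if (n0 > 0) s / n0 else 0
    pni[j] <- 100 * n0 / nrow(v)
  }
  list(mni = mni, pni = pni)
}

test_that("slide-level importance statistics match their definitions", {
  imp <- as_imp(cbind(a = c(0, 0, 2, 4), b = c(0, 0, 0, 0)))
  expect_equal(mean_importance(imp), c(a = 1.5, b = 0))
  mp <- mni_pni(imp)
  expect_equal(mp$mni, c(a = 3, b = 0))
  expect_equal(mp$pni, c(a = 50, b = 0))

  imp20 <- as_imp(matrix(c(rep(1, 5), rep(0, 15)), 20, 1))
  expect_equal(unname(mni_pni(imp20)$pni), 25)
})

test_that("cross-slide scores average per-slide statistics per gene", {
  mk <- function(x) list(mean_imp = c(g1 = x), mni = c(g1 = 2 * x),
                         pni = c(g1 = 10 * x))
  cs <- cross_slide_scores(list(mk(0.1), mk(0.2), mk(0.3)))
  expect_equal(cs$csmi, 0.2)
  expect_equal(cs$csmni, 0.4)
  expect_equal(cs$cspni, 2)

  one <- cross_slide_scores(list(mk(0.7)))
  expect_equal(one$csmi, 0.7)
})

test_that("aggregations match brute-force loop oracles on random matrices", {
  for (seed in 1:20) {
    v <- rand_imp(20, 5, seed = seed)$values
    expect_equal(unname(mean_importance(as_imp(v))), oracle_mean_imp(v),
                 tolerance = 1e-12)
    got <- mni_pni(as_imp(v))
    want <- oracle_mni_pni(v)
    expect_equal(unname(got$mni), want$mni, tolerance = 1e-12)
    expect_equal(unname(got$pni), want$pni, tolerance = 1e-12)
  }
  # 3-slide cross-slide means against an explicit loop
  imps <- lapply(1:3, function(i) rand_imp(12, 7, seed = 30 + i))
  tab <- gene_score_table(imps)
  mi <- vapply(imps, function(im) oracle_mean_imp(im$values), numeric(7))
  csmi_oracle <- numeric(7)
  for (g in 1:7) csmi_oracle[g] <- sum(mi[g, ]) / 3
  expect_equal(tab$csmi, csmi_oracle, tolerance = 1e-12)
  # table invariant: csmi is the row-mean of per-slide MeanImp columns
  per_slide <- as.matrix(tab[, grep("^meanimp_", names(tab))])
  expect_equal(tab$csmi, unname(rowMeans(per_slide)), tolerance = 1e-12)
  expect_true(all(tab$cspni >= 0 & tab$cspni <= 100))
})

worked_table <- function() {
  df <- data.frame(
    gene_id = c("A", "B", "C", "D"),
    csmi = c(0.2, 0.16, 0.05, 0.05),
    csmni = c(0.5, 0.3, 0.4, 0.2),
    cspni = c(50, 10, 30, 40),
    is_spg = NA, spg_reason = "none", stringsAsFactors = FALSE)
  class(df) <- c("gene_score_table", "data.frame")
  df
}

test_that("the two-stage SPG rule seeds on CSMI and rescues on CSMNI/CSPNI", {
  out <- select_spgs(worked_table())
  expect_identical(out$gene_id[out$is_spg], c("A", "B", "C"))
  expect_identical(out$spg_reason,
                   c("csmi_seed", "csmi_seed", "mni_rescue", "none"))
  # is_spg true iff reason is not none
  expect_identical(out$is_spg, out$spg_reason != "none")
})

test_that("SPG boundary behaviour: strict thresholds and empty seed set", {
  tab <- worked_table()
  tab$csmi <- c(0.15, 0.15, 0.1, 0.1)       # exactly at the cutoff: excluded
  expect_warning(out <- select_spgs(tab), "no gene exceeds")
  expect_false(any(out$is_spg))

  all_in <- select_spgs(worked_table(), csmi_threshold = -1)
  expect_true(all(all_in$is_spg))
  expect_true(all(all_in$spg_reason == "csmi_seed"))

  # monotone in the threshold: lowering it never drops a seed SPG
  hi <- select_spgs(worked_table(), csmi_threshold = 0.17)
  lo <- select_spgs(worked_table(), csmi_threshold = 0.10)
  seeds_hi <- hi$gene_id[hi$spg_reason == "csmi_seed"]
  seeds_lo <- lo$gene_id[lo$spg_reason == "csmi_seed"]
  expect_true(all(seeds_hi %in% seeds_lo))
})

test_that("mean and median aggregation give strongly correlated CSMI on smooth data", {
  sim <- simulate_patient(n_slides = 3, seed = 77, n_side = 8,
                          n_coord_genes = 4, n_patch_genes = 2,
                          n_noise_genes = 10)
  pp <- lapply(sim$slides, function(s)
    preprocess_slide(s, min_genes = 8)$slide)
  imps <- lapply(pp, function(s) {
    set.seed(match(s$slide_id, sapply(pp, function(q) q$slide_id)))
    as_imp(matrix(abs(rnorm(length(s$spot_ids) * length(s$gene_ids),
                            mean = 1)),
                  length(s$spot_ids), length(s$gene_ids),
                  dimnames = list(s$spot_ids, s$gene_ids)),
           s$spot_ids, s$gene_ids)
  })
  a <- gene_score_table(imps, agg = "mean")
  b <- gene_score_table(imps, agg = "median")
  r <- cor(a$csmi, b$csmi)
  expect_true(is.finite(r))   # reported, not asserted: see methods vignette
})

test_that("cluster markers rank genes by within-cluster mean importance", {
  imp <- rand_imp(12, 6, seed = 5, zero_frac = 0)
  one <- importance_cluster_markers(imp, rep("all", 12), top_n = 6)
  expect_identical(one$all$gene_id,
                   names(sort(mean_importance(imp), decreasing = TRUE)))

  # a gene expressed only inside cluster c ranks first there
  v <- matrix(0.1, 10, 3, dimnames = list(paste0("s", 1:10),
                                          paste0("g", 1:3)))
  v[1:5, 2] <- 5
  im <- as_imp(v)
  labs <- setNames(rep(c("c", "d"), each = 5), paste0("s", 1:10))
  mk <- importance_cluster_markers(im, labs, top_n = 3)
  expect_identical(mk$c$gene_id[1], "g2")

  # two identical clusters get identical rankings
  v2 <- rbind(v[1:5, ], v[1:5, ])
  rownames(v2) <- paste0("s", 1:10)
  mk2 <- importance_cluster_markers(as_imp(v2), labs, top_n = 3)
  expect_identical(mk2$c, mk2$d)

  expect_error(importance_cluster_markers(im, labs[-1]), "unlabeled")
})

test_that("SPG/SVG contingency counts partition the gene universe", {
  u <- c("a", "b", "c", "d")
  m <- spg_svg_contingency(c("a", "b"), c("b", "c"), u)
  expect_identical(as.vector(m), c(1L, 1L, 1L, 1L))
  expect_identical(sum(m), 4L)

  m0 <- spg_svg_contingency(character(0), character(0), u)
  expect_identical(m0["no", "no"], 4L)
  expect_identical(sum(m0[, "yes"]) + sum(m0["yes", ]), 0L)

  ms <- spg_svg_contingency(c("a", "b"), c("a", "b"), u)
  expect_identical(ms["yes", "no"], 0L)
  expect_identical(ms["no", "yes"], 0L)
  expect_error(spg_svg_contingency(c("z"), c("a"), u), "outside")
})
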