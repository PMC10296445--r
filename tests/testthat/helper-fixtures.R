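# In-code fixtures shared across the suite. Everything is generated, seeded
# and small.

# random count slide on an arbitrary (non-grid) coordinate layout
toy_count_slide <- function(n_spots = 8, n_genes = 6, seed = 1,
                            max_count = 20, slide_id = "toy") {
  set.seed(seed)
  counts <- matrix(rpois(n_spots * n_genes, lambda = max_count / 2),
                   n_spots, n_genes)
  coords <- cbind(x = runif(n_spots, 0, 10), y = runif(n_spots, 0, 10))
  spatial_slide(counts, coords,
                gene_ids = paste0("gene", seq_len(n_genes)),
                spot_ids = paste0("spot", seq_len(n_spots)),
                slide_id = slide_id)
}

# wrap a plain matrix as an importance_matrix
as_imp <- function(values, spot_ids = rownames(values),
                   gene_ids = colnames(values)) {
  if (is.null(spot_ids)) spot_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  dimnames(values) <- list(spot_ids, gene_ids)
  structure(list(values = values, spot_ids = spot_ids, gene_ids = gene_ids,
                 target_mode = "sum_xy", fold = NULL),
            class = "importance_matrix")
}

# random importance matrix with a controlled share of exact zeros
rand_imp <- function(n_spots = 20, n_genes = 15, seed = 1, zero_frac = 0.3) {
  set.seed(seed)
  v <- matrix(runif(n_spots * n_genes, 0, 2), n_spots, n_genes)
  v[runif(length(v)) < zero_frac] <- 0
  as_imp(v)
}

# a noiseless slide whose first two genes are exact (scaled) coordinates —
# a linear map the network can realize
planted_linear_slide <- function(n_side = 10, n_noise_genes = 0, seed = 1,
                                 coord_scale = 10) {
  p <- 2 * (seq_len(n_side) - 1)
  p <- p - mean(p)
  g <- as.matrix(expand.grid(x = p, y = p, KEEP.OUT.ATTRS = FALSE))
  n <- nrow(g)
  set.seed(seed)
  X <- cbind(g[, 1] / coord_scale, g[, 2] / coord_scale)
  if (n_noise_genes > 0)
    X <- cbind(X, matrix(rnorm(n * n_noise_genes), n))
  colnames(X) <- paste0("gene", seq_len(ncol(X)))
  rownames(X) <- paste0("spot", seq_len(n))
  spatial_slide(X, g, normalized = TRUE)
}

# tiny trained network on the planted slide, for attribution tests
trained_toy_model <- function(n_noise_genes = 3, max_epochs = 30, seed = 5) {
  sl <- planted_linear_slide(n_side = 8, n_noise_genes = n_noise_genes,
                             seed = seed)
  spec <- arch_spec(ncol(sl$expression),
                    plan_architecture(max(ncol(sl$expression), 4), 1),
                    learning_rate = 0.05, max_epochs = max_epochs,
                    seed = seed)
  list(model = coord_mlp(sl, spec), slide = sl)
}

# a hand-built network that computes exactly y1 = 2*g1, y2 = 3*g2 on
# non-negative inputs (identity hidden layer, batch-norm neutralized)
linear_toy_model <- function() {
  spec <- arch_spec(2, 2, seed = 1)
  m <- build_model(spec)
  m$layers[[1]]$W <- diag(2)
  m$layers[[1]]$b <- c(0, 0)
  m$layers[[1]]$gamma <- c(1, 1)
  m$layers[[1]]$beta <- c(0, 0)
  m$layers[[1]]$rm <- c(0, 0)
  m$layers[[1]]$rv <- c(1, 1) - spgdetect:::BN_EPS  # BN scale exactly 1
  m$out$W <- matrix(c(2, 0, 0, 3), 2, 2)
  m$out$b <- c(0, 0)
  m$trained <- TRUE
  m
}
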