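test_that("hidden-width allocation halves layers and totals half the input", {
  expect_identical(plan_architecture(1000, 1), 500L)
  expect_identical(plan_architecture(1000, 3), c(286L, 143L, 71L))
  expect_identical(plan_architecture(1000, 5), c(258L, 129L, 65L, 32L, 16L))
  for (L in c(1, 3, 5)) {
    w <- plan_architecture(1000, L)
    expect_lte(abs(sum(w) - 500), 2)
    if (L > 1)
      expect_true(all(abs(w[-1] - w[-length(w)] / 2) <= 1))
  }
  expect_identical(plan_architecture(1000, 3, first_layer_half = TRUE),
                   c(500L, 250L, 125L))
  expect_error(plan_architecture(8, 5), "below 2")
  expect_error(plan_architecture(3, 1), "at least 4")
})

test_that("model construction is seeded and counts parameters correctly", {
  spec <- arch_spec(8, 4, seed = 99)
  m1 <- build_model(spec); m2 <- build_model(spec)
  # dense 8*4+4, BN scale/shift 2*4, output 4*2+2
  expect_identical(n_params(m1), 54L)
  expect_identical(m1$layers[[1]]$W, m2$layers[[1]]$W)
  expect_identical(m1$out$W, m2$out$W)
  m3 <- build_model(arch_spec(8, 4, seed = 100))
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))
})

test_that("mean distance error is the mean Euclidean displacement", {
  a <- rbind(c(0, 0), c(1, 1))
  expect_identical(mean_distance_error(a, a), 0)
  expect_identical(mean_distance_error(rbind(c(3, 4)), rbind(c(0, 0))), 5)
  expect_identical(mean_distance_error(rbind(c(3, 4), c(1, 1)),
                                       rbind(c(0, 0), c(1, 1))), 2.5)
  expect_error(mean_distance_error(a, a[1, , drop = FALSE]), "dimensions")
})

test_that("training is deterministic given a seed and skips at 0 epochs", {
  sl <- planted_linear_slide(n_side = 6, n_noise_genes = 2, seed = 3)
  spec <- arch_spec(4, 2, learning_rate = 0.05, max_epochs = 8, seed = 21)
  f1 <- coord_mlp(sl, spec)
  f2 <- coord_mlp(sl, spec)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, sl), predict(f2, sl))

  spec0 <- arch_spec(4, 2, max_epochs = 0, seed = 21)
  f0 <- coord_mlp(sl, spec0)
  expect_identical(nrow(f0$history), 0L)
  init <- build_model(spec0, gene_ids = colnames(sl$expression))
  expect_identical(f0$layers[[1]]$W, init$layers[[1]]$W)
})

test_that("a noiseless linear coordinate code is learned almost exactly", {
  sl <- planted_linear_slide(n_side = 10, n_noise_genes = 0, seed = 1)
  n <- nrow(sl$expression)
  set.seed(2)
  idx <- sample(n); tr <- idx[seq_len(80)]; va <- idx[81:n]
  spec <- arch_spec(2, 4, learning_rate = 0.05, max_epochs = 200,
                    early_stopping_patience = 30, seed = 11)
  fit <- coord_mlp(subset_slide(sl, spots = tr), spec,
                   val = subset_slide(sl, spots = va))
  diameter <- sqrt(sum((apply(sl$coords, 2, max) -
                        apply(sl$coords, 2, min))^2))
  expect_lt(min(fit$history$val_mde), 0.05 * diameter)
})

test_that("prediction is deterministic, batch-consistent and total", {
  tm <- trained_toy_model()
  X <- tm$slide$expression
  p1 <- predict(tm$model, X)
  p2 <- predict(tm$model, X)
  expect_identical(p1, p2)
  # batch prediction equals per-spot prediction (inference-mode batch norm)
  rows <- c(1, 5, 9)
  per_spot <- do.call(rbind, lapply(rows, function(i)
    predict(tm$model, X[i, , drop = FALSE])))
  expect_equal(unname(per_spot), unname(p1[rows, ]))
  # all-zero input gives finite coordinates
  expect_true(all(is.finite(predict(tm$model, matrix(0, 1, ncol(X))))))
  expect_error(predict(tm$model, X[, -1]), "genes")
})

test_that("cross-validation partitions spots and reports a consistent CV error", {
  sl <- planted_linear_slide(n_side = 10, n_noise_genes = 3, seed = 6)
  cv <- cv_coord_mlp(sl, layers = 1, learning_rates = 0.05, k = 5, seed = 8,
                     max_epochs = 60)
  # bijection: every spot in exactly one test fold, sizes sum to n
  expect_identical(sort(names(cv$fold_assignment)), sort(sl$spot_ids))
  expect_identical(sum(table(cv$fold_assignment)), length(sl$spot_ids))
  expect_true(all(table(cv$fold_assignment) == 20))
  expect_false(anyNA(cv$test_predictions))
  # stored CV error matches recomputation from the returned predictions
  expect_equal(cv$cv_mde,
               mean_distance_error(cv$test_predictions, sl$coords),
               tolerance = 1e-6)
  # a single grid point is best by construction
  expect_identical(cv$best_hyperparams,
                   list(n_hidden_layers = 1, learning_rate = 0.05))
  # planted coordinates: the model clearly beats the centroid null
  expect_lt(cv$cv_mde, 0.5 * centroid_null_mde(sl))

  expect_error(cv_coord_mlp(sl, k = 2), "k must be")
  expect_error(cv_coord_mlp(subset_slide(sl, spots = 1:4), k = 5),
               "at least k spots")
})

test_that("cross-validation is bit-reproducible for a fixed seed", {
  sl <- planted_linear_slide(n_side = 6, n_noise_genes = 2, seed = 4)
  cv1 <- cv_coord_mlp(sl, layers = 1, learning_rates = 0.05, k = 3,
                      seed = 5, max_epochs = 5)
  cv2 <- cv_coord_mlp(sl, layers = 1, learning_rates = 0.05, k = 3,
                      seed = 5, max_epochs = 5)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$test_predictions, cv2$test_predictions)
  expect_identical(cv1$cv_mde, cv2$cv_mde)
})
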