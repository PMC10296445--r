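# Dense feedforward coordinate-regression network, implemented directly in
# base R matrix code. Architecture: input -> [dense -> batch-norm -> ReLU]
# per hidden width -> dense(2, linear). He-normal init, Adam, mean-distance
# loss. Everything is seeded and single-threaded, so runs are reproducible.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9   # running = mom * running + (1 - mom) * batch

#' Build (initialize) a coordinate-regression model
#'
#' Creates the network described by an [arch_spec()]: each hidden block is a
#' dense layer followed by batch normalization and ReLU; the output layer is
#' a linear 2-node layer for (x, y). Weights are He-normal initialized
#' (sd = sqrt(2 / fan_in)) using `spec$seed`, so two builds with the same
#' spec are identical.
#'
#' @param spec An [arch_spec()].
#' @param gene_ids Optional gene ids to stamp on the model (checked at
#'   prediction time).
#' @return An object of class `coord_mlp` (untrained).
#' @export
build_model <- function(spec, gene_ids = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  if (!is.null(gene_ids) && length(gene_ids) != spec$n_input)
    stop("gene_ids length != spec$n_input")
  set.seed(spec$seed)
  fan_in <- spec$n_input
  layers <- vector("list", length(spec$hidden_widths))
  for (i in seq_along(spec$hidden_widths)) {
    w <- spec$hidden_widths[i]
    layers[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * w, sd = sqrt(2 / fan_in)), fan_in, w),
      b = numeric(w), gamma = rep(1, w), beta = numeric(w),
      rm = numeric(w), rv = rep(1, w))
    fan_in <- w
  }
  out <- list(W = matrix(stats::rnorm(fan_in * 2, sd = sqrt(2 / fan_in)),
                         fan_in, 2),
              b = numeric(2))
  structure(list(spec = spec, layers = layers, out = out,
                 gene_ids = gene_ids, trained = FALSE, history = NULL),
            class = "coord_mlp")
}

relu <- function(x) pmax(x, 0)

# inference-mode forward pass; returns n x 2 predictions
mlp_forward_infer <- function(model, X) {
  A <- X
  for (ly in model$layers) {
    Z <- A %*% ly$W + rep(ly$b, each = nrow(A))
    Zh <- sweep(sweep(Z, 2, ly$rm), 2, sqrt(ly$rv + BN_EPS), "/")
    A <- relu(sweep(sweep(Zh, 2, ly$gamma, "*"), 2, ly$beta, "+"))
  }
  A %*% model$out$W + rep(model$out$b, each = nrow(A))
}

# training-mode forward pass on one minibatch: batch statistics for BN,
# caches for backprop, updated running stats
mlp_forward_train <- function(model, X) {
  caches <- vector("list", length(model$layers))
  A <- X
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    Z <- A %*% ly$W + rep(ly$b, each = nrow(A))
    mu <- colMeans(Z)
    va <- colMeans(sweep(Z, 2, mu)^2)
    invstd <- 1 / sqrt(va + BN_EPS)
    Zh <- sweep(sweep(Z, 2, mu), 2, invstd, "*")
    Bn <- sweep(sweep(Zh, 2, ly$gamma, "*"), 2, ly$beta, "+")
    Aout <- relu(Bn)
    caches[[i]] <- list(A_in = A, Zh = Zh, invstd = invstd, Bn = Bn)
    model$layers[[i]]$rm <- BN_MOMENTUM * ly$rm + (1 - BN_MOMENTUM) * mu
    model$layers[[i]]$rv <- BN_MOMENTUM * ly$rv + (1 - BN_MOMENTUM) * va
    A <- Aout
  }
  pred <- A %*% model$out$W + rep(model$out$b, each = nrow(A))
  list(model = model, pred = pred, A_last = A, caches = caches)
}

# gradients of mean-distance loss wrt all parameters for one minibatch
mlp_backward <- function(model, fw, Y) {
  n <- nrow(Y)
  diff <- fw$pred - Y
  d <- sqrt(rowSums(diff^2))
  dP <- diff / (n * pmax(d, 1e-12))          # d MDE / d pred
  grads <- list(out = list(W = crossprod(fw$A_last, dP), b = colSums(dP)),
                layers = vector("list", length(model$layers)))
  delta <- dP %*% t(model$out$W)             # gradient wrt last activation
  for (i in rev(seq_along(model$layers))) {
    ca <- fw$caches[[i]]
    ly <- model$layers[[i]]
    delta <- delta * (ca$Bn > 0)             # through ReLU
    dgamma <- colSums(delta * ca$Zh)
    dbeta <- colSums(delta)
    dZh <- sweep(delta, 2, ly$gamma, "*")
    m <- nrow(dZh)
    sum_dZh <- colSums(dZh)
    sum_dZhZh <- colSums(dZh * ca$Zh)
    dZ <- sweep(m * dZh, 2, sum_dZh) - sweep(ca$Zh, 2, sum_dZhZh, "*")
    dZ <- sweep(dZ, 2, ca$invstd / m, "*")
    grads$layers[[i]] <- list(W = crossprod(ca$A_in, dZ), b = colSums(dZ),
                              gamma = dgamma, beta = dbeta)
    delta <- dZ %*% t(ly$W)
  }
  grads
}

# flat views of trainable parameters (BN running stats excluded)
mlp_params <- function(model) {
  p <- list()
  for (i in seq_along(model$layers))
    for (nm in c("W", "b", "gamma", "beta"))
      p[[paste0("l", i, ".", nm)]] <- model$layers[[i]][[nm]]
  p[["out.W"]] <- model$out$W
  p[["out.b"]] <- model$out$b
  p
}

mlp_set_params <- function(model, p) {
  for (i in seq_along(model$layers))
    for (nm in c("W", "b", "gamma", "beta"))
      model$layers[[i]][[nm]] <- p[[paste0("l", i, ".", nm)]]
  model$out$W <- p[["out.W"]]
  model$out$b <- p[["out.b"]]
  model
}

grads_as_params <- function(model, grads) {
  p <- list()
  for (i in seq_along(model$layers))
    for (nm in c("W", "b", "gamma", "beta"))
      p[[paste0("l", i, ".", nm)]] <- grads$layers[[i]][[nm]]
  p[["out.W"]] <- grads$out$W
  p[["out.b"]] <- grads$out$b
  p
}

#' Number of trainable parameters (excluding batch-norm running statistics)
#' @param model A `coord_mlp`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  sum(vapply(mlp_params(model), length, integer(1)))
}

#' Fit the coordinate-regression network
#'
#' Trains a [build_model()] network to predict spot (x, y) coordinates from
#' expression, minimizing the mean distance error with Adam. Training stops
#' early when validation MDE has not improved for
#' `spec$early_stopping_patience` epochs, and the best-validation weights
#' are restored. With `max_epochs = 0` the initialized model is returned
#' untouched with an empty history.
#'
#' @param train A normalized [spatial_slide()] (or a list with `expression`
#'   and `coords` matrices) to train on.
#' @param spec An [arch_spec()]; `spec$n_input` must equal the number of
#'   genes.
#' @param val Optional slide monitored for early stopping; must share the
#'   training gene set. If `NULL`, training MDE is monitored instead.
#' @return A trained `coord_mlp` whose `history` is a data frame with
#'   per-epoch `train_mde` and `val_mde`.
#' @export
coord_mlp <- function(train, spec, val = NULL) {
  X <- as.matrix(train$expression)
  Y <- as.matrix(train$coords)
  if (ncol(X) != spec$n_input)
    stop("training matrix has ", ncol(X), " genes but spec expects ",
         spec$n_input)
  if (!is.null(val)) {
    if (!identical(colnames(val$expression), colnames(X)))
      stop("validation slide gene set/order differs from training")
    Xv <- as.matrix(val$expression)
    Yv <- as.matrix(val$coords)
  }
  model <- build_model(spec, gene_ids = colnames(X))
  n <- nrow(X)
  if (spec$max_epochs == 0L) {
    model$history <- data.frame(epoch = integer(), train_mde = numeric(),
                                val_mde = numeric())
    return(model)
  }

  # Adam state
  adam_m <- lapply(mlp_params(model), function(x) x * 0)
  adam_v <- adam_m
  t_step <- 0L
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  lr <- spec$learning_rate

  best_val <- Inf
  best_params <- NULL
  best_stats <- NULL
  wait <- 0L
  hist_epoch <- integer(); hist_train <- numeric(); hist_val <- numeric()

  for (epoch in seq_len(spec$max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = spec$batch_size)
    for (s in starts) {
      rows <- idx[s:min(s + spec$batch_size - 1L, n)]
      fw <- mlp_forward_train(model, X[rows, , drop = FALSE])
      model <- fw$model                       # running-stat update
      if (any(!is.finite(fw$pred)))
        stop("non-finite loss at epoch ", epoch,
             "; consider a smaller learning rate")
      grads <- grads_as_params(model,
                               mlp_backward(model, fw, Y[rows, , drop = FALSE]))
      t_step <- t_step + 1L
      par <- mlp_params(model)
      for (nm in names(par)) {
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grads[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1^t_step)
        vhat <- adam_v[[nm]] / (1 - b2^t_step)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + aeps)
      }
      model <- mlp_set_params(model, par)
    }
    train_mde <- mean_distance_error(mlp_forward_infer(model, X), Y)
    val_mde <- if (is.null(val)) train_mde
               else mean_distance_error(mlp_forward_infer(model, Xv), Yv)
    if (!is.finite(val_mde))
      stop("non-finite validation loss at epoch ", epoch)
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, train_mde)
    hist_val <- c(hist_val, val_mde)
    if (val_mde < best_val) {
      best_val <- val_mde
      best_params <- mlp_params(model)
      best_stats <- lapply(model$layers, function(ly) ly[c("rm", "rv")])
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$early_stopping_patience) break
    }
  }

  if (!is.null(best_params)) {
    model <- mlp_set_params(model, best_params)
    for (i in seq_along(model$layers)) {
      model$layers[[i]]$rm <- best_stats[[i]]$rm
      model$layers[[i]]$rv <- best_stats[[i]]$rv
    }
  }
  model$trained <- TRUE
  model$history <- data.frame(epoch = hist_epoch, train_mde = hist_train,
                              val_mde = hist_val)
  model
}

#' Predict spot coordinates from expression
#'
#' Deterministic inference-mode forward pass (batch normalization uses its
#' running statistics), so batch prediction equals row-by-row prediction.
#'
#' @param object A `coord_mlp`.
#' @param newdata A [spatial_slide()] or numeric matrix (spots x genes) in
#'   the training gene order.
#' @param ... Unused.
#' @return An n x 2 matrix with columns `x`, `y`.
#' @export
predict.coord_mlp <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spatial_slide")) newdata$expression
       else as.matrix(newdata)
  if (ncol(X) != object$spec$n_input)
    stop("newdata has ", ncol(X), " genes; model expects ",
         object$spec$n_input)
  if (!is.null(object$gene_ids) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$gene_ids))
    stop("newdata gene ids/order differ from the training genes")
  p <- mlp_forward_infer(object, X)
  colnames(p) <- c("x", "y")
  rownames(p) <- rownames(X)
  p
}

#' @export
print.coord_mlp <- function(x, ...) {
  cat(sprintf("coord_mlp: %d -> [%s] -> 2 (%s, %d parameters)\n",
              x$spec$n_input, paste(x$spec$hidden_widths, collapse = ", "),
              if (x$trained) "trained" else "untrained", n_params(x)))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  %d epochs; best val MDE %.4g\n",
                nrow(x$history), min(x$history$val_mde)))
  invisible(x)
}

#' @export
residuals.coord_mlp <- function(object, newdata, ...) {
  if (missing(newdata)) stop("supply the slide to compute residuals on")
  Y <- as.matrix(newdata$coords)
  predict(object, newdata) - Y
}
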