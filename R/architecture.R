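#' Plan hidden-layer widths for the coordinate-regression network
#'
#' Widths form a halving sequence whose total is as close as possible to
#' half the input size: the first width is `n_input / (2 * S)` with
#' `S = sum(2^-(0:(L-1)))`, and layer `j` is that unrounded base divided by
#' `2^(j-1)`, each rounded to the nearest integer (round-half-even, R's
#' `round()`). An alternative reading — first hidden layer exactly half the
#' input, then halving — is available via `first_layer_half = TRUE`.
#'
#' @param n_input Number of input genes (>= 4).
#' @param n_hidden_layers Number of hidden layers (the tuning grid uses 1,
#'   3, 5).
#' @param first_layer_half If `TRUE`, use the first-layer-= n/2 reading
#'   instead of total-= n/2.
#' @return Integer vector of hidden widths, strictly decreasing, each >= 2.
#' @export
#' @examples
#' plan_architecture(1000, 1) # 500
#' plan_architecture(1000, 3) # 286 143 71
plan_architecture <- function(n_input, n_hidden_layers,
                              first_layer_half = FALSE) {
  if (n_input < 4) stop("n_input must be at least 4")
  if (n_hidden_layers < 1) stop("need at least one hidden layer")
  L <- as.integer(n_hidden_layers)
  w1 <- if (first_layer_half) n_input / 2 else {
    S <- sum(2^-(0:(L - 1)))
    n_input / (2 * S)
  }
  widths <- as.integer(round(w1 / 2^(0:(L - 1))))
  if (any(widths < 2))
    stop("n_input = ", n_input, " is too small for ", L,
         " halving hidden layers (width would fall below 2)")
  if (L > 1 && any(diff(widths) >= 0))
    stop("hidden widths are not strictly decreasing for n_input = ", n_input)
  widths
}

#' Hyperparameter specification for one coordinate-regression model
#'
#' @param n_input Number of input genes.
#' @param hidden_widths Integer hidden-layer widths, e.g. from
#'   [plan_architecture()].
#' @param learning_rate Adam learning rate (tuning grid: 0.1, 0.01, 0.001).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Training epoch cap (default 100).
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping (default 10); best-validation weights are restored.
#' @param seed Integer seed controlling initialization and batching.
#' @return An object of class `arch_spec`.
#' @export
arch_spec <- function(n_input, hidden_widths, learning_rate = 0.01,
                      batch_size = 32, max_epochs = 100,
                      early_stopping_patience = 10, seed = 1) {
  hidden_widths <- as.integer(hidden_widths)
  stopifnot(n_input >= 1, length(hidden_widths) >= 1, all(hidden_widths >= 2),
            learning_rate > 0, batch_size >= 1, max_epochs >= 0,
            early_stopping_patience >= 1)
  if (length(hidden_widths) > 1 && any(diff(hidden_widths) >= 0))
    stop("hidden_widths must be strictly decreasing")
  structure(list(n_input = as.integer(n_input),
                 hidden_widths = hidden_widths,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed)),
            class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf(
    "arch_spec: %d inputs -> [%s] -> 2 outputs | lr %g, batch %d, <=%d epochs, patience %d, seed %d\n",
    x$n_input, paste(x$hidden_widths, collapse = ", "), x$learning_rate,
    x$batch_size, x$max_epochs, x$early_stopping_patience, x$seed))
  invisible(x)
}

#' Mean distance error between predicted and actual coordinates
#'
#' The training loss and evaluation metric: the mean Euclidean distance
#' between each spot's predicted and actual (x, y) position, in slide
#' coordinate units.
#'
#' @param predicted,actual Numeric n x 2 matrices.
#' @return A single non-negative number.
#' @export
mean_distance_error <- function(predicted, actual) {
  predicted <- as.matrix(predicted); actual <- as.matrix(actual)
  if (!identical(dim(predicted), dim(actual)))
    stop("predicted and actual must have identical dimensions")
  if (nrow(predicted) < 1) stop("need at least one spot")
  if (ncol(predicted) != 2) stop("coordinate matrices must have 2 columns")
  mean(sqrt(rowSums((predicted - actual)^2)))
}
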