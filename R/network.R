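#' Three-layer network architecture specification
#'
#' Describes a feedforward regression network with one hidden layer: `t`
#' input nodes, `g` hidden nodes (logistic sigmoid) and `p` output nodes
#' (linear, suited to targets min-max normalised to \[0, 1\]).
#'
#' @param n_input Number of input nodes (>= 1).
#' @param n_hidden Number of hidden nodes (>= 1).
#' @param n_output Number of output nodes (>= 1); 1 for a scalar load score.
#' @return An object of class `layer_spec`.
#' @examples
#' layer_spec(6, 4, 1)
#' @export
layer_spec <- function(n_input, n_hidden, n_output = 1L) {
  for (v in c(n_input, n_hidden, n_output)) {
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop("layer sizes must be single integers >= 1", call. = FALSE)
  }
  structure(
    list(n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
         n_output = as.integer(n_output)),
    class = "layer_spec")
}

#' @export
print.layer_spec <- function(x, ...) {
  cat(sprintf("<layer_spec> %d-%d-%d feedforward regression network\n",
              x$n_input, x$n_hidden, x$n_output))
  invisible(x)
}

#' Total number of free parameters of a network
#'
#' Counts weights and biases: `g*(t+1) + p*(g+1)` for a `t`-`g`-`p` network.
#' Biases are ordinary parameter slots (they share the weight interval in the
#' ant-colony search).
#'
#' @param spec A [layer_spec()].
#' @return Integer slot count.
#' @export
n_param_slots <- function(spec) {
  stopifnot(inherits(spec, "layer_spec"))
  spec$n_hidden * (spec$n_input + 1L) + spec$n_output * (spec$n_hidden + 1L)
}

#' Backpropagation training configuration
#'
#' @param learning_rate Positive step size for full-batch gradient descent.
#' @param momentum Momentum coefficient in \[0, 1); 0 gives plain
#'   backpropagation, the conventional 0.9 gives the momentum variant.
#' @param max_iterations Iteration cap (the `Y_BP` budget); >= 1.
#' @param target_error Stop once training MSE falls to this level (the `R_0`
#'   threshold, on the normalised scale).
#' @param seed Integer seed controlling any randomness downstream.
#' @return An object of class `bp_config`.
#' @export
bp_config <- function(learning_rate = 0.3, momentum = 0,
                      max_iterations = 13000L, target_error = 0.004,
                      seed = 1L) {
  if (!is.finite(learning_rate) || learning_rate <= 0)
    stop("learning_rate must be positive", call. = FALSE)
  if (!is.finite(momentum) || momentum < 0 || momentum >= 1)
    stop("momentum must lie in [0, 1)", call. = FALSE)
  if (!is.finite(max_iterations) || max_iterations < 1)
    stop("max_iterations must be >= 1", call. = FALSE)
  if (!is.finite(target_error) || target_error <= 0)
    stop("target_error must be positive", call. = FALSE)
  structure(
    list(learning_rate = learning_rate, momentum = momentum,
         max_iterations = as.integer(max_iterations),
         target_error = target_error, seed = as.integer(seed)),
    class = "bp_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialise network parameters uniformly on an interval
#'
#' Every weight and bias is drawn i.i.d. uniform on `[low, high]`,
#' reproducibly for a fixed seed. The plain-backpropagation baseline uses
#' `[-0.2, 0.2]`; the ant-colony search uses the wider `[-3, 3]` interval.
#'
#' @param spec A [layer_spec()].
#' @param low,high Interval bounds, `low < high`.
#' @param seed Integer seed.
#' @return An object of class `mlp_params` with fields `W1` (g x t), `b1`
#'   (g), `W2` (p x g), `b2` (p) and the originating `spec`.
#' @export
init_network <- function(spec, low = -0.2, high = 0.2, seed = 1L) {
  stopifnot(inherits(spec, "layer_spec"))
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("invalid interval: require low < high", call. = FALSE)
  n <- n_param_slots(spec)
  theta <- withr::with_seed(as.integer(seed), stats::runif(n, low, high))
  unflatten_params(theta, spec)
}

#' Flatten network parameters to a single vector
#'
#' Slot order is fixed (W1 column-major, b1, W2 column-major, b2) so that the
#' discretised candidate grid, pheromone tables and gradients all index the
#' same slots.
#'
#' @param params An `mlp_params` object.
#' @return Numeric vector of length [n_param_slots()].
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "mlp_params"))
  c(as.vector(params$W1), params$b1, as.vector(params$W2), params$b2)
}

#' Rebuild structured parameters from a flat slot vector
#'
#' Inverse of [flatten_params()].
#'
#' @param theta Numeric vector of length [n_param_slots()].
#' @param spec A [layer_spec()].
#' @return An `mlp_params` object.
#' @export
unflatten_params <- function(theta, spec) {
  stopifnot(inherits(spec, "layer_spec"))
  t <- spec$n_input; g <- spec$n_hidden; p <- spec$n_output
  if (length(theta) != n_param_slots(spec))
    stop("parameter vector length does not match layer_spec", call. = FALSE)
  if (!all(is.finite(theta)))
    stop("network parameters must be finite", call. = FALSE)
  i <- 0L
  W1 <- matrix(theta[i + seq_len(g * t)], g, t); i <- i + g * t
  b1 <- theta[i + seq_len(g)]; i <- i + g
  W2 <- matrix(theta[i + seq_len(p * g)], p, g); i <- i + p * g
  b2 <- theta[i + seq_len(p)]
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, spec = spec),
            class = "mlp_params")
}

#' Forward pass of the regression network
#'
#' Hidden activations are `sigmoid(W1 x + b1)`; the output layer is linear:
#' `W2 h + b2`. Accepts a single input vector or a matrix with one row per
#' observation.
#'
#' @param params An `mlp_params` object.
#' @param x Numeric vector of length `n_input`, or an `n x n_input` matrix.
#' @return For a vector input, a numeric vector of length `n_output`; for a
#'   matrix input, an `n x n_output` matrix of outputs.
#' @export
forward <- function(params, x) {
  stopifnot(inherits(params, "mlp_params"))
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != params$spec$n_input)
    stop("dimension error: input has ", ncol(X), " columns, network expects ",
         params$spec$n_input, call. = FALSE)
  H <- sigmoid(sweep(X %*% t(params$W1), 2L, params$b1, `+`))
  Y <- sweep(H %*% t(params$W2), 2L, params$b2, `+`)
  if (single) as.vector(Y) else Y
}

#' Mean squared error over a sample of vectors
#'
#' Mean over observations of the squared Euclidean distance between
#' prediction and target; for scalar outputs this is the ordinary MSE.
#'
#' @param predictions,targets Numeric vectors (scalar outputs) or matrices
#'   with one row per observation.
#' @return Nonnegative scalar.
#' @export
mse <- function(predictions, targets) {
  P <- if (is.null(dim(predictions))) matrix(predictions, ncol = 1L) else as.matrix(predictions)
  Tm <- if (is.null(dim(targets))) matrix(targets, ncol = 1L) else as.matrix(targets)
  if (nrow(P) == 0L) stop("empty data: no observations", call. = FALSE)
  if (!all(dim(P) == dim(Tm)))
    stop("dimension error: predictions and targets differ in shape", call. = FALSE)
  sum((P - Tm)^2) / nrow(P)
}

#' Analytic gradients of the batch MSE
#'
#' Exact gradients of [mse()] with respect to every weight and bias, obtained
#' by propagating the output error back through the linear output layer and
#' the sigmoid hidden layer.
#'
#' @param params An `mlp_params` object.
#' @param inputs `n x n_input` matrix.
#' @param targets `n x n_output` matrix (or vector for scalar output).
#' @return A list shaped like the parameters: `W1`, `b1`, `W2`, `b2`.
#' @export
backprop_gradients <- function(params, inputs, targets) {
  stopifnot(inherits(params, "mlp_params"))
  X <- as.matrix(inputs)
  Tm <- if (is.null(dim(targets))) matrix(targets, ncol = 1L) else as.matrix(targets)
  n <- nrow(X)
  if (n == 0L) stop("empty data: no observations", call. = FALSE)
  if (ncol(X) != params$spec$n_input || ncol(Tm) != params$spec$n_output ||
      nrow(Tm) != n)
    stop("dimension error: batch shapes do not match the network", call. = FALSE)
  H <- sigmoid(sweep(X %*% t(params$W1), 2L, params$b1, `+`))
  Y <- sweep(H %*% t(params$W2), 2L, params$b2, `+`)
  dY <- 2 * (Y - Tm) / n                       # d(mse)/dY
  dW2 <- t(dY) %*% H
  db2 <- colSums(dY)
  dH <- dY %*% params$W2
  dZ1 <- dH * H * (1 - H)
  dW1 <- t(dZ1) %*% X
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Train a network by full-batch backpropagation
#'
#' Gradient descent on the training MSE, full batch (the monitoring tables
#' are small), with an optional momentum term: `v <- momentum * v -
#' learning_rate * grad; w <- w + v`. Iterates until the training MSE falls
#' to `cfg$target_error` or `cfg$max_iterations` is reached. The returned
#' parameters are the best-so-far set along the run, so the reported error
#' never exceeds the starting error.
#'
#' @param params Initial `mlp_params` (e.g. from [init_network()] or the
#'   ant-colony search).
#' @param data A [monitoring_table()] normalised to \[0, 1\].
#' @param cfg A [bp_config()].
#' @return An object of class `train_result`: `params` (best-so-far),
#'   `error_trace` (data.frame with `iteration`, `mse`, `phase`),
#'   `best_mse`, `stop_reason` (`"target_reached"` or `"max_iterations"`)
#'   and `seed`.
#' @export
bp_train <- function(params, data, cfg = bp_config()) {
  stopifnot(inherits(params, "mlp_params"), inherits(cfg, "bp_config"))
  xy <- table_matrices(data)
  X <- xy$X; Tm <- xy$Y
  if (nrow(X) == 0L) stop("empty data: no observations", call. = FALSE)
  W1 <- params$W1; b1 <- params$b1; W2 <- params$W2; b2 <- params$b2
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
  lr <- cfg$learning_rate; mom <- cfg$momentum
  trace <- numeric(cfg$max_iterations + 1L)
  cur <- structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                        spec = params$spec), class = "mlp_params")
  err <- mse(forward(cur, X), Tm)
  trace[1L] <- err
  best_err <- err; best <- cur
  stop_reason <- "max_iterations"
  it <- 0L
  if (err <= cfg$target_error) {
    stop_reason <- "target_reached"
  } else {
    for (it in seq_len(cfg$max_iterations)) {
      H <- sigmoid(sweep(X %*% t(W1), 2L, b1, `+`))
      Y <- sweep(H %*% t(W2), 2L, b2, `+`)
      dY <- 2 * (Y - Tm) / nrow(X)
      dW2 <- t(dY) %*% H; db2 <- colSums(dY)
      dZ1 <- (dY %*% W2) * H * (1 - H)
      dW1 <- t(dZ1) %*% X; db1 <- colSums(dZ1)
      vW1 <- mom * vW1 - lr * dW1; W1 <- W1 + vW1
      vb1 <- mom * vb1 - lr * db1; b1 <- b1 + vb1
      vW2 <- mom * vW2 - lr * dW2; W2 <- W2 + vW2
      vb2 <- mom * vb2 - lr * db2; b2 <- b2 + vb2
      H <- sigmoid(sweep(X %*% t(W1), 2L, b1, `+`))
      Y <- sweep(H %*% t(W2), 2L, b2, `+`)
      err <- sum((Y - Tm)^2) / nrow(X)
      if (!is.finite(err) || err > 1e6)
        stop("divergence at iteration ", it,
             ": training MSE non-finite or above 1e6; reduce learning_rate",
             call. = FALSE)
      trace[it + 1L] <- err
      if (err < best_err) {
        best_err <- err
        best <- structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                               spec = params$spec), class = "mlp_params")
      }
      if (err <= cfg$target_error) { stop_reason <- "target_reached"; break }
    }
  }
  trace <- trace[seq_len(it + 1L)]
  structure(
    list(params = best, best_mse = best_err,
         error_trace = data.frame(iteration = seq_along(trace) - 1L,
                                  mse = trace, phase = "bp"),
         stop_reason = stop_reason, seed = cfg$seed),
    class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf(
    "<train_result> best training MSE %.6g after %d recorded iterations (%s)\n",
    x$best_mse, nrow(x$error_trace) - 1L, x$stop_reason))
  invisible(x)
}

#' Empirical hidden-layer sizing rules
#'
#' Three rules of thumb for the hidden node count `g` of a three-layer
#' network with `t` inputs and `p` outputs:
#' \describe{
#'   \item{`"sqrt_sum"`}{`g = round(sqrt(t + p)) + alpha`, with the additive
#'     constant `alpha` between 1 and 10 (the default rule).}
#'   \item{`"log2"`}{`g = ceiling(log2(t))`.}
#'   \item{`"geometric"`}{`g = round(sqrt(t * p))`.}
#' }
#' The literal variants `"sum_literal"` (`t + 1 + alpha`) and
#' `"product_literal"` (`t * p`) are also selectable.
#'
#' @param t Input node count (>= 1).
#' @param p Output node count (>= 1).
#' @param rule One of `"sqrt_sum"`, `"log2"`, `"geometric"`,
#'   `"sum_literal"`, `"product_literal"`.
#' @param alpha Additive constant in \[1, 10\] (used by the sum rules).
#' @return Integer hidden node count, at least 1.
#' @examples
#' hidden_node_count(8, 1, "log2")       # 3
#' hidden_node_count(8, 1, alpha = 4)    # round(sqrt(9)) + 4 = 7
#' @export
hidden_node_count <- function(t, p = 1L,
                              rule = c("sqrt_sum", "log2", "geometric",
                                       "sum_literal", "product_literal"),
                              alpha = 4L) {
  rule <- match.arg(rule)
  stopifnot(t >= 1, p >= 1)
  if (alpha < 1 || alpha > 10)
    stop("alpha must lie in [1, 10]", call. = FALSE)
  g <- switch(rule,
    sqrt_sum = round(sqrt(t + p)) + alpha,
    log2 = ceiling(log2(t)),
    geometric = round(sqrt(t * p)),
    sum_literal = t + 1 + alpha,
    product_literal = t * p)
  as.integer(max(1, g))
}
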