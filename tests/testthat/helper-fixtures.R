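# Shared fixtures, built in code.

# Small deterministic monitoring table on the normalised scale.
toy_table <- function(n = 20L, seed = 7L) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * 2L), n, 2L, dimnames = list(NULL, c("a", "b")))
    df <- as.data.frame(x)
    df$load_score <- 0.3 * df$a + 0.2  # linear, exactly representable
    monitoring_table(df, "load_score")
  })
}

# Random small network with finite weights.
random_net <- function(spec, seed, scale = 1) {
  init_network(spec, -scale, scale, seed = seed)
}

# Central finite-difference gradient of the batch MSE, slot by slot:
# the independent oracle for backprop_gradients.
fd_gradient <- function(params, X, Y, h = 1e-6) {
  theta <- flatten_params(params)
  vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    (mse(forward(unflatten_params(up, params$spec), X), Y) -
     mse(forward(unflatten_params(dn, params$spec), X), Y)) / (2 * h)
  }, numeric(1))
}

# Unit-square 4-city instance: optimal perimeter tour has length 4.
unit_square_tsp <- function() {
  xy <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2L, byrow = TRUE)
  tsp_instance(as.matrix(stats::dist(xy)))
}
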