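test_that("init_network draws uniformly on the interval, reproducibly", {
  spec <- layer_spec(2L, 3L, 1L)
  expect_error(init_network(spec, 0.2, 0.2), "invalid interval")
  a <- init_network(spec, -0.2, 0.2, seed = 7L)
  b <- init_network(spec, -0.2, 0.2, seed = 7L)
  expect_identical(flatten_params(a), flatten_params(b))
  expect_true(all(abs(flatten_params(a)) <= 0.2))
  expect_false(identical(flatten_params(a),
                         flatten_params(init_network(spec, -0.2, 0.2, seed = 8L))))
  expect_length(flatten_params(a), 3L * 3L + 1L * 4L)
})

test_that("forward pass matches explicit arithmetic", {
  spec <- layer_spec(2L, 3L, 1L)
  zero <- unflatten_params(rep(0, n_param_slots(spec)), spec)
  expect_equal(forward(zero, c(0.4, 0.9)), 0)

  # zero first layer, unit second-layer weights: output = sigmoid(0) * g
  theta <- rep(0, n_param_slots(spec))
  theta[10:12] <- 1                       # W2 slots of a 2-3-1 network
  half <- unflatten_params(theta, spec)
  expect_equal(forward(half, c(1, -1)), 0.5 * 3)

  # hand-set 1-1-1 chain, evaluated by independent arithmetic
  s111 <- layer_spec(1L, 1L, 1L)
  p <- unflatten_params(c(0.5, 0.1, 2, -0.3), s111)
  h <- 1 / (1 + exp(-(0.5 * 1 + 0.1)))
  expect_equal(forward(p, 1), 2 * h - 0.3, tolerance = 1e-14)

  expect_error(forward(p, c(1, 2)), "dimension")
})

test_that("mse equals the naive per-sample loop and is permutation invariant", {
  expect_equal(mse(c(1, 1), c(1, 1)), 0)
  expect_equal(mse(c(0, 1), c(1, 1)), 0.5)
  expect_error(mse(numeric(0), numeric(0)), "empty")
  withr::with_seed(11L, {
    P <- matrix(rnorm(30), 10, 3)
    Tm <- matrix(rnorm(30), 10, 3)
  })
  loop <- mean(sapply(1:10, function(i) sum((P[i, ] - Tm[i, ])^2)))
  expect_equal(mse(P, Tm), loop, tolerance = 1e-12)
  perm <- sample(10)
  expect_equal(mse(P[perm, ], Tm[perm, ]), mse(P, Tm))
})

test_that("analytic gradients match central finite differences", {
  specs <- list(layer_spec(2L, 3L, 1L), layer_spec(4L, 5L, 2L),
                layer_spec(1L, 1L, 1L))
  for (case in 1:30) {
    spec <- specs[[(case %% length(specs)) + 1L]]
    net <- random_net(spec, seed = case, scale = 1.5)
    withr::with_seed(1000L + case, {
      X <- matrix(runif(6L * spec$n_input), 6L, spec$n_input)
      Y <- matrix(runif(6L * spec$n_output), 6L, spec$n_output)
    })
    g <- backprop_gradients(net, X, Y)
    flat <- c(as.vector(g$W1), g$b1, as.vector(g$W2), g$b2)
    fd <- fd_gradient(net, X, Y)
    expect_lt(max(abs(flat - fd)) / max(abs(fd), 1e-8), 1e-5)
  }
})

test_that("gradients vanish at a perfect fit and ignore sample duplication", {
  spec <- layer_spec(2L, 2L, 1L)
  net <- random_net(spec, seed = 3L)
  X <- matrix(c(0.1, 0.9, 0.4, 0.2), 2L, 2L)
  Y <- forward(net, X)                   # targets equal predictions
  g <- backprop_gradients(net, X, Y)
  expect_equal(max(abs(unlist(g[c("W1", "b1", "W2", "b2")]))), 0)

  withr::with_seed(4L, Y2 <- matrix(runif(2), 2L, 1L))
  g1 <- backprop_gradients(net, X, Y2)
  g2 <- backprop_gradients(net, rbind(X, X), rbind(Y2, Y2))
  expect_equal(g1, g2, tolerance = 1e-14)
})

test_that("bp_train fits a linear toy problem and is deterministic", {
  tab <- toy_table()
  spec <- layer_spec(2L, 3L, 1L)
  net <- init_network(spec, -0.2, 0.2, seed = 5L)
  cfg <- bp_config(learning_rate = 0.5, momentum = 0.9,
                   max_iterations = 3000L, target_error = 1e-4, seed = 5L)
  res <- bp_train(net, tab, cfg)
  expect_s3_class(res, "train_result")
  expect_lt(res$best_mse, 1e-3)
  expect_true(res$stop_reason %in% c("target_reached", "max_iterations"))
  # best-so-far along the trace is non-increasing
  expect_true(all(diff(cummin(res$error_trace$mse)) <= 0))
  res2 <- bp_train(net, tab, cfg)
  expect_identical(res$error_trace, res2$error_trace)
  expect_error(bp_config(max_iterations = 0L), "max_iterations")
})

test_that("bp_train reports divergence with the iteration", {
  tab <- toy_table()
  net <- init_network(layer_spec(2L, 3L, 1L), -0.2, 0.2, seed = 1L)
  expect_error(
    bp_train(net, tab, bp_config(learning_rate = 500, max_iterations = 200L)),
    "divergence at iteration")
})

test_that("hidden-layer sizing rules follow their stated conventions", {
  expect_identical(hidden_node_count(8L, 1L, "log2"), 3L)
  expect_identical(hidden_node_count(4L, 1L, "geometric"), 2L)
  expect_identical(hidden_node_count(8L, 1L, "sqrt_sum", alpha = 4L), 7L)
  expect_identical(hidden_node_count(6L, 1L, "sum_literal", alpha = 4L), 11L)
  expect_identical(hidden_node_count(3L, 2L, "product_literal"), 6L)
  expect_error(hidden_node_count(8L, 1L, alpha = 11L), "alpha")
  expect_error(hidden_node_count(8L, 1L, alpha = 0L), "alpha")
})
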