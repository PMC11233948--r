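test_that("transition probabilities follow the tau^alpha * eta^beta rule", {
  # uniform pheromone over 50 candidates, no heuristic: uniform choice
  p <- transition_probabilities(rep(1, 50))
  expect_equal(p, rep(1 / 50, 50))

  expect_equal(transition_probabilities(c(3, 1), alpha = 1), c(0.75, 0.25))

  withr::with_seed(2L, {
    tau <- runif(8, 0.1, 2); eta <- runif(8, 0.1, 2)
  })
  allowed <- c(2L, 3L, 5L, 8L)
  p <- transition_probabilities(tau, eta, alpha = 1.3, beta = 2, allowed)
  # naive loop normalisation oracle
  w <- numeric(8)
  for (i in allowed) w[i] <- tau[i]^1.3 * eta[i]^2
  expect_equal(p, w / sum(w), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p[-allowed] == 0))

  expect_error(transition_probabilities(tau, allowed = integer(0)),
               "no feasible move")
})

test_that("roulette-wheel sampling matches its distribution", {
  expect_identical(withr::with_seed(1L, sample_component(c(1, 0))), 1L)
  draws <- withr::with_seed(99L,
    replicate(10000, sample_component(c(0.75, 0.25))))
  expect_lt(abs(mean(draws == 1L) - 0.75), 0.02)
  expect_identical(withr::with_seed(5L, replicate(20, sample_component(c(0.5, 0.5)))),
                   withr::with_seed(5L, replicate(20, sample_component(c(0.5, 0.5)))))
  expect_error(sample_component(c(0.5, NaN)), "invalid distribution")
  expect_error(sample_component(c(-0.2, 1.2)), "invalid distribution")
})

test_that("pheromone update evaporates, deposits, and stays bounded", {
  expect_equal(update_pheromones(1, 0, 0.5), 0.5)
  # two ants deposit 0.2 and 0.3 on one edge at evaporation 0.1
  expect_equal(update_pheromones(1, 0.2 + 0.3, 0.1), 0.9 + 0.5)
  expect_error(update_pheromones(1, 0.1, 0), "range error")
  expect_error(update_pheromones(1, 0.1, 1), "range error")
  # geometric-series bound: tau <= tau_0 + D / evaporation
  tau <- 1
  for (i in 1:200) tau <- update_pheromones(tau, 0.7, 0.25)
  expect_lte(tau, 1 + 0.7 / 0.25)
  expect_gt(tau, 0)
})

test_that("tour length sums consecutive distances including the return", {
  two <- tsp_instance(matrix(c(0, 5, 5, 0), 2))
  expect_equal(tour_length(two, c(1L, 2L)), 10)
  expect_equal(tour_length(unit_square_tsp(), 1:4), 4)
  inst <- withr::with_seed(3L, {
    xy <- matrix(runif(12), 6, 2)
    tsp_instance(as.matrix(stats::dist(xy)))
  })
  tour <- withr::with_seed(4L, sample(6L))
  loop <- sum(sapply(1:6, function(i)
    inst$distance[tour[i], tour[(i %% 6) + 1L]]))
  expect_equal(tour_length(inst, tour), loop)
  expect_error(tour_length(inst, c(1L, 1L, 2L, 3L, 4L, 5L)), "invalid tour")
})

test_that("brute force finds the global optimum on small instances", {
  expect_equal(brute_force_tsp(unit_square_tsp())$length, 4)
  tri <- tsp_instance(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3))
  opt <- brute_force_tsp(tri)
  expect_equal(opt$length, 12)           # any 3-city tour is the perimeter
  inst <- withr::with_seed(8L, {
    xy <- matrix(runif(14), 7, 2)
    tsp_instance(as.matrix(stats::dist(xy)))
  })
  opt <- brute_force_tsp(inst)
  expect_equal(tour_length(inst, opt$tour), opt$length)
  rnd <- withr::with_seed(9L, replicate(100, tour_length(inst, sample(7L))))
  expect_true(all(opt$length <= rnd + 1e-12))
  big <- tsp_instance(matrix(1, 11, 11) - diag(11))
  expect_error(brute_force_tsp(big), "size error")
})

test_that("ant-system TSP search is consistent, deterministic, monotone", {
  tri <- tsp_instance(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3))
  sol <- solve_tsp(tri, aco_config(n_ants = 5L, beta = 2, n_iterations = 5L,
                                   seed = 1L))
  expect_equal(sol$length, 12)           # all 3-city tours are optimal

  inst <- tsp_fixture6()
  cfg <- aco_config(n_ants = 10L, beta = 2, n_iterations = 30L, seed = 11L)
  a <- solve_tsp(inst, cfg)
  b <- solve_tsp(inst, cfg)
  expect_identical(a, b)
  expect_equal(a$length, tour_length(inst, a$tour))
  expect_true(all(diff(a$trace) <= 0))   # best-so-far is non-increasing
  expect_gte(a$length, brute_force_tsp(inst)$length - 1e-12)
})

test_that("run_colony solves a single-candidate problem trivially", {
  prob <- list(
    n_tau = 1L, n_steps = 1L,
    init_state = function() list(done = FALSE),
    allowed = function(state) list(choices = list(1L), tau_idx = 1L, eta = 1),
    advance = function(state, choice) list(done = TRUE),
    cost = function(state) 3.5)
  res <- run_colony(prob, aco_config(n_ants = 1L, n_iterations = 1L, seed = 1L))
  expect_equal(res$best$components, 1L)
  expect_equal(res$best$cost, 3.5)
})
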