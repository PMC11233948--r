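#' Ant-colony optimiser configuration
#'
#' Parameters of the basic ant system: colony size, the pheromone and
#' heuristic importance exponents, the per-cycle evaporation fraction, the
#' deposit constant `Q` (each ant deposits `Q / cost`), and the iteration
#' budget.
#'
#' @param n_ants Colony size (>= 1); default 30.
#' @param alpha Pheromone-importance exponent (>= 0).
#' @param beta Heuristic-importance exponent (>= 0); 0 gives the
#'   pure-pheromone selection rule used for weight search.
#' @param evaporation Fraction of pheromone lost per cycle, in (0, 1).
#' @param deposit_constant Positive `Q` in the ant-cycle deposit `Q / cost`.
#' @param n_iterations Number of colony cycles (>= 0; 0 disables the search).
#' @param seed Integer seed.
#' @return An object of class `aco_config`.
#' @export
aco_config <- function(n_ants = 30L, alpha = 1, beta = 0, evaporation = 0.5,
                       deposit_constant = 1, n_iterations = 50L, seed = 1L) {
  if (!is.finite(n_ants) || n_ants < 1)
    stop("n_ants must be >= 1", call. = FALSE)
  if (alpha < 0 || beta < 0)
    stop("alpha and beta must be >= 0", call. = FALSE)
  if (!is.finite(evaporation) || evaporation <= 0 || evaporation >= 1)
    stop("range error: evaporation must lie in (0, 1)", call. = FALSE)
  if (!is.finite(deposit_constant) || deposit_constant <= 0)
    stop("deposit_constant must be positive", call. = FALSE)
  if (!is.finite(n_iterations) || n_iterations < 0)
    stop("n_iterations must be >= 0", call. = FALSE)
  structure(
    list(n_ants = as.integer(n_ants), alpha = alpha, beta = beta,
         evaporation = evaporation, deposit_constant = deposit_constant,
         n_iterations = as.integer(n_iterations), seed = as.integer(seed)),
    class = "aco_config")
}

TAU_MIN <- 1e-9   # pheromone floor: keeps every component selectable

#' Ant-system transition probabilities
#'
#' Selection probability of each allowed component is proportional to
#' `tau^alpha * eta^beta`; components outside `allowed` get probability 0.
#' With `beta = 0` this is the pure-pheromone rule used when ants pick
#' discretised network weights.
#'
#' @param tau Pheromone levels (positive on `allowed`).
#' @param eta Heuristic desirabilities; `NULL` means no heuristic term.
#' @param alpha,beta Importance exponents.
#' @param allowed Integer indices of the feasible components; defaults to
#'   all of them.
#' @return Probability vector over all components (sums to 1).
#' @export
transition_probabilities <- function(tau, eta = NULL, alpha = 1, beta = 0,
                                     allowed = seq_along(tau)) {
  if (length(allowed) == 0L)
    stop("no feasible move: allowed set is empty", call. = FALSE)
  if (is.null(eta)) eta <- rep(1, length(tau))
  if (any(!is.finite(tau[allowed])) || any(tau[allowed] <= 0) ||
      any(!is.finite(eta[allowed])) || any(eta[allowed] <= 0))
    stop("tau and eta must be positive and finite on the allowed set",
         call. = FALSE)
  w <- numeric(length(tau))
  w[allowed] <- tau[allowed]^alpha * eta[allowed]^beta
  w / sum(w)
}

#' Roulette-wheel draw from a probability vector
#'
#' The random-ratio selection rule: one component index is drawn with the
#' given probabilities.
#'
#' @param probs Probability vector (nonnegative, summing to 1).
#' @return A single integer index.
#' @export
sample_component <- function(probs) {
  if (any(!is.finite(probs)) || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-8)
    stop("invalid distribution: probabilities must be nonnegative and sum to 1",
         call. = FALSE)
  sample.int(length(probs), 1L, prob = probs)
}

#' Evaporate and deposit pheromone
#'
#' One pheromone-update cycle: `tau' = (1 - evaporation) * tau + deposits`,
#' floored at a small positive minimum so no component becomes permanently
#' unreachable. `deposits` holds the summed contributions of all ants for
#' the cycle.
#'
#' @param tau Pheromone vector.
#' @param deposits Nonnegative vector of the same length (total deposit per
#'   component).
#' @param evaporation Evaporation fraction in (0, 1).
#' @return Updated pheromone vector.
#' @export
update_pheromones <- function(tau, deposits, evaporation) {
  if (!is.finite(evaporation) || evaporation <= 0 || evaporation >= 1)
    stop("range error: evaporation must lie in (0, 1)", call. = FALSE)
  if (length(deposits) != length(tau) || any(deposits < 0))
    stop("deposits must be nonnegative and match tau in length", call. = FALSE)
  pmax((1 - evaporation) * tau + deposits, TAU_MIN)
}

#' Run an ant colony on a generic construction problem
#'
#' Each cycle, every ant builds a complete solution step by step: at each
#' step the problem exposes the allowed components (with their pheromone
#' indices and heuristic values), the ant draws one by the transition rule,
#' and the problem advances its state. Completed solutions deposit pheromone
#' on the components they used in inverse proportion to their cost
#' (ant-cycle rule), normalised by the cycle's best cost:
#' `delta_tau = deposit_constant * c_best / cost`, so the cycle's best ant
#' deposits exactly `deposit_constant` and worse ants deposit less. The
#' normalisation keeps deposits on the order of the unit initial pheromone
#' whatever the cost scale (tour lengths and mean squared errors differ by
#' orders of magnitude), which preserves exploration; a raw `Q / cost`
#' deposit would either swamp or never touch the initial pheromone.
#' Evaporation is applied once per cycle. The incumbent (best-so-far)
#' solution and its per-cycle trace are returned.
#'
#' The problem interface is a list with fields `n_tau` (pheromone vector
#' length), `n_steps`, `init_state()`, `allowed(state)` (returns
#' `choices`, `tau_idx`, `eta`), `advance(state, choice)`, `cost(state)`.
#'
#' @param problem Construction-problem interface (see Details).
#' @param cfg An [aco_config()].
#' @return A list: `best` (class `ant_solution`: `components`, `cost`),
#'   `trace` (best-so-far cost per cycle, non-increasing), `pheromone`
#'   (final pheromone vector).
#' @export
run_colony <- function(problem, cfg) {
  stopifnot(inherits(cfg, "aco_config"))
  tau <- rep(1, problem$n_tau)          # uniform start: no path preferred
  best <- NULL
  trace <- numeric(cfg$n_iterations)
  withr::with_seed(cfg$seed, {
    for (cycle in seq_len(cfg$n_iterations)) {
      ants <- vector("list", cfg$n_ants)
      for (ant in seq_len(cfg$n_ants)) {
        state <- problem$init_state()
        comps <- vector("list", problem$n_steps)
        used <- integer(problem$n_steps)
        for (step in seq_len(problem$n_steps)) {
          opt <- problem$allowed(state)
          probs <- transition_probabilities(tau[opt$tau_idx], opt$eta,
                                            cfg$alpha, cfg$beta)
          pick <- sample_component(probs)
          comps[[step]] <- opt$choices[[pick]]
          used[step] <- opt$tau_idx[pick]
          state <- problem$advance(state, opt$choices[[pick]])
        }
        cost <- problem$cost(state)
        extra <- if (is.null(problem$extra_tau_idx)) integer(0)
                 else problem$extra_tau_idx(state)
        ants[[ant]] <- list(cost = cost, idx = c(used, extra),
                            comps = unlist(comps))
      }
      costs <- vapply(ants, `[[`, numeric(1), "cost")
      if (!any(is.finite(costs)))
        stop("search failure: no ant produced a finite cost in cycle ", cycle,
             call. = FALSE)
      c_best <- min(costs[is.finite(costs)])
      deposits <- numeric(problem$n_tau)
      for (a in ants) {
        if (!is.finite(a$cost)) next
        amount <- cfg$deposit_constant *
          if (a$cost == 0) 1 else c_best / a$cost
        deposits[a$idx] <- deposits[a$idx] + amount
        if (is.null(best) || a$cost < best$cost)
          best <- structure(list(components = a$comps, cost = a$cost),
                            class = "ant_solution")
      }
      tau <- update_pheromones(tau, deposits, cfg$evaporation)
      trace[cycle] <- best$cost
    }
  })
  list(best = best, trace = trace, pheromone = tau)
}

#' @export
print.ant_solution <- function(x, ...) {
  cat(sprintf("<ant_solution> cost %.6g, %d components\n",
              x$cost, length(x$components)))
  invisible(x)
}

#' Travelling-salesman instance from a distance matrix
#'
#' @param distance Symmetric nonnegative matrix with zero diagonal.
#' @return An object of class `tsp_instance`.
#' @export
tsp_instance <- function(distance) {
  d <- as.matrix(distance)
  if (nrow(d) != ncol(d) || any(d < 0) || any(diag(d) != 0) ||
      !isTRUE(all.equal(d, t(d))))
    stop("distance must be a symmetric nonnegative matrix with zero diagonal",
         call. = FALSE)
  structure(list(distance = unname(d), n_cities = nrow(d)),
            class = "tsp_instance")
}

#' Length of a closed tour
#'
#' Sum of consecutive inter-city distances including the return edge.
#'
#' @param instance A [tsp_instance()].
#' @param tour Permutation of `1:n_cities`.
#' @return Tour length.
#' @export
tour_length <- function(instance, tour) {
  stopifnot(inherits(instance, "tsp_instance"))
  n <- instance$n_cities
  if (length(tour) != n || !setequal(tour, seq_len(n)))
    stop("invalid tour: not a permutation of the cities", call. = FALSE)
  nxt <- c(tour[-1L], tour[1L])
  sum(instance$distance[cbind(tour, nxt)])
}

# All permutations of a vector (small n only).
permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}

#' Exhaustive travelling-salesman solver
#'
#' Enumerates all tours with city 1 fixed first (closed tours are rotation
#' invariant) and returns a global optimum. Intended as an oracle for small
#' instances.
#'
#' @param instance A [tsp_instance()] with at most 10 cities.
#' @return List with `tour` (optimal permutation) and `length`.
#' @export
brute_force_tsp <- function(instance) {
  stopifnot(inherits(instance, "tsp_instance"))
  n <- instance$n_cities
  if (n > 10L) stop("size error: brute force limited to 10 cities", call. = FALSE)
  if (n == 1L) return(list(tour = 1L, length = 0))
  best_tour <- NULL; best_len <- Inf
  for (p in permutations_of(seq_len(n)[-1L])) {
    tour <- c(1L, p)
    len <- tour_length(instance, tour)
    if (len < best_len) { best_len <- len; best_tour <- tour }
  }
  list(tour = best_tour, length = best_len)
}

# run_colony problem interface for a TSP: pheromone per directed edge,
# heuristic visibility 1/distance, tabu list of visited cities.
tsp_problem <- function(instance) {
  n <- instance$n_cities
  d <- instance$distance
  list(
    n_tau = n * n,
    n_steps = n - 1L,
    init_state = function() {
      start <- sample.int(n, 1L)
      list(tour = start, visited = start)
    },
    allowed = function(state) {
      cur <- state$tour[length(state$tour)]
      cand <- setdiff(seq_len(n), state$visited)
      list(choices = as.list(cand),
           tau_idx = (cand - 1L) * n + cur,     # edge (cur -> cand)
           eta = 1 / pmax(d[cur, cand], .Machine$double.eps))
    },
    advance = function(state, choice) {
      list(tour = c(state$tour, choice), visited = c(state$visited, choice))
    },
    cost = function(state) tour_length(instance, state$tour),
    # deposit also on the reverse edges and the closing edge (symmetric TSP)
    extra_tau_idx = function(state) {
      tour <- state$tour
      nxt <- c(tour[-1L], tour[1L])
      c((tour - 1L) * n + nxt,                       # reverse edges
        (nxt[length(nxt)] - 1L) * n + tour[length(tour)])
    }
  )
}

#' Solve a travelling-salesman instance with the ant system
#'
#' Specialises [run_colony()] with a tabu list (each city visited once),
#' heuristic visibility `1/distance`, and pheromone per directed edge. The
#' components of the returned solution are the tour after the ant's start
#' city; `tour` in the result carries the full closed tour.
#'
#' @param instance A [tsp_instance()].
#' @param cfg An [aco_config()]; `beta = 2` is a sensible visibility weight.
#' @return List with `tour`, `length`, and the best-so-far `trace`.
#' @export
solve_tsp <- function(instance, cfg = aco_config(beta = 2)) {
  stopifnot(inherits(instance, "tsp_instance"))
  prob <- tsp_problem(instance)
  res <- run_colony(prob, cfg)
  # reconstruct full tour: run_colony components exclude the start city,
  # which is the one city missing from them
  comps <- res$best$components
  start <- setdiff(seq_len(instance$n_cities), comps)
  list(tour = c(start, comps), length = res$best$cost, trace = res$trace)
}

#' Six-city benchmark instance
#'
#' A fixed planar instance with documented coordinates, small enough for
#' the exhaustive oracle: (0,0), (4,0), (5,3), (2,5), (-1,4), (1,2).
#'
#' @return A [tsp_instance()].
#' @export
tsp_fixture6 <- function() {
  xy <- matrix(c(0, 0, 4, 0, 5, 3, 2, 5, -1, 4, 1, 2),
               ncol = 2L, byrow = TRUE)
  tsp_instance(as.matrix(stats::dist(xy)))
}
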