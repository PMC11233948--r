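#' Discretise the weight interval into per-slot candidate sets
#'
#' Each of the network's parameter slots (weights and biases alike) gets the
#' same evenly spaced candidate set on `[lo, hi]`, endpoints included, with
#' spacing `(hi - lo) / (k - 1)`. The default divides the `[-3, 3]`
#' domain into 50 candidates. The quantisation error this introduces is what
#' the backpropagation fine-tuning phase corrects.
#'
#' @param spec A [layer_spec()].
#' @param lo,hi Interval bounds, `lo < hi`.
#' @param k Number of candidates per slot (>= 2; `k = 1` is allowed as the
#'   degenerate midpoint-only grid used to disable the search).
#' @return An object of class `weight_grid`: `n_slots`, `lo`, `hi`, `k`,
#'   `values` (candidate vector shared by all slots), `spec`.
#' @export
discretize_weights <- function(spec, lo = -3, hi = 3, k = 50L) {
  stopifnot(inherits(spec, "layer_spec"))
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("range error: require lo < hi", call. = FALSE)
  if (k < 1) stop("range error: k must be >= 1", call. = FALSE)
  values <- if (k == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = k)
  structure(
    list(n_slots = n_param_slots(spec), lo = lo, hi = hi, k = as.integer(k),
         values = values, spec = spec),
    class = "weight_grid")
}

#' @export
print.weight_grid <- function(x, ...) {
  cat(sprintf("<weight_grid> %d slots x %d candidates on [%g, %g]\n",
              x$n_slots, x$k, x$lo, x$hi))
  invisible(x)
}

# run_colony problem: one decision step per parameter slot, candidates are
# the grid values, pheromone table is n_slots x k, cost is training MSE.
weight_search_problem <- function(grid, X, Y) {
  k <- grid$k
  list(
    n_tau = grid$n_slots * k,
    n_steps = grid$n_slots,
    init_state = function() list(slot = 0L, theta = numeric(grid$n_slots)),
    allowed = function(state) {
      q <- state$slot + 1L
      list(choices = as.list(seq_len(k)),
           tau_idx = (q - 1L) * k + seq_len(k),
           eta = rep(1, k))
    },
    advance = function(state, choice) {
      state$slot <- state$slot + 1L
      state$theta[state$slot] <- grid$values[choice]
      state
    },
    cost = function(state) {
      params <- unflatten_params(state$theta, grid$spec)
      mse(forward(params, X), Y)
    }
  )
}

#' Ant-colony search over the discretised weight space
#'
#' Every ant selects one candidate value per parameter slot using the
#' pure-pheromone transition rule (uniform pheromone at the start, so the
#' first cycle samples each candidate with probability `1/k`). The assembled
#' network is scored by training MSE and each ant deposits `Q / MSE` on the
#' (slot, candidate) pairs it chose; evaporation follows once per cycle.
#'
#' Deposits follow [run_colony()]'s cost-relative ant-cycle rule, so the
#' candidate values of low-error networks are reinforced most.
#'
#' @param grid A [weight_grid()].
#' @param data Normalised training [monitoring_table()].
#' @param cfg An [aco_config()]; `beta` is forced to 0 (no heuristic term in
#'   the weight-selection rule).
#' @return List: `theta` (best flat weight vector), `best_mse`, `trace`
#'   (best-so-far MSE per cycle), `pheromone` (final slot-by-candidate
#'   matrix).
#' @export
aco_weight_search <- function(grid, data, cfg = aco_config()) {
  stopifnot(inherits(grid, "weight_grid"), inherits(cfg, "aco_config"))
  xy <- table_matrices(data)
  if (ncol(xy$X) != grid$spec$n_input)
    stop("dimension error: data features do not match the grid's layer_spec",
         call. = FALSE)
  if (cfg$beta != 0) cfg$beta <- 0
  if (grid$k == 1L || cfg$n_iterations == 0L) {
    # degenerate grid or disabled search: the single representable network
    theta <- rep(grid$values[1L], grid$n_slots)
    if (grid$k > 1L) theta <- rep((grid$lo + grid$hi) / 2, grid$n_slots)
    best <- mse(forward(unflatten_params(theta, grid$spec), xy$X), xy$Y)
    return(list(theta = theta, best_mse = best, trace = best,
                pheromone = matrix(1, grid$n_slots, grid$k)))
  }
  prob <- weight_search_problem(grid, xy$X, xy$Y)
  res <- run_colony(prob, cfg)
  theta <- grid$values[res$best$components]
  list(theta = theta, best_mse = res$best$cost, trace = res$trace,
       pheromone = matrix(res$pheromone, grid$n_slots, grid$k, byrow = TRUE))
}

#' Combined configuration for the hybrid trainer
#'
#' Bundles the network architecture, the candidate grid, the ant-colony
#' settings and the backpropagation settings. Defaults: 30 ants, weight interval `[-3, 3]` divided into 50, stopping
#' threshold 0.004, iteration cap 13000.
#'
#' @param spec A [layer_spec()].
#' @param lo,hi,k Candidate-grid interval and resolution
#'   (see [discretize_weights()]).
#' @param aco An [aco_config()].
#' @param bp A [bp_config()]; the hybrid's fine-tuning phase defaults to the
#'   momentum update (`momentum = 0.9`), which copes better with the
#'   saturated hidden units a coarse-grid start can produce.
#' @return An object of class `acobp_config`.
#' @export
acobp_config <- function(spec, lo = -3, hi = 3, k = 50L,
                         aco = aco_config(), bp = bp_config(momentum = 0.9)) {
  stopifnot(inherits(spec, "layer_spec"), inherits(aco, "aco_config"),
            inherits(bp, "bp_config"))
  structure(
    list(spec = spec, grid = discretize_weights(spec, lo, hi, k),
         aco = aco, bp = bp),
    class = "acobp_config")
}

#' Train a network by ant-colony search plus backpropagation fine-tuning
#'
#' The headline hybrid: the ant colony searches the discretised weight
#' space for a good initial weight vector (global, gradient-free), then
#' backpropagation fine-tunes from that start until the target error or the
#' iteration cap. With `aco$n_iterations = 0` the method degenerates to
#' plain backpropagation from the grid-midpoint initialisation.
#'
#' @param data_train Normalised training [monitoring_table()].
#' @param data_val Normalised validation/test [monitoring_table()] used to
#'   report generalisation (not for stopping).
#' @param cfg An [acobp_config()].
#' @return A `train_result` whose `error_trace` carries both phases
#'   (`phase` column `"aco"` then `"bp"`), plus `aco_best_mse`, `val_mse`
#'   and `theta_init` (the ant-chosen start).
#' @export
train_aco_bp <- function(data_train, data_val, cfg) {
  stopifnot(inherits(cfg, "acobp_config"))
  if (nrow(data_train) == 0L || nrow(data_val) == 0L)
    stop("empty data: both tables must be non-empty", call. = FALSE)
  search <- aco_weight_search(cfg$grid, data_train, cfg$aco)
  init <- unflatten_params(search$theta, cfg$spec)
  fit <- bp_train(init, data_train, cfg$bp)
  aco_trace <- if (length(search$trace))
    data.frame(iteration = seq_along(search$trace), mse = search$trace,
               phase = "aco")
  else NULL
  fit$error_trace <- rbind(aco_trace, fit$error_trace)
  fit$aco_best_mse <- search$best_mse
  fit$theta_init <- search$theta
  xy <- table_matrices(data_val)
  fit$val_mse <- mse(forward(fit$params, xy$X), xy$Y)
  fit$seed <- cfg$aco$seed
  fit
}
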