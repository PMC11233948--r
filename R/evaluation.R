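#' Compare trainers at iteration checkpoints
#'
#' Runs each trainer `n_replicates` times with derived seeds and reports the
#' mean best-so-far training MSE at each backpropagation-iteration
#' checkpoint -- the familiar "MSE at I = 200 / 600 / 800" comparison
#' format. Best-so-far reporting makes the columns monotone non-increasing;
#' the raw traces remain available from the individual results.
#'
#' A trainer is either a [bp_config()] (plain or momentum backpropagation,
#' started from a uniform `[-0.2, 0.2]` initialisation) or an
#' [acobp_config()] (ant-colony search then fine-tuning). Checkpoints count
#' backpropagation iterations; the ant-colony phase runs within its own
#' budget before iteration 0.
#'
#' @param data Normalised training [monitoring_table()].
#' @param trainers Named list of trainer configurations.
#' @param spec A [layer_spec()] used for the plain-backpropagation
#'   initialisation.
#' @param checkpoints Increasing iteration counts, all within every
#'   trainer's `max_iterations` budget.
#' @param n_replicates Replicates per trainer (>= 1).
#' @param seed Integer seed; replicate `r` of every trainer uses
#'   `seed + r` so the comparison is paired.
#' @return A data.frame of class `comparison_report`: `trainer`,
#'   `checkpoint`, `mean_mse`, `n_replicates`, plus a `seeds` attribute.
#' @export
compare_trainers <- function(data, trainers, spec,
                             checkpoints = c(200L, 600L, 800L),
                             n_replicates = 1L, seed = 1L) {
  stopifnot(is.list(trainers), length(names(trainers)) == length(trainers),
            inherits(spec, "layer_spec"))
  checkpoints <- sort(as.integer(checkpoints))
  for (tr in trainers) {
    budget <- if (inherits(tr, "acobp_config")) tr$bp$max_iterations
              else tr$max_iterations
    if (max(checkpoints) > budget)
      stop("range error: checkpoint beyond a trainer's iteration budget",
           call. = FALSE)
  }
  seeds <- seed + seq_len(n_replicates)
  acc <- matrix(0, length(trainers), length(checkpoints),
                dimnames = list(names(trainers), NULL))
  for (r in seq_len(n_replicates)) {
    for (nm in names(trainers)) {
      tr <- trainers[[nm]]
      res <- if (inherits(tr, "acobp_config")) {
        tr$aco$seed <- seeds[r]; tr$bp$seed <- seeds[r]
        train_aco_bp(data, data, tr)
      } else {
        init <- init_network(spec, -0.2, 0.2, seed = seeds[r])
        tr$seed <- seeds[r]
        bp_train(init, data, tr)
      }
      bp_trace <- res$error_trace[res$error_trace$phase == "bp", ]
      best <- cummin(bp_trace$mse)
      # trace may stop early at the target; later checkpoints keep the
      # final best-so-far value
      at <- pmin(checkpoints + 1L, length(best))
      acc[nm, ] <- acc[nm, ] + best[at]
    }
  }
  rep <- data.frame(
    trainer = rep(names(trainers), each = length(checkpoints)),
    checkpoint = rep(checkpoints, times = length(trainers)),
    mean_mse = as.vector(t(acc / n_replicates)),
    n_replicates = n_replicates)
  attr(rep, "seeds") <- seeds
  class(rep) <- c("comparison_report", "data.frame")
  rep
}

#' Per-sample prediction report on both scales
#'
#' Forward-passes the test table, reports normalised outputs with signed
#' errors (`error = prediction - target`), and inverts the scaler to give
#' point predictions on the original load scale.
#'
#' @param result A `train_result`.
#' @param test Normalised test [monitoring_table()].
#' @param scaler The `minmax_scaler` fitted on the training data.
#' @return A list: `samples` (data.frame with `output`, `target`, `error`,
#'   `predicted_load`, `actual_load`, `load_error`) and `max_abs_error`
#'   (normalised scale).
#' @export
prediction_report <- function(result, test, scaler) {
  stopifnot(inherits(result, "train_result"),
            inherits(test, "monitoring_table"),
            inherits(scaler, "minmax_scaler"))
  if (nrow(test) == 0L) stop("empty data: test table has no rows", call. = FALSE)
  tg <- target_column(test)
  if (!tg %in% names(scaler$min))
    stop("schema error: scaler lacks the target column", call. = FALSE)
  xy <- table_matrices(test)
  out <- as.vector(forward(result$params, xy$X))
  err <- out - as.vector(xy$Y)
  samples <- data.frame(
    sample = seq_along(out),
    output = out,
    target = as.vector(xy$Y),
    error = err,
    predicted_load = denormalize(out, scaler, tg),
    actual_load = denormalize(as.vector(xy$Y), scaler, tg))
  samples$load_error <- samples$predicted_load - samples$actual_load
  list(samples = samples, max_abs_error = max(abs(err)))
}

#' Per-parameter significance testing of trainer settings
#'
#' For each named parameter, the objective is evaluated `n_replicates`
#' times at a low and a high setting (all other settings fixed at the
#' base configuration) and the two groups are compared with Welch's
#' two-sample t-test at the given significance level; a parameter is
#' declared significant when `p < level`. Degenerate groups (zero variance
#' in both, equal means) report `p = 1` rather than an error.
#'
#' @param base_config Named list (or config object) of baseline settings.
#' @param param_grid Named list; each element is a length-2 vector
#'   `c(low, high)` of settings for that parameter.
#' @param objective Function `(config, seed) -> numeric` returning the
#'   outcome (e.g. final test MSE) for one replicate. `config` is
#'   `base_config` with the one parameter overridden.
#' @param n_replicates Replicates per setting (>= 2).
#' @param level Significance level in (0, 1), default 0.05.
#' @param seed Integer seed; replicate seeds are derived from it.
#' @return A data.frame of class `significance_report`: `parameter`,
#'   `p_value`, `level`, `significant`, `mean_low`, `mean_high`.
#' @export
parameter_significance <- function(base_config, param_grid, objective,
                                   n_replicates = 10L, level = 0.05,
                                   seed = 1L) {
  stopifnot(is.list(param_grid), length(names(param_grid)) == length(param_grid),
            n_replicates >= 2, level > 0, level < 1)
  base <- as.list(base_config)
  rows <- lapply(seq_along(param_grid), function(i) {
    par <- names(param_grid)[i]
    settings <- param_grid[[i]]
    stopifnot(length(settings) == 2L)
    grp <- lapply(1:2, function(s) {
      cfg <- base
      cfg[[par]] <- settings[[s]]
      vapply(seq_len(n_replicates), function(r)
        objective(cfg, seed + (i - 1L) * 2L * n_replicates +
                         (s - 1L) * n_replicates + r),
        numeric(1))
    })
    p <- if (stats::sd(grp[[1]]) == 0 && stats::sd(grp[[2]]) == 0) {
      if (mean(grp[[1]]) == mean(grp[[2]])) 1 else 0
    } else {
      stats::t.test(grp[[1]], grp[[2]], var.equal = FALSE)$p.value
    }
    data.frame(parameter = par, p_value = p, level = level,
               significant = p < level,
               mean_low = mean(grp[[1]]), mean_high = mean(grp[[2]]))
  })
  rep <- do.call(rbind, rows)
  class(rep) <- c("significance_report", "data.frame")
  rep
}

#' Cheap surrogate objective for harness calibration
#'
#' Evaluates the training MSE of a small fixed network on a freshly
#' generated noisy panel -- inexpensive but genuinely stochastic, which
#' makes it suitable for checking the significance harness's false-positive
#' rate under the null (where the tested setting does not enter the
#' objective at all).
#'
#' @param config Ignored except for an optional `bias` entry added to the
#'   outcome (used to plant a true effect when validating power).
#' @param seed Integer seed for the replicate.
#' @return A single numeric outcome.
#' @export
surrogate_objective <- function(config, seed) {
  cfg <- generator_config(n_rows = 10L, noise_sd = 0.05, missing_rate = 0,
                          seed = seed)
  panel <- generate_athlete_panel(cfg)
  norm <- normalize_table(panel)
  xy <- table_matrices(norm$table)
  net <- init_network(layer_spec(cfg$n_features, 3L, 1L), -0.5, 0.5,
                      seed = 1L)
  bias <- if (!is.null(config$bias)) config$bias else 0
  mse(forward(net, xy$X), xy$Y) + bias
}
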