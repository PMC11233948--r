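#' Synthetic-panel generator configuration
#'
#' Emulates the shape of a small athlete-monitoring campaign: 154 records, a
#' handful of numeric blood/training indicators, a smooth nonlinear
#' indicator-to-load relationship plus noise, occasional missing cells, and
#' a load score on roughly the 8.5-10 scale.
#'
#' @param n_rows Number of records (default 154).
#' @param n_features Number of indicator columns (default 6, >= 5; the
#'   sixth and any later columns are deliberate nuisance features that do
#'   not influence the load).
#' @param noise_sd Standard deviation of Gaussian noise added to the latent
#'   load on the \[0, 1\] scale (>= 0).
#' @param missing_rate Fraction of feature cells set missing, in \[0, 1).
#' @param target_scale Length-2 `(low, high)` range the \[0, 1\] load is
#'   mapped onto (default `c(8.5, 10)`).
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_rows = 154L, n_features = 6L, noise_sd = 0.02,
                             missing_rate = 0.02,
                             target_scale = c(8.5, 10), seed = 42L) {
  if (n_rows < 1) stop("n_rows must be >= 1", call. = FALSE)
  if (n_features < 5) stop("n_features must be >= 5", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (length(target_scale) != 2L || target_scale[1] >= target_scale[2])
    stop("target_scale must be (low, high) with low < high", call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_features = as.integer(n_features),
         noise_sd = noise_sd, missing_rate = missing_rate,
         target_scale = target_scale, seed = as.integer(seed)),
    class = "generator_config")
}

#' Latent indicator-to-load relationship
#'
#' The pinned closed form behind the generator, mapping the unit feature
#' cube to a \[0, 1\] load:
#' `f = 0.3 * sigmoid(4 (x1 - 0.5)) + 0.3 * x2 * x3 + 0.1 * sin(pi * x4) +
#' 0.2 * x5`, clipped to \[0, 1\]. Smooth and nonlinear (so a three-layer
#' network can fit it), and invariant to `x6` onwards -- nuisance features
#' included so feature selection and the significance harness have
#' signal-versus-noise structure to detect.
#'
#' @param features Numeric vector in `[0,1]^d` (`d >= 5`) or a matrix with
#'   one such row per observation.
#' @return Load value(s) in \[0, 1\].
#' @export
latent_load_function <- function(features) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1L)
       else as.matrix(features)
  if (ncol(X) < 5L)
    stop("dimension error: need at least 5 features", call. = FALSE)
  f <- 0.3 * sigmoid(4 * (X[, 1] - 0.5)) + 0.3 * X[, 2] * X[, 3] +
       0.1 * sin(pi * X[, 4]) + 0.2 * X[, 5]
  unname(pmin(pmax(f, 0), 1))
}

#' Generate a synthetic athlete-monitoring panel
#'
#' Indicator columns are i.i.d. uniform on \[0, 1\]; the load target is the
#' latent relationship plus Gaussian noise, affinely mapped onto
#' `target_scale`; missing values are injected uniformly over feature cells
#' at `missing_rate`. Fully reproducible for a fixed seed.
#'
#' @param cfg A [generator_config()].
#' @return A [monitoring_table()] with columns `heart_rate`,
#'   `blood_lactate`, `blood_urea`, `urine_protein`, `training_volume`,
#'   `creatine_kinase`, ... (generic names past six) and target
#'   `load_score`.
#' @export
generate_athlete_panel <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  base_names <- c("heart_rate", "blood_lactate", "blood_urea",
                  "urine_protein", "training_volume", "creatine_kinase")
  nm <- if (cfg$n_features <= 6L) base_names[seq_len(cfg$n_features)]
        else c(base_names, paste0("indicator_", seq_len(cfg$n_features - 6L)))
  withr::with_seed(cfg$seed, {
    X <- matrix(stats::runif(cfg$n_rows * cfg$n_features),
                cfg$n_rows, cfg$n_features, dimnames = list(NULL, nm))
    latent <- latent_load_function(X) +
      stats::rnorm(cfg$n_rows, sd = cfg$noise_sd)
    lo <- cfg$target_scale[1]; hi <- cfg$target_scale[2]
    target <- lo + (hi - lo) * latent
    Xm <- X
    if (cfg$missing_rate > 0) {
      miss <- stats::runif(length(Xm)) < cfg$missing_rate
      Xm[miss] <- NA_real_
    }
    df <- as.data.frame(Xm)
    df$load_score <- target
    monitoring_table(df, "load_score")
  })
}
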