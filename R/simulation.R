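# Synthetic group-structured data generator and the simulation benchmark
# harness.

#' Simulation configuration for group-structured designs
#'
#' Describes the data-generating process: rows of `X` are zero-mean
#' Gaussian with unit variances and correlation `rho` between any two
#' columns of the same group (and zero across groups) under the default
#' `"within_group"` scheme, or `rho` between every pair of columns under
#' `"global_equicorrelated"`; `y = X beta + eps` with
#' `eps ~ N(0, sigma2)`. The default coefficient pattern sets every
#' coefficient in odd-numbered groups to 1 and the rest to 0.
#'
#' @param n Training sample size.
#' @param p Number of predictors (divisible by `group_size` for the
#'   built-in pattern).
#' @param group_size Variables per group (default 20).
#' @param rho Within-correlation in `[0, 1)` (default 0.5).
#' @param sigma2 Noise variance (default 10).
#' @param beta_pattern `"alternating_groups"` or a custom length-`p`
#'   numeric vector.
#' @param correlation_scheme `"within_group"` or `"global_equicorrelated"`.
#' @param n_test Test sample size (default `n`).
#' @param seed Integer seed.
#' @return A `"simulation_config"` list.
#' @export
simulation_config <- function(n = 200, p = 500, group_size = 20, rho = 0.5,
                              sigma2 = 10,
                              beta_pattern = "alternating_groups",
                              correlation_scheme = c("within_group",
                                                     "global_equicorrelated"),
                              n_test = n, seed = 1) {
  correlation_scheme <- match.arg(correlation_scheme)
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)")
  if (sigma2 < 0) stop("'sigma2' must be nonnegative")
  if (is.character(beta_pattern)) {
    beta_pattern <- match.arg(beta_pattern, "alternating_groups")
    if (p %% group_size != 0)
      stop("'p' must be divisible by 'group_size' for the built-in pattern")
  } else if (length(beta_pattern) != p) {
    stop("custom 'beta_pattern' must have length p")
  }
  structure(
    list(n = n, p = p, group_size = group_size, G = p %/% group_size,
         rho = rho, sigma2 = sigma2, beta_pattern = beta_pattern,
         correlation_scheme = correlation_scheme, n_test = n_test,
         seed = seed),
    class = "simulation_config")
}

#' Preset simulation configurations
#'
#' Named designs used throughout the package's simulation study:
#' `"example1"`-`"example4"` are the small-sample designs (`n = 200`,
#' `p = 500/1000/1500/2000` in groups of 20) and `"table7_n500"` ...
#' `"table7_n2000"` the large-sample designs (`p = 100` in 5 groups of 20,
#' `n = 500/1000/1500/2000`). All use `rho = 0.5`, `sigma2 = 10`, and the
#' alternating all-ones/all-zeros group pattern.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A `"simulation_config"`.
#' @export
sim_preset <- function(name, seed = 1) {
  presets <- list(
    example1 = list(n = 200, p = 500), example2 = list(n = 200, p = 1000),
    example3 = list(n = 200, p = 1500), example4 = list(n = 200, p = 2000),
    table7_n500 = list(n = 500, p = 100),
    table7_n1000 = list(n = 1000, p = 100),
    table7_n1500 = list(n = 1500, p = 100),
    table7_n2000 = list(n = 2000, p = 100))
  name <- match.arg(name, names(presets))
  ps <- presets[[name]]
  simulation_config(n = ps$n, p = ps$p, seed = seed)
}

sim_true_beta <- function(config) {
  if (is.numeric(config$beta_pattern)) return(config$beta_pattern)
  grp <- rep(seq_len(config$G), each = config$group_size)
  as.numeric(grp %% 2 == 1)
}

draw_X <- function(nr, config) {
  p <- config$p
  G <- config$G
  rho <- config$rho
  if (config$correlation_scheme == "within_group") {
    U <- matrix(rnorm(nr * G), nr, G)
    shared <- U[, rep(seq_len(G), each = config$group_size), drop = FALSE]
  } else {
    shared <- matrix(rnorm(nr), nr, p)
  }
  sqrt(rho) * shared + sqrt(1 - rho) * matrix(rnorm(nr * p), nr, p)
}

#' Simulate a grouped regression data set
#'
#' Draws an independent training and test set from the configured law. The
#' random stream is seeded once from `config$seed` and consumed in a fixed
#' order (training X, training noise, test X, test noise), so results are
#' fully reproducible and the test set shares no draws with the training
#' set.
#'
#' @param config A [simulation_config()].
#' @return A list with `train` and `test` ([grouped_design()] objects) and
#'   `true_beta`.
#' @export
simulate_grouped <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  beta <- sim_true_beta(config)
  grp <- rep(seq_len(config$G), each = config$group_size)
  cn <- paste0("V", seq_len(config$p))
  sd_eps <- sqrt(config$sigma2)
  with_seed(config$seed, {
    Xtr <- draw_X(config$n, config)
    ytr <- as.numeric(Xtr %*% beta) + rnorm(config$n, 0, sd_eps)
    Xte <- draw_X(config$n_test, config)
    yte <- as.numeric(Xte %*% beta) + rnorm(config$n_test, 0, sd_eps)
  })
  colnames(Xtr) <- cn
  colnames(Xte) <- cn
  list(train = grouped_design(Xtr, ytr, grp, cn),
       test = grouped_design(Xte, yte, grp, cn),
       true_beta = beta)
}

BENCHMARK_METHODS <- c("grsubset_ridge", "grsubset_grlasso", "grlasso",
                       "grmcp", "grscad", "lasso", "mcp", "scad", "enet",
                       "alasso", "stacking")

# Fit one benchmark method on a training design; returns a predictor.
fit_benchmark_method <- function(train, method, seed, K = 5, nlambda = 100,
                                 n_secondary = NULL, tol = 1e-5, ...) {
  if (method == "stacking") {
    fit_stacking(train, K = K, seed = seed, nlambda = nlambda,
                 n_secondary = n_secondary, tol = tol, ...)
  } else {
    cv <- cross_validate(train, method, K = K, seed = seed,
                         nlambda = nlambda, n_secondary = n_secondary,
                         tol = tol)
    cv$best_fit
  }
}

#' Run a simulation benchmark
#'
#' For each configuration and replicate, simulates independent training and
#' test data, fits each method on the training set (tuning by K-fold CV;
#' the stacking ensemble with its default base learners), and records
#' test-set R-squared, RMSE, and MAE. Replicate `r` of a configuration uses
#' seed `config$seed + r - 1`. The summary table reports per-method means
#' and Monte Carlo standard errors.
#'
#' @param configs A [simulation_config()] or list of them.
#' @param methods Character vector drawn from `grsubset_ridge`,
#'   `grsubset_grlasso`, `grlasso`, `grmcp`, `grscad`, `lasso`, `mcp`,
#'   `scad`, `enet`, `alasso`, `stacking`.
#' @param replicates Number of replicates per configuration.
#' @param K,nlambda,n_secondary,tol Tuning controls passed through.
#' @return A `"benchmark_result"` list with `results` (one row per
#'   config/method/replicate; failures recorded as `NA`) and `summary`
#'   (means and standard errors).
#' @export
run_benchmark <- function(configs, methods = BENCHMARK_METHODS,
                          replicates = 1, K = 5, nlambda = 100,
                          n_secondary = NULL, tol = 1e-5) {
  if (inherits(configs, "simulation_config")) configs <- list(configs)
  methods <- match.arg(methods, BENCHMARK_METHODS, several.ok = TRUE)
  rows <- list()
  for (ci in seq_along(configs)) {
    config <- configs[[ci]]
    for (r in seq_len(replicates)) {
      rc <- config
      rc$seed <- config$seed + r - 1
      data <- simulate_grouped(rc)
      for (m in methods) {
        fit <- tryCatch(
          suppressWarnings(
            fit_benchmark_method(data$train, m, seed = rc$seed, K = K,
                                 nlambda = nlambda,
                                 n_secondary = n_secondary, tol = tol)),
          error = function(e) NULL)
        if (is.null(fit)) {
          res <- list(r2 = NA_real_, rmse = NA_real_, mae = NA_real_)
        } else {
          pred <- predict(fit, data$test$X)
          res <- list(r2 = r_squared(data$test$y, pred),
                      rmse = rmse(data$test$y, pred),
                      mae = mae(data$test$y, pred))
        }
        rows[[length(rows) + 1]] <- data.frame(
          config = ci, n = config$n, p = config$p, method = m,
          replicate = r, seed = rc$seed, r2 = res$r2, rmse = res$rmse,
          mae = res$mae)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       se = stats::sd(v, na.rm = TRUE) /
                         sqrt(max(sum(!is.na(v)), 1)))
  summ <- do.call(rbind, lapply(
    split(results, list(results$config, results$method), drop = TRUE),
    function(d) {
      r2 <- agg(d$r2); rm_ <- agg(d$rmse); ma <- agg(d$mae)
      data.frame(config = d$config[1], n = d$n[1], p = d$p[1],
                 method = d$method[1], replicates = nrow(d),
                 r2 = r2["mean"], r2_se = r2["se"],
                 rmse = rm_["mean"], rmse_se = rm_["se"],
                 mae = ma["mean"], mae_se = ma["se"], row.names = NULL)
    }))
  summ <- summ[order(summ$config, match(summ$method, BENCHMARK_METHODS)), ]
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a benchmark summary as CSV
#'
#' One row per (configuration, method) with mean R-squared, RMSE, MAE and
#' their Monte Carlo standard errors.
#'
#' @param bench A `"benchmark_result"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_csv <- function(bench, path) {
  write.csv(bench$summary, path, row.names = FALSE)
  invisible(path)
}
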