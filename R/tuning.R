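# Tuning-parameter grids and K-fold cross-validation for model selection.

#' Smallest penalty that zeroes the whole model
#'
#' For scalar families this is `max_j |x_j' y / n|` on the standardized
#' design (divided by the coordinate weight for the adaptive lasso); for
#' group families `max_g ||X_g' y / n|| / sqrt(m_g)` on the orthonormalized
#' blocks; for the group-subset families it is the largest entering
#' threshold `(||X_g'y/n|| - lambda1_g)_+^2 / (2 m_g cbar_g)` of the
#' adaptive grid. Fitting at this value returns the all-zero model.
#'
#' @param design A [grouped_design()].
#' @param family Penalty family name.
#' @param weights Adaptive-lasso weights (computed from a ridge initial fit
#'   when `NULL`).
#' @param lambda1 Group-lasso shrinkage level for `grsubset_grlasso`.
#' @param group_multiplier Scale group penalties by `sqrt(m_g)`.
#' @return A single nonnegative number (0, with a warning, when the
#'   centered response is orthogonal to every column).
#' @export
lambda_max <- function(design, family, weights = NULL, lambda1 = 0,
                       group_multiplier = TRUE) {
  family <- match.arg(family, ALL_FAMILIES)
  if (family %in% SUBSET_FAMILIES) {
    std <- standardize_design(design)
    n <- std$n
    G <- std$G
    pk <- as.numeric(std$grp_len)
    lam1k <- if (family == "grsubset_grlasso") lambda1 * sqrt(pk) else
      rep(0, G)
    th <- vapply(seq_len(G), function(g) {
      idx <- std$grp_start[g]:(std$grp_start[g] + std$grp_len[g] - 1L)
      B <- std$X[, idx, drop = FALSE]
      cb <- max(eigen(crossprod(B) / n, symmetric = TRUE,
                      only.values = TRUE)$values)
      if (cb <= 0) return(0)
      gn <- sqrt(sum((crossprod(B, std$y) / n)^2))
      max(gn - lam1k[g], 0)^2 / (2 * pk[g] * cb)
    }, numeric(1))
    out <- max(th)
    if (out <= 0)
      warning("response is orthogonal to all columns; lambda_max = 0")
    return(out)
  }
  std <- standardize_design(design,
                            orthonormalize = family %in% GROUP_FAMILIES)
  if (family == "alasso" && is.null(weights))
    weights <- alasso_weights(std$X, std$y)
  lambda_max_std(std, family, weights, group_multiplier)
}

#' Logarithmically spaced penalty grid
#'
#' `n_points` log-spaced values from `lam_max` down to `ratio * lam_max`,
#' inclusive of both endpoints.
#'
#' @param lam_max Positive anchor (see [lambda_max()]).
#' @param n_points Grid size (default 100).
#' @param ratio `lambda_min / lambda_max` (default `1e-4`); must be `< 1`.
#' @return Strictly decreasing numeric vector of length `n_points`.
#' @export
make_grid <- function(lam_max, n_points = 100, ratio = 1e-4) {
  if (!is.numeric(lam_max) || lam_max <= 0) stop("'lam_max' must be positive")
  if (n_points < 1) stop("'n_points' must be at least 1")
  if (ratio >= 1) stop("'ratio' must be < 1")
  logspace(lam_max, lam_max * ratio, n_points)
}

#' Nonconvexity-parameter grid for SCAD/MCP
#'
#' Log-spaced grid of the nonconvexity parameter, descending from `g_max`
#' to `g_min`. The default lower endpoint `2 + 1e-4` sits just above the
#' SCAD admissibility bound (`gamma > 2`) and is also admissible for MCP
#' (`gamma > 1`).
#'
#' @param g_max Upper endpoint (default 100).
#' @param g_min Lower endpoint (default `2 + 1e-4`).
#' @param n_points Grid size (default 30).
#' @param family `"scad"`, `"mcp"`, `"grscad"`, or `"grmcp"` (admissibility
#'   check only).
#' @return Decreasing numeric vector of length `n_points`.
#' @export
make_gamma_grid <- function(g_max = 100, g_min = 2 + 1e-4, n_points = 30,
                            family = c("scad", "mcp", "grscad", "grmcp")) {
  family <- match.arg(family)
  if (g_min >= g_max) stop("'g_min' must be below 'g_max'")
  if (family %in% c("scad", "grscad") && g_min <= 2)
    stop("SCAD requires g_min > 2")
  if (family %in% c("mcp", "grmcp") && g_min <= 1)
    stop("MCP requires g_min > 1")
  logspace(g_max, g_min, n_points)
}

secondary_kind <- function(family) {
  switch(family,
         scad = , mcp = , grscad = , grmcp = "gamma",
         enet = , grsubset_ridge = "lambda2",
         grsubset_grlasso = "lambda1",
         "none")
}

default_secondary <- function(family, design, n_secondary) {
  kind <- secondary_kind(family)
  if (kind == "none") return(list(kind = kind, values = NA_real_))
  if (kind == "gamma") {
    if (is.null(n_secondary) || n_secondary <= 1)
      return(list(kind = kind, values = default_gamma(family)))
    return(list(kind = kind,
                values = make_gamma_grid(n_points = n_secondary,
                                         family = family)))
  }
  if (kind == "lambda2") {
    if (is.null(n_secondary)) n_secondary <- 5
    return(list(kind = kind, values = logspace(10, 1e-4, n_secondary)))
  }
  # lambda1 for grsubset_grlasso: scaled to the group-lasso lambda_max
  std <- standardize_design(design)
  z <- as.numeric(crossprod(std$X, std$y)) / std$n
  l1max <- max(vapply(seq_len(std$G), function(g) {
    idx <- std$grp_start[g]:(std$grp_start[g] + std$grp_len[g] - 1L)
    sqrt(sum(z[idx]^2)) / sqrt(std$grp_len[g])
  }, numeric(1)))
  if (is.null(n_secondary)) n_secondary <- 5
  if (l1max <= 0) l1max <- 1
  list(kind = kind, values = logspace(0.5 * l1max, 0.01 * l1max, n_secondary))
}

intercept_fit <- function(design) {
  beta <- stats::setNames(numeric(design$p), design$column_names)
  cfg <- structure(list(family = "intercept", lambda = 0, gamma = NA_real_,
                        lambda2 = 0, lambda0 = 0, lambda1 = 0,
                        weights = NULL), class = "penalty_config")
  new_coef_fit(intercept = mean(design$y), beta = beta,
               groups = design$groups, group_labels = design$group_labels,
               objective = 0.5 * mean((design$y - mean(design$y))^2),
               converged = TRUE, iterations = 0, config = cfg)
}

# Fit one path (any family) on a design with a fixed primary grid and a
# fixed secondary value; shared by cross_validate.
fit_family_path <- function(design, family, lambda, secondary, kind,
                            weights = NULL, alpha = 0.9, grid_size = 100,
                            group_multiplier = TRUE, tol = 1e-5,
                            max_iter = 10000, nlambda = 100,
                            lambda_min_ratio = 1e-4) {
  if (family %in% SUBSET_FAMILIES) {
    shrink <- switch(family, grsubset = "none",
                     grsubset_grlasso = "grlasso", grsubset_ridge = "ridge")
    fit_group_subset(design,
                     lambda1 = if (kind == "lambda1") secondary else 0,
                     lambda2 = if (kind == "lambda2") secondary else 0,
                     shrink_family = shrink, alpha = alpha,
                     grid_size = if (is.null(lambda)) grid_size else
                       length(lambda),
                     lambda0 = lambda, tol = tol, max_iter = max_iter)
  } else {
    fit_path(design, family, lambda = lambda, nlambda = nlambda,
             lambda_min_ratio = lambda_min_ratio,
             gamma = if (kind == "gamma") secondary else NULL,
             lambda2 = if (kind == "lambda2") secondary else 0,
             weights = weights, group_multiplier = group_multiplier,
             tol = tol, max_iter = max_iter)
  }
}

#' K-fold cross-validation for penalized fits
#'
#' Seeded random partition into `K` near-equal folds; for every
#' (secondary, lambda) configuration the path is fit on each training fold
#' with warm starts and scored by RMSE on the held-out fold. The mean CV
#' curve is the average of the fold curves, and the selected configuration
#' attains its minimum, with ties broken toward larger lambda and then the
#' earlier (more convex / more heavily shrunk) secondary value. The primary
#' grid is anchored at the full-data `lambda_max` so the same grid is used
#' on every fold; for the group-subset families the adaptive lambda0 grid
#' is likewise generated once on the full data.
#'
#' Secondary tuning parameters default to single fixed values
#' (SCAD `gamma = 3.7`, MCP `gamma = 3`) or short grids; set `n_secondary`
#' (e.g. to 30) for a full joint search.
#'
#' @param design A [grouped_design()].
#' @param family Penalty family, or `"intercept"` for the null model.
#' @param K Number of folds (default 5).
#' @param seed Seed for the fold partition.
#' @param grid Optional primary grid (decreasing numeric vector).
#' @param nlambda,lambda_min_ratio Primary grid size/ratio when `grid` is
#'   `NULL` (defaults 100 and `1e-4`).
#' @param n_secondary Secondary grid size (`NULL` = family default).
#' @param alpha,grid_size Adaptive-grid parameters for the group-subset
#'   families.
#' @param group_multiplier,tol,max_iter Passed to the solvers.
#' @return A `"cv_result"` with the CV curves, the selected configuration,
#'   the refit full-data path (`fit`) and fitted model (`best_fit`), and
#'   the minimized CV RMSE (`cv_error`).
#' @export
cross_validate <- function(design, family, K = 5, seed = 1, grid = NULL,
                           nlambda = 100, lambda_min_ratio = 1e-4,
                           n_secondary = NULL, alpha = 0.9, grid_size = 100,
                           group_multiplier = TRUE, tol = 1e-5,
                           max_iter = 10000) {
  if (K < 2) stop("'K' must be at least 2")
  if (design$n < K) stop("need at least K observations")
  folds <- make_folds(design$n, K, seed)
  if (min(tabulate(folds, K)) < 1) stop("empty fold")
  if (identical(family, "intercept")) {
    pred <- numeric(design$n)
    for (k in seq_len(K)) {
      idx <- which(folds == k)
      pred[idx] <- mean(design$y[-idx])
    }
    errs <- vapply(seq_len(K), function(k) {
      idx <- which(folds == k)
      rmse(design$y[idx], pred[idx])
    }, numeric(1))
    fit <- intercept_fit(design)
    return(structure(
      list(family = "intercept", K = K, seed = seed, folds = folds,
           secondary = NA, secondary_kind = "none", lambda = list(0),
           cvm = list(mean(errs)), cvsd = list(stats::sd(errs) / sqrt(K)),
           fold_errors = matrix(errs, ncol = 1), best_secondary = NA,
           best_index = 1L, best_config = fit$config, fit = NULL,
           best_fit = fit, cv_error = mean(errs), oof = pred),
      class = "cv_result"))
  }
  family <- match.arg(family, ALL_FAMILIES)
  weights <- NULL
  if (family == "alasso") {
    std <- standardize_design(design)
    weights <- alasso_weights(std$X, std$y)
  }
  sec <- default_secondary(family, design, n_secondary)
  if (is.list(grid)) {
    if (!is.null(grid$secondary)) sec$values <- grid$secondary
    grid <- grid$primary
  }
  S <- length(sec$values)
  lam_list <- vector("list", S)
  cvm_list <- vector("list", S)
  cvsd_list <- vector("list", S)
  full_paths <- vector("list", S)
  fold_designs <- lapply(seq_len(K), function(k)
    subset_design(design, which(folds != k)))
  for (s in seq_len(S)) {
    sval <- sec$values[s]
    if (family %in% SUBSET_FAMILIES) {
      full <- fit_family_path(design, family, lambda = grid,
                              secondary = sval, kind = sec$kind,
                              alpha = alpha, grid_size = grid_size,
                              tol = tol, max_iter = max_iter,
                              nlambda = nlambda)
      lam <- full$lambda
      full_paths[[s]] <- full
    } else {
      if (is.null(grid)) {
        lmax <- suppressWarnings(
          lambda_max(design, family, weights = weights,
                     group_multiplier = group_multiplier))
        if (lmax <= 0) lmax <- 1e-3
        lam <- make_grid(lmax, nlambda, lambda_min_ratio)
      } else lam <- sort(grid, decreasing = TRUE)
    }
    errs <- matrix(NA_real_, K, length(lam))
    for (k in seq_len(K)) {
      idx <- which(folds == k)
      pk <- suppressWarnings(
        fit_family_path(fold_designs[[k]], family, lambda = lam,
                        secondary = sval, kind = sec$kind,
                        weights = weights, alpha = alpha,
                        grid_size = grid_size, tol = tol,
                        max_iter = max_iter))
      pred <- predict(pk, design$X[idx, , drop = FALSE])
      Lk <- ncol(pred)
      errs[k, seq_len(Lk)] <- sqrt(colMeans((design$y[idx] - pred)^2))
      if (Lk < length(lam)) errs[k, (Lk + 1):length(lam)] <- errs[k, Lk]
    }
    lam_list[[s]] <- lam
    cvm_list[[s]] <- colMeans(errs)
    cvsd_list[[s]] <- apply(errs, 2, stats::sd) / sqrt(K)
  }
  best_s <- 1L
  best_l <- 1L
  best_val <- Inf
  for (s in seq_len(S)) {
    l <- which.min(cvm_list[[s]])
    if (cvm_list[[s]][l] < best_val) {
      best_val <- cvm_list[[s]][l]
      best_s <- s
      best_l <- l
    }
  }
  if (is.null(full_paths[[best_s]])) {
    full_paths[[best_s]] <- suppressWarnings(
      fit_family_path(design, family, lambda = lam_list[[best_s]],
                      secondary = sec$values[best_s], kind = sec$kind,
                      weights = weights, alpha = alpha,
                      grid_size = grid_size, tol = tol,
                      max_iter = max_iter))
  }
  fit <- full_paths[[best_s]]
  best_l <- min(best_l, length(fit$lambda))
  best_fit <- path_fit(fit, best_l)
  structure(
    list(family = family, K = K, seed = seed, folds = folds,
         secondary = sec$values, secondary_kind = sec$kind,
         lambda = lam_list, cvm = cvm_list, cvsd = cvsd_list,
         best_secondary = sec$values[best_s], best_index = best_l,
         best_config = best_fit$config, fit = fit, best_fit = best_fit,
         cv_error = best_val, weights = weights),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$family, " K =", x$K, " CV RMSE =",
      format(x$cv_error, digits = 5), "\n")
  invisible(x)
}

#' @export
predict.cv_result <- function(object, newdata, ...) {
  predict(object$best_fit, newdata)
}
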