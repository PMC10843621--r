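# Coordinate-descent fitting engines: cyclic CD for scalar penalties, block
# CD for group penalties on orthonormalized blocks, and the L0 group-subset
# coordinate descent with its adaptively generated lambda0 grid.

# Identity "standardization" used when standardize = FALSE: columns are
# reordered into contiguous group blocks but otherwise untouched, and no
# intercept is fit. Group solvers then assume X_g'X_g/n = I within blocks.
identity_std <- function(design) {
  ord <- order(design$groups)
  grp <- design$groups[ord]
  G <- design$G
  sizes <- as.integer(tabulate(grp, nbins = G))
  starts <- cumsum(c(1L, sizes[-G]))
  list(X = design$X[, ord, drop = FALSE], y = design$y, ybar = 0,
       centers = rep(0, design$p), scales = rep(1, design$p), ord = ord,
       grp_start = as.integer(starts), grp_len = sizes, orig_sizes = sizes,
       orig_starts = as.integer(starts), transforms = NULL, n = design$n,
       G = G)
}

# Adaptive-lasso weights from a ridge initial fit on the standardized
# design; the ridge penalty is chosen by generalized cross-validation so the
# weights are deterministic. Returns weights on the standardized scale.
alasso_weights <- function(X, y) {
  n <- nrow(X)
  sv <- svd(X, nu = min(n, ncol(X)))
  d2 <- sv$d^2
  uty <- crossprod(sv$u, y)
  grid <- logspace(1e-6, 1e4, 50) * mean(d2)
  gcv <- vapply(grid, function(a) {
    shrink <- d2 / (d2 + a)
    fit <- sv$u %*% (shrink * uty)
    df <- sum(shrink)
    n * sum((y - fit)^2) / (n - df)^2
  }, numeric(1))
  a <- grid[which.min(gcv)]
  b <- sv$v %*% (sv$d / (d2 + a) * uty)
  1 / (abs(as.numeric(b)) + 1e-8)
}

# Internal lambda_max on an already-standardized design (see lambda_max()
# for the exported, user-facing version).
lambda_max_std <- function(std, family, weights = NULL,
                           group_multiplier = TRUE) {
  z <- as.numeric(crossprod(std$X, std$y)) / std$n
  if (family %in% c(SCALAR_FAMILIES)) {
    if (family == "alasso") {
      w <- weights
      out <- max(abs(z) / pmax(w, 1e-12))
    } else out <- max(abs(z))
  } else {
    G <- length(std$grp_start)
    mult <- if (group_multiplier) sqrt(std$grp_len) else rep(1, G)
    zn <- vapply(seq_len(G), function(g) {
      idx <- std$grp_start[g]:(std$grp_start[g] + std$grp_len[g] - 1L)
      sqrt(sum(z[idx]^2))
    }, numeric(1))
    out <- max(zn / mult)
  }
  if (out <= 0) warning("response is orthogonal to all columns; lambda_max = 0")
  out
}

make_reg_path <- function(design, family, lambda, betas, intercepts, active,
                          objective, iters, converged, gamma = NA,
                          lambda2 = 0, lambda1 = 0, weights = NULL,
                          group_multiplier = TRUE, states = NULL) {
  rownames(betas) <- design$column_names
  structure(
    list(family = family, lambda = lambda, gamma = gamma, lambda2 = lambda2,
         lambda1 = lambda1, weights = weights, betas = betas,
         intercepts = intercepts, active = active, objective = objective,
         iterations = iters, converged = converged,
         group_multiplier = group_multiplier, group_labels = design$group_labels,
         groups = design$groups, p = design$p, states = states),
    class = "reg_path")
}

#' @export
print.reg_path <- function(x, ...) {
  cat("<reg_path>", x$family, "path with", length(x$lambda), "points;",
      "df range", min(colSums(x$betas != 0)), "-",
      max(colSums(x$betas != 0)), "\n")
  invisible(x)
}

#' Predictions along a regularization path
#'
#' @param object A `"reg_path"`.
#' @param newdata Numeric matrix with `p` columns.
#' @param index Optional path point; all points if `NULL`.
#' @param ... Unused.
#' @return Matrix of predictions (rows of `newdata` by path points), or a
#'   vector if `index` is given.
#' @export
predict.reg_path <- function(object, newdata, index = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) stop("newdata has wrong number of columns")
  if (is.null(index)) {
    sweep(newdata %*% object$betas, 2, object$intercepts, "+")
  } else {
    as.numeric(newdata %*% object$betas[, index] + object$intercepts[index])
  }
}

#' Extract one fitted model from a path
#'
#' @param path A `"reg_path"`.
#' @param index Path point to extract.
#' @return A `"coef_fit"`.
#' @export
path_fit <- function(path, index) {
  beta <- path$betas[, index]
  fam <- path$family
  config <- penalty_config(
    fam,
    lambda = if (fam %in% SUBSET_FAMILIES) path$lambda1 else path$lambda[index],
    gamma = if (is.na(path$gamma)) NULL else path$gamma,
    lambda2 = path$lambda2,
    lambda0 = if (fam %in% SUBSET_FAMILIES) path$lambda[index] else 0,
    lambda1 = path$lambda1, weights = path$weights)
  new_coef_fit(intercept = path$intercepts[index], beta = beta,
               groups = path$groups, group_labels = path$group_labels,
               objective = path$objective[index],
               converged = path$converged[index],
               iterations = path$iterations[index], config = config)
}

new_coef_fit <- function(intercept, beta, groups, group_labels, objective,
                         converged, iterations, config) {
  active <- group_labels[sort(unique(groups[beta != 0]))]
  structure(
    list(intercept = intercept, beta = beta, active_groups = active,
         objective = objective, converged = converged,
         iterations = iterations, config = config,
         family = config$family, groups = groups,
         group_labels = group_labels),
    class = "coef_fit")
}

#' @export
print.coef_fit <- function(x, ...) {
  cat("<coef_fit>", x$family, " nonzero =", sum(x$beta != 0), "of",
      length(x$beta), " groups:", length(x$active_groups), "\n")
  invisible(x)
}

#' @export
coef.coef_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
predict.coef_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta))
    stop("newdata has wrong number of columns")
  as.numeric(newdata %*% object$beta + object$intercept)
}

#' Fit a regularization path
#'
#' Warm-started coordinate descent over a decreasing lambda grid for the
#' scalar families (`lasso`, `scad`, `mcp`, `enet`, `alasso`) and block
#' coordinate descent for the group families (`grlasso`, `grscad`,
#' `grmcp`). Columns are standardized internally (centered, scaled to unit
#' variance) and group blocks are additionally orthonormalized for the
#' group families; coefficients are returned on the original scale. With
#' `standardize = FALSE` the data are used as-is, no intercept is fit, and
#' group solvers assume orthonormal blocks (`X_g'X_g/n = I`).
#'
#' @param design A [grouped_design()].
#' @param family Penalty family name.
#' @param lambda Optional decreasing grid; computed from `lambda_max` if
#'   `NULL`.
#' @param nlambda,lambda_min_ratio Grid size and ratio `lambda_min /
#'   lambda_max` when `lambda` is `NULL`.
#' @param gamma Nonconvexity parameter (SCAD default 3.7, MCP default 3).
#' @param lambda2 Elastic-net ridge weight.
#' @param weights Adaptive-lasso weights (standardized scale); computed from
#'   a ridge initial fit when `NULL`.
#' @param group_multiplier Scale each group's penalty by `sqrt(m_g)`
#'   (default `TRUE`).
#' @param standardize Standardize internally (default `TRUE`).
#' @param tol,max_iter Convergence tolerance (max absolute coefficient
#'   change per sweep below `tol * (1 + max|beta|)`) and sweep cap.
#' @return A `"reg_path"`.
#' @export
fit_path <- function(design, family, lambda = NULL, nlambda = 100,
                     lambda_min_ratio = 1e-4, gamma = NULL, lambda2 = 0,
                     weights = NULL, group_multiplier = TRUE,
                     standardize = TRUE, tol = 1e-7, max_iter = 10000) {
  family <- match.arg(family, c(SCALAR_FAMILIES, GROUP_FAMILIES))
  is_group <- family %in% GROUP_FAMILIES
  if (is.null(gamma)) gamma <- default_gamma(family)
  std <- if (standardize) standardize_design(design, orthonormalize = is_group)
         else identity_std(design)
  n <- std$n
  if (family == "alasso" && is.null(weights))
    weights <- alasso_weights(std$X, std$y)
  if (is.null(lambda)) {
    lmax <- lambda_max_std(std, family, weights, group_multiplier)
    if (lmax <= 0) lambda <- 0
    else lambda <- logspace(lmax, lmax * lambda_min_ratio, nlambda)
  } else {
    lambda <- sort(lambda, decreasing = TRUE)
  }
  w <- if (is.null(weights)) rep(1, ncol(std$X)) else weights
  if (is_group) {
    mult <- if (group_multiplier) sqrt(std$grp_len) else rep(1, std$G)
    fit <- cd_group_path_cpp(std$X, std$y, std$grp_start - 1L, std$grp_len,
                             lambda, group_code(family), gamma, mult, tol,
                             as.integer(max_iter))
  } else {
    fit <- cd_scalar_path_cpp(std$X, std$y, lambda, scalar_code(family),
                              if (is.na(gamma)) 0 else gamma, lambda2, w,
                              tol, as.integer(max_iter))
  }
  L <- length(lambda)
  betas <- matrix(0, design$p, L)
  intercepts <- numeric(L)
  for (l in seq_len(L)) {
    bt <- unstandardize_beta(std, design, fit$beta[, l])
    betas[, l] <- bt$beta
    intercepts[l] <- bt$intercept
  }
  conv <- fit$converged == 1
  if (!all(conv))
    warning(sprintf("%d of %d path points did not converge within max_iter",
                    sum(!conv), L))
  active <- lapply(seq_len(L), function(l)
    design$group_labels[sort(unique(design$groups[betas[, l] != 0]))])
  make_reg_path(design, family, lambda, betas, intercepts, active,
                fit$objective, fit$iters, conv, gamma = gamma,
                lambda2 = lambda2, weights = weights,
                group_multiplier = group_multiplier)
}

#' Fit a scalar-penalized linear model at one configuration
#'
#' Cyclic coordinate descent for the lasso, SCAD, MCP, elastic-net, and
#' adaptive-lasso penalties. Nonconvex families are warm-started along an
#' internal path from `lambda_max` down to the requested `lambda` to avoid
#' poor local minima. Non-convergence yields a warning, never an error.
#'
#' @param design A [grouped_design()].
#' @param config A [penalty_config()] with a scalar family.
#' @param tol,max_iter,standardize See [fit_path()].
#' @return A `"coef_fit"` with the intercept, coefficients on the original
#'   scale, active groups, internal objective value, and convergence state.
#' @export
fit_penalized <- function(design, config, tol = 1e-7, max_iter = 10000,
                          standardize = TRUE) {
  stopifnot(inherits(config, "penalty_config"))
  if (!(config$family %in% SCALAR_FAMILIES))
    stop("fit_penalized handles scalar families; see fit_group_penalized")
  lamseq <- single_config_grid(design, config, standardize)
  path <- fit_path(design, config$family, lambda = lamseq,
                   gamma = if (is.na(config$gamma)) NULL else config$gamma,
                   lambda2 = config$lambda2, weights = config$weights,
                   standardize = standardize, tol = tol, max_iter = max_iter)
  out <- path_fit(path, length(path$lambda))
  out$config$weights <- path$weights
  out
}

#' Fit a group-penalized linear model at one configuration
#'
#' Block coordinate descent for the group lasso, group SCAD, and group MCP
#' penalties on internally orthonormalized groups; coefficients are mapped
#' back to the original basis. The per-group penalty is
#' `lambda * sqrt(m_g)` unless `group_multiplier = FALSE`.
#'
#' @inheritParams fit_penalized
#' @param group_multiplier Scale group penalties by `sqrt(m_g)`.
#' @return A `"coef_fit"`.
#' @export
fit_group_penalized <- function(design, config, tol = 1e-7, max_iter = 10000,
                                standardize = TRUE, group_multiplier = TRUE) {
  stopifnot(inherits(config, "penalty_config"))
  if (!(config$family %in% GROUP_FAMILIES))
    stop("fit_group_penalized handles grlasso/grscad/grmcp")
  lamseq <- single_config_grid(design, config, standardize, group_multiplier)
  path <- fit_path(design, config$family, lambda = lamseq,
                   gamma = if (is.na(config$gamma)) NULL else config$gamma,
                   group_multiplier = group_multiplier,
                   standardize = standardize, tol = tol, max_iter = max_iter)
  path_fit(path, length(path$lambda))
}

# Internal warm-start grid ending at config$lambda: a single point for the
# convex families, a short descending path for the nonconvex ones.
single_config_grid <- function(design, config, standardize,
                               group_multiplier = TRUE) {
  fam <- config$family
  if (fam %in% c("lasso", "enet", "alasso", "grlasso")) return(config$lambda)
  std <- if (standardize)
    standardize_design(design, orthonormalize = fam %in% GROUP_FAMILIES)
  else identity_std(design)
  w <- config$weights
  if (fam == "alasso" && is.null(w)) w <- alasso_weights(std$X, std$y)
  lmax <- suppressWarnings(
    lambda_max_std(std, fam, w, group_multiplier))
  if (config$lambda >= lmax || lmax <= 0) return(config$lambda)
  lo <- max(config$lambda, lmax * 1e-6)
  seq_ <- logspace(lmax, lo, 25)
  if (config$lambda < lo) seq_ <- c(seq_, config$lambda)
  seq_
}

#' Fit the L0 group-subset path
#'
#' Block coordinate descent for group subset selection: each group carries a
#' selection penalty `lambda0 * m_g * 1(v_g != 0)` plus optional shrinkage
#' (`shrink_family = "grlasso"`: `lambda1 * sqrt(m_g) * ||v_g||`;
#' `"ridge"`: `lambda2 * ||v_g||^2`). Block updates are proximal
#' (majorize-minimize) steps with per-group constants `cbar_g`, the largest
#' eigenvalue of `X_g'X_g/n`. The lambda0 grid is generated adaptively: the
#' first value is the smallest that keeps every group at zero, and each
#' subsequent value is `alpha` times the largest entering threshold among
#' inactive groups, so at least one new group enters per grid point. The
#' path stops when all groups are active or `grid_size` points are reached.
#'
#' @param design A [grouped_design()].
#' @param lambda1 Group-lasso shrinkage level (used when
#'   `shrink_family = "grlasso"`); per-group weight `lambda1 * sqrt(m_g)`.
#' @param lambda2 Ridge weight (used when `shrink_family = "ridge"`).
#' @param shrink_family `"none"`, `"grlasso"`, or `"ridge"`.
#' @param alpha Grid decay factor in `[0, 1)`.
#' @param grid_size Maximum number of lambda0 grid points.
#' @param lambda0 Optional fixed decreasing lambda0 grid; overrides the
#'   adaptive construction (used, e.g., to share one grid across CV folds).
#' @param tol,max_iter,standardize See [fit_path()].
#' @return A `"reg_path"` whose `lambda` slot holds the lambda0 grid and
#'   whose `states` slot holds one group-subset state per point (see
#'   [next_lambda0()]).
#' @export
fit_group_subset <- function(design, lambda1 = 0, lambda2 = 0,
                             shrink_family = c("none", "grlasso", "ridge"),
                             alpha = 0.9, grid_size = 100, lambda0 = NULL,
                             tol = 1e-7, max_iter = 10000,
                             standardize = TRUE) {
  shrink_family <- match.arg(shrink_family)
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("'alpha' must be in [0, 1)")
  shrink <- match(shrink_family, c("none", "grlasso", "ridge")) - 1L
  std <- if (standardize) standardize_design(design) else identity_std(design)
  n <- std$n
  G <- std$G
  pk <- as.numeric(std$grp_len)
  lam1k <- if (shrink == 1L) lambda1 * sqrt(pk) else rep(0, G)
  cbar <- vapply(seq_len(G), function(g) {
    idx <- std$grp_start[g]:(std$grp_start[g] + std$grp_len[g] - 1L)
    B <- std$X[, idx, drop = FALSE]
    max(eigen(crossprod(B) / n, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))

  enter_thresh <- function(gradnorm, active) {
    th <- (pmax(gradnorm - lam1k, 0))^2 / (2 * pk * cbar)
    th[cbar <= 0] <- -Inf
    th[active] <- -Inf
    th
  }

  grad0 <- vapply(seq_len(G), function(g) {
    idx <- std$grp_start[g]:(std$grp_start[g] + std$grp_len[g] - 1L)
    sqrt(sum((crossprod(std$X[, idx, drop = FALSE], std$y) / n)^2))
  }, numeric(1))

  adaptive <- is.null(lambda0)
  if (adaptive) {
    l0 <- max(c(enter_thresh(grad0, rep(FALSE, G)), 0))
    grid <- l0
  } else {
    grid <- sort(lambda0, decreasing = TRUE)
  }

  v <- numeric(ncol(std$X))
  res <- list()
  states <- list()
  t <- 1L
  repeat {
    cur <- grid[t]
    fit <- cd_grsubset_fit_cpp(std$X, std$y, std$grp_start - 1L, std$grp_len,
                               cur, shrink, lam1k, lambda2, cbar, v, tol,
                               as.integer(max_iter))
    v <- as.numeric(fit$v)
    res[[t]] <- fit
    states[[t]] <- structure(
      list(beta = v, active_set = which(fit$active == 1),
           gradnorm = as.numeric(fit$gradnorm), block_constants = cbar,
           group_sizes = pk, lambda1k = lam1k, alpha = alpha, lambda0 = cur),
      class = "group_subset_state")
    if (adaptive) {
      if (t >= grid_size || all(fit$active == 1) || cur == 0) break
      nxt <- alpha * max(enter_thresh(as.numeric(fit$gradnorm),
                                      fit$active == 1))
      if (!is.finite(nxt) || nxt < 0) break
      if (nxt >= cur) nxt <- cur * 0.5 # guard; cannot occur at convergence
      grid <- c(grid, nxt)
      t <- t + 1L
    } else {
      if (t >= length(grid)) break
      t <- t + 1L
    }
  }

  L <- length(res)
  betas <- matrix(0, design$p, L)
  intercepts <- numeric(L)
  for (l in seq_len(L)) {
    bt <- unstandardize_beta(std, design, res[[l]]$v)
    betas[, l] <- bt$beta
    intercepts[l] <- bt$intercept
  }
  conv <- vapply(res, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv))
    warning(sprintf("%d of %d lambda0 points did not converge", sum(!conv), L))
  active <- lapply(seq_len(L), function(l)
    design$group_labels[which(res[[l]]$active == 1)])
  family <- switch(shrink_family, none = "grsubset",
                   grlasso = "grsubset_grlasso", ridge = "grsubset_ridge")
  out <- make_reg_path(design, family, grid[seq_len(L)], betas, intercepts,
                       active, vapply(res, `[[`, numeric(1), "objective"),
                       vapply(res, `[[`, numeric(1), "iters"), conv,
                       lambda2 = lambda2, lambda1 = lambda1,
                       states = states)
  out$alpha <- alpha
  out
}

#' Next lambda0 on the adaptive group-subset grid
#'
#' Given a converged group-subset state, returns the next (strictly
#' smaller) selection penalty `alpha * max_k (||grad_k L|| - lambda1_k)_+^2 /
#' (2 p_k cbar_k)` over inactive groups `k`, which guarantees that at least
#' one new group enters at the next fit. The block-restricted gradient norm
#' is used for each inactive group. Returns `NA` when every group is
#' already active (the grid is exhausted).
#'
#' @param state A `"group_subset_state"` (from the `states` slot of a
#'   [fit_group_subset()] path), or a list with fields `gradnorm`,
#'   `active_set`, `block_constants`, `group_sizes`, `lambda1k`, `alpha`.
#' @return The next lambda0, or `NA_real_` if all groups are active.
#' @export
next_lambda0 <- function(state) {
  G <- length(state$gradnorm)
  inactive <- setdiff(seq_len(G), state$active_set)
  if (length(inactive) == 0) {
    warning("all groups are active; lambda0 grid exhausted")
    return(NA_real_)
  }
  th <- (pmax(state$gradnorm - state$lambda1k, 0))^2 /
    (2 * state$group_sizes * state$block_constants)
  th[state$block_constants <= 0] <- 0
  state$alpha * max(th[inactive])
}
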