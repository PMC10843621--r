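# Penalty families, their tuning-parameter container, and the scalar/group
# thresholding (proximal) operators used by the coordinate-descent solvers.

SCALAR_FAMILIES <- c("lasso", "scad", "mcp", "enet", "alasso")
GROUP_FAMILIES <- c("grlasso", "grscad", "grmcp")
SUBSET_FAMILIES <- c("grsubset", "grsubset_grlasso", "grsubset_ridge")
ALL_FAMILIES <- c(SCALAR_FAMILIES, GROUP_FAMILIES, SUBSET_FAMILIES)

scalar_code <- function(family) {
  match(family, SCALAR_FAMILIES)
}
group_code <- function(family) {
  match(family, GROUP_FAMILIES)
}

default_gamma <- function(family) {
  switch(family, scad = 3.7, grscad = 3.7, mcp = 3, grmcp = 3, NA_real_)
}

#' Penalty configuration
#'
#' Container for a penalty family and its tuning parameters. `lambda` is the
#' primary tuning parameter; `gamma` is the nonconvexity parameter of SCAD
#' (`gamma > 2`, default 3.7) and MCP (`gamma > 1`, default 3); `lambda2` is
#' the elastic-net ridge weight or the ridge companion of the group-subset
#' variants; `weights` are adaptive-lasso coordinate weights; `lambda0` is
#' the per-group selection penalty of the group-subset families and
#' `lambda1` their group-lasso shrinkage level.
#'
#' @param family One of `"lasso"`, `"scad"`, `"mcp"`, `"enet"`, `"alasso"`,
#'   `"grlasso"`, `"grscad"`, `"grmcp"`, `"grsubset"`, `"grsubset_grlasso"`,
#'   `"grsubset_ridge"`.
#' @param lambda Nonnegative primary tuning parameter.
#' @param gamma Nonconvexity parameter (SCAD/MCP families only).
#' @param lambda2 Nonnegative ridge weight (enet / grsubset_ridge).
#' @param lambda0 Nonnegative per-group selection penalty (grsubset families).
#' @param lambda1 Nonnegative group shrinkage level (grsubset_grlasso); the
#'   per-group weight is `lambda1 * sqrt(m_g)`.
#' @param weights Optional nonnegative adaptive-lasso weights.
#' @return An object of class `"penalty_config"`.
#' @export
penalty_config <- function(family, lambda = 0, gamma = NULL, lambda2 = 0,
                           lambda0 = 0, lambda1 = 0, weights = NULL) {
  family <- match.arg(family, ALL_FAMILIES)
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda < 0)
    stop("'lambda' must be a single nonnegative number")
  if (is.null(gamma)) gamma <- default_gamma(family)
  if (family %in% c("scad", "grscad") && (!is.finite(gamma) || gamma <= 2))
    stop("SCAD requires gamma > 2")
  if (family %in% c("mcp", "grmcp") && (!is.finite(gamma) || gamma <= 1))
    stop("MCP requires gamma > 1")
  if (!is.numeric(lambda2) || lambda2 < 0)
    stop("'lambda2' must be nonnegative")
  if (!is.numeric(lambda0) || lambda0 < 0)
    stop("'lambda0' must be nonnegative")
  if (!is.numeric(lambda1) || lambda1 < 0)
    stop("'lambda1' must be nonnegative")
  if (!is.null(weights)) {
    if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights < 0))
      stop("'weights' must be nonnegative and finite")
  }
  structure(
    list(family = family, lambda = lambda, gamma = gamma, lambda2 = lambda2,
         lambda0 = lambda0, lambda1 = lambda1, weights = weights),
    class = "penalty_config")
}

#' @export
print.penalty_config <- function(x, ...) {
  cat("<penalty_config> family =", x$family, " lambda =",
      format(x$lambda, digits = 4))
  if (!is.na(x$gamma)) cat("  gamma =", format(x$gamma, digits = 4))
  if (x$lambda2 > 0) cat("  lambda2 =", format(x$lambda2, digits = 4))
  if (x$family %in% SUBSET_FAMILIES)
    cat("  lambda0 =", format(x$lambda0, digits = 4),
        " lambda1 =", format(x$lambda1, digits = 4))
  cat("\n")
  invisible(x)
}

#' Evaluate a scalar penalty function
#'
#' Returns `P(t)` for the scalar penalty families: `lambda * t` for the
#' lasso, the three-branch SCAD penalty, the two-branch MCP penalty,
#' `lambda * t + lambda2 * t^2` for the elastic net, and `lambda * w * t`
#' for the adaptive lasso (with a single coordinate weight). All are
#' continuous in `t` and nondecreasing on `[0, Inf)` except the elastic
#' net's ridge term which is trivially increasing.
#'
#' @param t Nonnegative magnitude(s) `|beta|` at which to evaluate.
#' @param config A [penalty_config()] with a scalar family.
#' @return Penalty value(s), same length as `t`.
#' @export
penalty_value <- function(t, config) {
  stopifnot(inherits(config, "penalty_config"))
  if (!(config$family %in% SCALAR_FAMILIES))
    stop("penalty_value is defined for scalar families only")
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be nonnegative")
  w <- if (is.null(config$weights)) 1 else config$weights[1]
  vapply(t, penalty_value_cpp, numeric(1),
         family = scalar_code(config$family), lam = config$lambda,
         gam = if (is.na(config$gamma)) 0 else config$gamma,
         lam2 = config$lambda2, w = w)
}

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - lam, 0)`: the unique minimizer of
#' `(1/2)(b - z)^2 + lam * |b|`, the proximal operator of the lasso penalty.
#'
#' @param z Real value(s).
#' @param lam Nonnegative threshold.
#' @return Thresholded value(s).
#' @export
soft_threshold <- function(z, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || lam < 0)
    stop("'lam' must be a single nonnegative number")
  vapply(z, soft_threshold_cpp, numeric(1), lam = lam)
}

#' Scalar thresholding for the one-dimensional coordinate subproblem
#'
#' Exact minimizer of `(denom/2) b^2 - z b + P(|b|)` for a scalar penalty
#' family: soft thresholding for the lasso, the three-branch SCAD rule, firm
#' thresholding for MCP, a scaled soft threshold for the elastic net, and a
#' weighted soft threshold for the adaptive lasso. `denom` is the quadratic
#' curvature of the coordinate subproblem (1 for standardized columns).
#'
#' @param z Real value (the gradient-adjusted coordinate).
#' @param config A [penalty_config()] with a scalar family.
#' @param denom Positive curvature of the subproblem.
#' @return The minimizing coefficient value.
#' @export
scalar_threshold <- function(z, config, denom = 1) {
  stopifnot(inherits(config, "penalty_config"))
  if (!(config$family %in% SCALAR_FAMILIES))
    stop("scalar_threshold is defined for scalar families only")
  if (!is.numeric(denom) || denom <= 0) stop("'denom' must be positive")
  if (config$family == "mcp" && config$gamma * denom <= 1)
    stop("MCP update requires gamma * denom > 1")
  if (config$family == "scad" && config$gamma <= 2)
    stop("SCAD update requires gamma > 2")
  w <- if (is.null(config$weights)) 1 else {
    if (length(config$weights) != 1)
      stop("scalar_threshold expects a single adaptive-lasso weight")
    config$weights[1]
  }
  vapply(z, scalar_threshold_cpp, numeric(1),
         family = scalar_code(config$family), lam = config$lambda,
         gam = if (is.na(config$gamma)) 0 else config$gamma,
         lam2 = config$lambda2, w = w, denom = denom)
}

#' Group (block) thresholding for an orthonormalized group
#'
#' Exact minimizer of `(denom/2)||b||^2 - z'b + P(||b||)` where `P` is the
#' group-lasso norm penalty (`lambda * ||b||`), or the SCAD/MCP penalty
#' applied to the block norm. The solution is radial: the norm of `z` is
#' thresholded by the corresponding scalar rule and `z` is rescaled. The
#' output is exactly the zero vector iff `||z||` falls at or below the
#' family's zeroing threshold. `lambda` here is the effective group-level
#' penalty (any `sqrt(m_g)` scaling is applied by the caller).
#'
#' @param z Numeric vector (the group's gradient-adjusted coordinates).
#' @param config A [penalty_config()] with family `"grlasso"`, `"grscad"`,
#'   or `"grmcp"`.
#' @param denom Positive curvature of the block subproblem.
#' @return Numeric vector of the same length as `z`.
#' @export
group_threshold <- function(z, config, denom = 1) {
  stopifnot(inherits(config, "penalty_config"))
  if (!(config$family %in% GROUP_FAMILIES))
    stop("group_threshold is defined for group families only")
  if (length(z) == 0) stop("empty group vector")
  if (!is.numeric(denom) || denom <= 0) stop("'denom' must be positive")
  nz <- sqrt(sum(z^2))
  if (nz == 0) return(numeric(length(z)))
  # radial reduction: threshold the norm with the matching scalar rule
  bn <- scalar_threshold_cpp(nz, family = group_code(config$family),
                             lam = config$lambda,
                             gam = if (is.na(config$gamma)) 0 else config$gamma,
                             lam2 = 0, w = 1, denom = denom)
  z * (bn / nz)
}
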