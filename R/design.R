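# Grouped design container and the internal standardization /
# orthonormalization machinery shared by the solvers.

#' Grouped regression design
#'
#' Bundles a numeric design matrix, a continuous response, and a
#' non-overlapping group assignment for the columns. Group labels may be any
#' atomic values; they are coded internally as integers `1..G` in order of
#' first appearance. Columns of one group need not be contiguous.
#'
#' @param X Numeric matrix, `n x p`, no non-finite entries.
#' @param y Numeric response of length `n >= 2`.
#' @param groups Length-`p` vector assigning each column to a group.
#' @param column_names Optional column names (defaults to `colnames(X)`).
#' @return An object of class `"grouped_design"` with elements `X`, `y`,
#'   `groups` (integer codes), `group_labels`, `group_sizes`, `n`, `p`, `G`,
#'   `column_names`.
#' @export
grouped_design <- function(X, y, groups, column_names = colnames(X)) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("'X' must be numeric")
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (length(y) < 2) stop("need at least 2 observations")
  if (any(!is.finite(X))) stop("'X' contains non-finite entries")
  if (any(!is.finite(y))) stop("'y' contains non-finite entries")
  if (length(groups) != ncol(X))
    stop("'groups' must have one label per column of X")
  labels <- unique(groups)
  gi <- match(groups, labels)
  if (is.null(column_names)) column_names <- paste0("V", seq_len(ncol(X)))
  if (anyDuplicated(column_names)) stop("duplicate column names")
  colnames(X) <- column_names
  structure(
    list(X = X, y = y, groups = gi, group_labels = as.character(labels),
         group_sizes = as.integer(tabulate(gi, nbins = length(labels))),
         n = nrow(X), p = ncol(X), G = length(labels),
         column_names = column_names),
    class = "grouped_design")
}

#' @export
print.grouped_design <- function(x, ...) {
  cat("<grouped_design> n =", x$n, " p =", x$p, " groups =", x$G, "\n")
  invisible(x)
}

# Row subset of a grouped design.
subset_design <- function(design, idx) {
  grouped_design(design$X[idx, , drop = FALSE], design$y[idx],
                 design$groups, design$column_names)
}

# Standardize a grouped design for the solvers: center y, center and scale
# columns to unit variance (1/n denominator so x'x/n = 1), reorder columns
# into contiguous group blocks, and optionally orthonormalize each block so
# that X_g' X_g / n = I (SVD-based; rank-deficient blocks are reduced to
# their intrinsic rank with a warning). Returns everything needed to map
# coefficients back to the original basis and column order.
standardize_design <- function(design, orthonormalize = FALSE) {
  n <- design$n
  ord <- order(design$groups)
  X <- design$X[, ord, drop = FALSE]
  grp <- design$groups[ord]
  ybar <- mean(design$y)
  yc <- design$y - ybar
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers, "-")
  scales <- sqrt(colMeans(Xc^2))
  scales[scales < 1e-12] <- 1
  Xs <- sweep(Xc, 2, scales, "/")

  G <- design$G
  sizes <- as.integer(tabulate(grp, nbins = G))
  starts <- cumsum(c(1L, sizes[-G]))
  transforms <- NULL
  out_sizes <- sizes
  if (orthonormalize) {
    transforms <- vector("list", G)
    blocks <- vector("list", G)
    for (g in seq_len(G)) {
      cols <- starts[g]:(starts[g] + sizes[g] - 1L)
      B <- Xs[, cols, drop = FALSE]
      sv <- svd(B, nu = 0)
      keep <- sv$d > max(sv$d[1], 1) * 1e-10
      r <- sum(keep)
      if (r < sizes[g])
        warning(sprintf(
          "group %s is collinear; orthonormalized to rank %d of %d",
          design$group_labels[g], r, sizes[g]))
      Tg <- sv$v[, keep, drop = FALSE] %*%
        diag(sqrt(n) / sv$d[keep], nrow = r)
      transforms[[g]] <- Tg
      blocks[[g]] <- B %*% Tg
      out_sizes[g] <- r
    }
    Xs <- do.call(cbind, blocks)
  }
  out_starts <- cumsum(c(1L, out_sizes[-G]))
  list(X = Xs, y = yc, ybar = ybar, centers = centers, scales = scales,
       ord = ord, grp_start = as.integer(out_starts),
       grp_len = as.integer(out_sizes), orig_sizes = sizes,
       orig_starts = as.integer(starts), transforms = transforms, n = n,
       G = G)
}

# Map a coefficient vector on the standardized (possibly orthonormalized)
# basis back to the original columns and order; returns list(beta, intercept).
unstandardize_beta <- function(std, design, b) {
  p <- design$p
  if (is.null(std)) { # standardize = FALSE: identity transform
    return(list(beta = b, intercept = 0))
  }
  beta_ord <- numeric(p)
  if (!is.null(std$transforms)) {
    for (g in seq_len(std$G)) {
      cols_out <- std$grp_start[g]:(std$grp_start[g] + std$grp_len[g] - 1L)
      cols_in <- std$orig_starts[g]:(std$orig_starts[g] + std$orig_sizes[g] - 1L)
      beta_ord[cols_in] <- std$transforms[[g]] %*% b[cols_out]
    }
  } else {
    beta_ord <- b
  }
  beta_ord <- beta_ord / std$scales
  beta <- numeric(p)
  beta[std$ord] <- beta_ord
  intercept <- std$ybar - sum(std$centers * beta_ord)
  list(beta = beta, intercept = intercept)
}
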