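# Independent oracles used across the suite. These reimplement the penalty
# definitions directly from their closed forms and minimize objectives by
# brute-force search, so they share no code with the solver path they check.

# penalty definitions, written out independently
oracle_pen <- function(b, family, lam, gam = NA, lam2 = 0, w = 1) {
  t <- abs(b)
  switch(family,
    lasso = lam * t,
    alasso = lam * w * t,
    enet = lam * t + lam2 * t^2,
    scad = if (t <= lam) lam * t
           else if (t <= gam * lam)
             -(t^2 - 2 * gam * lam * t + lam^2) / (2 * (gam - 1))
           else (gam + 1) * lam^2 / 2,
    mcp = if (t <= gam * lam) lam * t - t^2 / (2 * gam)
          else gam * lam^2 / 2)
}

# Brute-force minimizer of (d/2) b^2 - z b + pen(|b|): dense grid then
# local refinement with optimize() in the winning bracket.
oracle_scalar_min <- function(z, family, lam, gam = NA, lam2 = 0, w = 1,
                              d = 1) {
  f <- function(b) d / 2 * b^2 - z * b +
    oracle_pen(b, family, lam, gam, lam2, w)
  hi <- abs(z) / d + 1
  grid <- seq(-hi, hi, length.out = 4001)
  vals <- vapply(grid, f, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1, 1)]
  up <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(f, c(lo, up), tol = 1e-12)
  cand <- c(opt$minimum, 0) # zero is always a kink candidate
  cand[which.min(vapply(cand, f, numeric(1)))]
}

# Radial brute-force minimizer of (d/2)||b||^2 - z'b + pen(||b||).
oracle_group_min <- function(z, family, lam, gam = NA, d = 1) {
  nz <- sqrt(sum(z^2))
  sfam <- switch(family, grlasso = "lasso", grscad = "scad", grmcp = "mcp")
  t <- oracle_scalar_min(nz, sfam, lam, gam, d = d)
  if (nz == 0) return(numeric(length(z)))
  z * (t / nz)
}

# Orthonormal design with X'X/n = I (and zero column means), so closed-form
# thresholding solutions are exact.
make_orthonormal_design <- function(n, p, group_size, seed) {
  stopifnot(n > p)
  set.seed(seed)
  M <- matrix(rnorm(n * (p + 1)), n, p + 1)
  M[, 1] <- 1
  Q <- qr.Q(qr(M))[, -1, drop = FALSE] # orthogonal to the intercept
  X <- Q * sqrt(n)
  grp <- rep(seq_len(p / group_size), each = group_size)
  list(X = X, groups = grp)
}

# Exhaustive-enumeration oracle for the group-subset objective on designs
# with orthonormal groups (X_g'X_g/n = I, cross-group orthogonal): every
# subset decouples, and the within-subset solution is the group soft
# threshold of z_g = X_g'y/n.
oracle_grsubset_enum <- function(X, y, groups, lambda0, lambda1) {
  n <- nrow(X)
  G <- max(groups)
  best <- list(obj = Inf, active = integer(0), v = numeric(ncol(X)),
               gap = Inf) # gap to the best solution with a different support
  z <- lapply(seq_len(G), function(g)
    as.numeric(crossprod(X[, groups == g, drop = FALSE], y)) / n)
  for (mask in 0:(2^G - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(G) - 1)) > 0)
    v <- numeric(ncol(X))
    pen <- 0
    for (g in S) {
      m <- sum(groups == g)
      l1g <- lambda1 * sqrt(m)
      zg <- z[[g]]
      nzg <- sqrt(sum(zg^2))
      vg <- if (nzg > 0) max(1 - l1g / nzg, 0) * zg else zg * 0
      v[groups == g] <- vg
      pen <- pen + lambda0 * m + l1g * sqrt(sum(vg^2))
    }
    obj <- 0.5 * mean((y - X %*% v)^2) + pen
    act <- S[vapply(S, function(g) any(v[groups == g] != 0), logical(1))]
    if (obj < best$obj) {
      gap <- if (setequal(act, best$active)) best$gap else best$obj - obj
      best <- list(obj = obj, active = act, v = v, gap = gap)
    } else if (!setequal(act, best$active)) {
      best$gap <- min(best$gap, obj - best$obj)
    }
  }
  best
}

# Small random regression fixture.
random_design <- function(n, p, group_size, seed, rho = 0.3, snr_beta = 1) {
  set.seed(seed)
  G <- p / group_size
  U <- matrix(rnorm(n * G), n, G)
  X <- sqrt(rho) * U[, rep(seq_len(G), each = group_size)] +
    sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
  beta <- rnorm(p) * snr_beta * rbinom(p, 1, 0.5)
  y <- as.numeric(X %*% beta + rnorm(n))
  grouped_design(X, y, rep(seq_len(G), each = group_size))
}
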