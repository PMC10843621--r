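# Coordinate-descent solvers: null models, closed forms, KKT conditions,
# descent, and the group-subset machinery.

test_that("grouped_design validates its inputs", {
  X <- matrix(1:12, 4, 3)
  expect_error(grouped_design(X, 1:3, c(1, 1, 2)), "length")
  expect_error(grouped_design(X, 1:4, c(1, 1)), "one label per column")
  X2 <- X; X2[1, 1] <- NA
  expect_error(grouped_design(X2, 1:4, c(1, 1, 2)), "non-finite")
  d <- grouped_design(X, c(1, 3, 2, 4), c("a", "a", "b"))
  expect_equal(d$G, 2)
  expect_equal(d$group_sizes, c(2L, 1L))
})

test_that("lambda >= lambda_max yields the null model for every family", {
  d <- random_design(60, 12, 3, seed = 11)
  for (fam in c("lasso", "scad", "mcp", "enet", "alasso")) {
    lm_ <- lambda_max(d, fam)
    f <- fit_penalized(d, penalty_config(fam, lambda = lm_ * 1.000001))
    expect_true(all(f$beta == 0), info = fam)
    expect_equal(f$intercept, mean(d$y), info = fam)
    f2 <- suppressWarnings(
      fit_penalized(d, penalty_config(fam, lambda = lm_ * 0.99)))
    expect_true(any(f2$beta != 0), info = fam)
  }
  for (fam in c("grlasso", "grscad", "grmcp")) {
    lm_ <- lambda_max(d, fam)
    f <- fit_group_penalized(d, penalty_config(fam, lambda = lm_ * 1.000001))
    expect_true(all(f$beta == 0), info = fam)
    expect_equal(f$intercept, mean(d$y), info = fam)
    f2 <- fit_group_penalized(d, penalty_config(fam, lambda = lm_ * 0.99))
    expect_true(any(f2$beta != 0), info = fam)
    expect_equal(length(f$active_groups), 0)
  }
})

test_that("solvers equal closed-form thresholding on orthonormal designs", {
  od <- make_orthonormal_design(60, 12, 3, seed = 21)
  set.seed(22)
  y <- rnorm(60, sd = 2)
  d <- grouped_design(od$X, y, od$groups)
  z <- as.numeric(crossprod(od$X, y)) / 60
  for (fam in c("lasso", "scad", "mcp")) {
    cfg <- penalty_config(fam, lambda = 0.2)
    f <- fit_penalized(d, cfg, standardize = FALSE, tol = 1e-10)
    expect_equal(unname(f$beta), scalar_threshold(z, cfg),
                 tolerance = 1e-8, info = fam)
  }
  for (fam in c("grlasso", "grscad", "grmcp")) {
    cfg <- penalty_config(fam, lambda = 0.2 / sqrt(3)) # undo sqrt(m_g)
    f <- fit_group_penalized(d, penalty_config(fam, lambda = 0.2 / sqrt(3)),
                             standardize = FALSE, tol = 1e-10)
    want <- unlist(lapply(1:4, function(g)
      group_threshold(z[od$groups == g],
                      penalty_config(fam, lambda = 0.2))))
    expect_equal(unname(f$beta), want, tolerance = 1e-8, info = fam)
  }
})

test_that("lambda = 0 with n > p recovers least squares", {
  d <- random_design(80, 10, 2, seed = 31)
  f <- fit_penalized(d, penalty_config("lasso", lambda = 0), tol = 1e-9)
  ls <- stats::lm(d$y ~ d$X)
  expect_equal(unname(f$beta), unname(coef(ls)[-1]), tolerance = 1e-6)
  expect_equal(f$intercept, unname(coef(ls)[1]), tolerance = 1e-6)
  fg <- fit_group_penalized(d, penalty_config("grlasso", lambda = 0),
                            tol = 1e-9)
  expect_equal(unname(fg$beta), unname(coef(ls)[-1]), tolerance = 1e-6)
})

test_that("KKT conditions hold for lasso and group-lasso fits", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(20:50, 1)
    G <- sample(2:6, 1)
    m <- sample(2:4, 1)
    p <- G * m
    d <- random_design(n, p, m, seed = s + 100)
    std <- grpstack:::standardize_design(d)
    lamf <- 0.3 * suppressWarnings(lambda_max(d, "lasso"))
    f <- fit_penalized(d, penalty_config("lasso", lambda = lamf),
                       tol = 1e-8)
    bstd <- f$beta[std$ord] * std$scales
    # on the standardized scale: |x_j'r/n| <= lambda (inactive),
    # x_j'r/n = lambda sign(b_j) (active)
    r <- std$y - std$X %*% bstd
    g <- as.numeric(crossprod(std$X, r)) / n
    act <- bstd != 0
    expect_true(all(abs(g[!act]) <= lamf + 1e-7))
    if (any(act))
      expect_true(all(abs(g[act] - lamf * sign(bstd[act])) <= 1e-7))
  }
  # group lasso: block KKT on the orthonormalized design
  od <- make_orthonormal_design(50, 12, 3, seed = 41)
  set.seed(42)
  y <- rnorm(50, 2)
  d <- grouped_design(od$X, y, od$groups)
  lamg <- 0.4 * suppressWarnings(
    lambda_max(d, "grlasso", group_multiplier = FALSE))
  f <- fit_group_penalized(d, penalty_config("grlasso", lambda = lamg),
                           standardize = FALSE, group_multiplier = FALSE,
                           tol = 1e-9)
  r <- y - od$X %*% f$beta
  for (g in 1:4) {
    zg <- as.numeric(crossprod(od$X[, od$groups == g], r)) / 50
    bg <- f$beta[od$groups == g]
    if (all(bg == 0)) {
      expect_lte(sqrt(sum(zg^2)), lamg + 1e-7)
    } else {
      expect_equal(zg, unname(lamg * bg / sqrt(sum(bg^2))),
                   tolerance = 1e-6)
    }
  }
})

test_that("path objectives are nonincreasing in the penalty level", {
  d <- random_design(60, 12, 3, seed = 51)
  for (fam in c("lasso", "grlasso")) {
    p <- fit_path(d, fam, nlambda = 30)
    expect_true(all(diff(p$objective) <= 1e-8), info = fam)
    # the fit at each lambda beats the null model under the same penalty
    std <- grpstack:::standardize_design(d, orthonormalize = fam == "grlasso")
    expect_true(all(p$objective <= 0.5 * mean(std$y^2) + 1e-10), info = fam)
  }
})

test_that("non-convergence returns a flagged fit with a warning", {
  d <- random_design(50, 10, 2, seed = 61)
  expect_warning(
    f <- fit_penalized(d, penalty_config("lasso", lambda = 1e-4),
                       max_iter = 2),
    "converge")
  expect_false(f$converged)
  expect_true(is.finite(f$objective))
})

test_that("group-subset CD matches exhaustive enumeration on orthogonal designs", {
  for (s in 1:12) {
    od <- make_orthonormal_design(40, 8, 2, seed = 70 + s)
    set.seed(700 + s)
    beta <- c(rnorm(2, 3), numeric(6))
    y <- as.numeric(od$X %*% beta + rnorm(40, sd = 0.5))
    d <- grouped_design(od$X, y, od$groups)
    lam1 <- runif(1, 0, 0.3)
    path <- fit_group_subset(d, lambda1 = lam1, shrink_family = "grlasso",
                             alpha = 0.3, standardize = FALSE, tol = 1e-9)
    for (i in seq_along(path$lambda)) {
      or <- oracle_grsubset_enum(od$X, y, od$groups, path$lambda[i], lam1)
      expect_equal(path$objective[i], or$obj, tolerance = 1e-6)
      # the grid anchor is an exact tie between supports by construction;
      # compare supports only where the optimum is unique
      if (or$gap > 1e-8)
        expect_setequal(path$active[[i]], as.character(or$active))
    }
  }
})

test_that("the adaptive lambda0 grid is anchored and strictly decreasing", {
  d <- random_design(80, 16, 4, seed = 81)
  path <- fit_group_subset(d, shrink_family = "none", alpha = 0.5)
  expect_true(all(path$betas[, 1] == 0)) # first point: empty active set
  expect_true(all(diff(path$lambda) < 0))
  expect_equal(length(path$active[[length(path$lambda)]]), d$G)
  # each grid point admits at least one new group
  sizes <- vapply(path$active, length, integer(1))
  expect_true(all(diff(sizes) >= 1))
  # objective at every grid point beats the all-zero model
  expect_true(all(path$objective <= 0.5 * mean((d$y - mean(d$y))^2) + 1e-10))
})

test_that("next_lambda0 implements the adaptive-grid formula", {
  st <- structure(
    list(gradnorm = c(3, 1), active_set = 2L, block_constants = c(1, 1),
         group_sizes = c(2, 2), lambda1k = c(1, 1), alpha = 0.5,
         lambda0 = 2),
    class = "group_subset_state")
  expect_equal(next_lambda0(st), 0.5 * (3 - 1)^2 / (2 * 2 * 1))
  st$alpha <- 0
  expect_equal(next_lambda0(st), 0)
  st$alpha <- 0.5
  st$gradnorm <- c(0.5, 0.2) # below lambda1k: positive part annihilates
  expect_equal(next_lambda0(st), 0)
  st$active_set <- c(1L, 2L)
  expect_warning(out <- next_lambda0(st), "exhausted")
  expect_true(is.na(out))
  # consistency with the grids fit_group_subset generates
  d <- random_design(60, 12, 3, seed = 91)
  path <- fit_group_subset(d, lambda1 = 0.1, shrink_family = "grlasso",
                           alpha = 0.4)
  for (i in seq_len(length(path$lambda) - 1))
    expect_equal(next_lambda0(path$states[[i]]), path$lambda[i + 1])
})

test_that("warm-started convex paths have stable active sets", {
  d <- random_design(70, 12, 3, seed = 101)
  p <- fit_path(d, "grlasso", nlambda = 40)
  acts <- lapply(p$active, identity)
  for (i in 2:(length(acts) - 1)) {
    nb <- union(acts[[i - 1]], acts[[i + 1]])
    extra <- setdiff(acts[[i]], nb)
    expect_length(extra, 0)
  }
})
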