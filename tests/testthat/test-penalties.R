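# Penalty evaluations and thresholding (proximal) operators.

test_that("penalty_value matches the piecewise closed forms", {
  scad <- penalty_config("scad", lambda = 1, gamma = 3.7)
  expect_equal(penalty_value(0, scad), 0)
  expect_equal(penalty_value(0.5, scad), 0.5) # first branch: lambda*|b|
  expect_equal(penalty_value(10, scad), (3.7 + 1) * 1 / 2) # constant branch
  mcp <- penalty_config("mcp", lambda = 1, gamma = 3)
  expect_equal(penalty_value(1, mcp), 1 - 1 / 6) # lambda|b| - b^2/(2 gamma)
  expect_equal(penalty_value(0, mcp), 0)
  las <- penalty_config("lasso", lambda = 2)
  expect_equal(penalty_value(c(0, 1, 2.5), las), c(0, 2, 5))
  expect_error(penalty_value(-1, las), "nonneg")
})

test_that("penalty_value is continuous at the SCAD/MCP branch boundaries", {
  for (lam in c(0.3, 1, 2.5)) {
    scad <- penalty_config("scad", lambda = lam, gamma = 3.7)
    eps <- 1e-9
    expect_lt(abs(penalty_value(lam - eps, scad) -
                    penalty_value(lam + eps, scad)), 1e-7)
    expect_lt(abs(penalty_value(3.7 * lam - eps, scad) -
                    penalty_value(3.7 * lam + eps, scad)), 1e-7)
    mcp <- penalty_config("mcp", lambda = lam, gamma = 3)
    expect_lt(abs(penalty_value(3 * lam - eps, mcp) -
                    penalty_value(3 * lam + eps, mcp)), 1e-7)
  }
})

test_that("soft_threshold matches its closed form", {
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(3.2, 0), 3.2)
  expect_equal(soft_threshold(-2, 0.5), -1.5)
  expect_equal(soft_threshold(2, 0.5), 1.5)
})

test_that("scalar_threshold solves the coordinate subproblem exactly", {
  mcp <- penalty_config("mcp", lambda = 1, gamma = 3)
  expect_equal(scalar_threshold(3, mcp), 3) # |z| >= gamma*lambda: unbiased
  las <- penalty_config("lasso", lambda = 1)
  expect_equal(scalar_threshold(1.5, las), 0.5)
  for (cfg in list(las, mcp, penalty_config("scad", lambda = 1)))
    expect_equal(scalar_threshold(0, cfg), 0)
  expect_error(scalar_threshold(1, penalty_config("mcp", gamma = 1.5),
                                denom = 0.5), "gamma")
})

test_that("thresholding operators agree with brute-force minimization", {
  set.seed(1)
  fams <- c("lasso", "scad", "mcp", "enet", "alasso")
  for (i in 1:60) {
    z <- runif(1, -6, 6)
    lam <- runif(1, 0.01, 2)
    d <- runif(1, 0.6, 2)
    fam <- sample(fams, 1)
    gam <- if (fam == "scad") runif(1, 2.2, 6) else runif(1, 1.6, 6)
    if (fam == "mcp" && gam * d <= 1.1) gam <- 1.5 / d + 1
    lam2 <- runif(1, 0, 1)
    w <- runif(1, 0.2, 3)
    cfg <- penalty_config(fam, lambda = lam, gamma = gam, lambda2 = lam2,
                          weights = if (fam == "alasso") w else NULL)
    got <- scalar_threshold(z, cfg, denom = d)
    want <- oracle_scalar_min(z, fam, lam, gam, lam2, w, d)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("group thresholding matches its closed form and radial oracle", {
  grl <- penalty_config("grlasso", lambda = 1)
  expect_equal(group_threshold(c(3, 4), grl), c(2.4, 3.2)) # factor 1-1/5
  expect_equal(group_threshold(c(0.3, 0.4), grl), c(0, 0)) # ||z|| <= lambda
  grs <- penalty_config("grscad", lambda = 1, gamma = 3.7)
  z <- c(6, 8) # ||z|| = 10 >= gamma*lambda: unpenalized region
  expect_equal(group_threshold(z, grs), z)
  set.seed(2)
  for (i in 1:40) {
    m <- sample(2:5, 1)
    z <- rnorm(m, sd = 2)
    lam <- runif(1, 0.05, 2)
    fam <- sample(c("grlasso", "grscad", "grmcp"), 1)
    gam <- if (fam == "grscad") runif(1, 2.2, 6) else runif(1, 1.6, 6)
    cfg <- penalty_config(fam, lambda = lam, gamma = gam)
    expect_equal(group_threshold(z, cfg),
                 oracle_group_min(z, fam, lam, gam), tolerance = 1e-6)
  }
  expect_error(group_threshold(numeric(0), grl), "empty")
})

test_that("family identities and monotone shrinkage hold", {
  set.seed(3)
  z <- rnorm(30, sd = 3)
  for (lam in c(0.1, 0.7, 1.5)) {
    las <- penalty_config("lasso", lambda = lam)
    enet0 <- penalty_config("enet", lambda = lam, lambda2 = 0)
    ala1 <- penalty_config("alasso", lambda = lam, weights = 1)
    expect_equal(scalar_threshold(z, enet0), scalar_threshold(z, las))
    expect_equal(scalar_threshold(z, ala1), scalar_threshold(z, las))
  }
  lams <- seq(0, 3, by = 0.25)
  for (zi in z[1:10]) {
    out <- vapply(lams, function(l)
      abs(scalar_threshold(zi, penalty_config("lasso", lambda = l))),
      numeric(1))
    expect_true(all(out <= abs(zi) + 1e-12))
    expect_true(all(diff(out) <= 1e-12)) # nonincreasing in lambda
  }
  zg <- c(1.5, -2, 0.5)
  norms <- vapply(lams, function(l) sqrt(sum(
    group_threshold(zg, penalty_config("grlasso", lambda = l))^2)),
    numeric(1))
  expect_true(all(norms <= sqrt(sum(zg^2)) + 1e-12))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("penalty_config validates parameter domains", {
  expect_error(penalty_config("scad", gamma = 2), "gamma > 2")
  expect_error(penalty_config("mcp", gamma = 1), "gamma > 1")
  expect_error(penalty_config("lasso", lambda = -1), "nonnegative")
  expect_error(penalty_config("alasso", weights = c(-1, 1)), "weights")
  expect_equal(penalty_config("scad")$gamma, 3.7)
  expect_equal(penalty_config("mcp")$gamma, 3)
})
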