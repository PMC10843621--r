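# Out-of-fold stacking machinery.

test_that("make_folds produces near-equal seeded partitions", {
  f <- make_folds(10, 5, seed = 1)
  expect_equal(unname(tabulate(f, 5)), rep(2L, 5))
  f2 <- make_folds(7, 5, seed = 1)
  expect_equal(sort(tabulate(f2, 5)), c(1L, 1L, 1L, 2L, 2L))
  expect_identical(make_folds(20, 4, seed = 3), make_folds(20, 4, seed = 3))
  expect_false(identical(make_folds(20, 4, seed = 3),
                         make_folds(20, 4, seed = 4)))
  expect_error(make_folds(10, 1), "at least 2")
  expect_error(make_folds(3, 5), "exceed")
})

test_that("out-of-fold predictions of the null learner are leave-block-out means", {
  y <- 1:5
  d <- grouped_design(matrix(rnorm(5), 5, 1), y, 1)
  folds <- 1:5 # one observation per fold
  Z <- oof_meta_features(d, list("intercept", "intercept"), folds)
  expect_equal(unname(Z[, 1]), c(3.5, 3.25, 3.0, 2.75, 2.5))
  # duplicate learner duplicates the column
  expect_equal(Z[, 1], unname(Z[, 2]), ignore_attr = TRUE)
  expect_equal(nrow(Z), 5) # same size as the original data
})

test_that("out-of-fold predictions never see their own response", {
  d <- random_design(40, 8, 2, seed = 15)
  folds <- make_folds(40, 4, seed = 2)
  cfg <- penalty_config("grlasso", lambda = 0.1)
  Z <- oof_meta_features(d, list(cfg), folds)
  i <- which(folds == 1)[1]
  y2 <- d$y
  y2[i] <- y2[i] + 1000
  d2 <- grouped_design(d$X, y2, d$groups)
  Z2 <- oof_meta_features(d2, list(cfg), folds)
  expect_equal(Z[i, 1], Z2[i, 1]) # row i's fold never trains on row i
  expect_false(isTRUE(all.equal(Z[-i, 1], Z2[-i, 1])))
})

test_that("failing base learners are dropped with a warning", {
  d <- random_design(30, 6, 2, seed = 16)
  bad <- structure(list(family = "nonsense"), class = "penalty_config")
  expect_warning(
    Z <- oof_meta_features(d, list("grlasso", "lasso", bad),
                           make_folds(30, 3, seed = 1)),
    "dropping")
  expect_equal(ncol(Z), 2)
  expect_equal(attr(Z, "dropped"), "nonsense")
})

test_that("stacking rides a base learner that predicts exactly", {
  # noiseless group-sparse truth: the group-lasso base can fit it almost
  # perfectly, and the meta-learner should lean on it
  od <- make_orthonormal_design(60, 12, 3, seed = 17)
  beta <- c(rep(2, 3), rep(0, 6), rep(-1, 3))
  y <- as.numeric(od$X %*% beta)
  d <- grouped_design(od$X, y, od$groups)
  m <- suppressWarnings(
    fit_stacking(d, base_families = c("grlasso", "intercept"), K = 5,
                 seed = 4, nlambda = 50))
  oof_rmse <- rmse(y, as.numeric(m$meta_features %*% m$meta_fit$beta) +
                     m$meta_fit$intercept)
  expect_lt(oof_rmse, 0.05 * stats::sd(y))
  expect_gt(m$meta_fit$beta["grlasso"], 0.9)
  expect_lt(abs(m$meta_fit$beta["intercept"]), 0.1)
  expect_lt(rmse(y, predict(m, od$X)), 0.05 * stats::sd(y))
})

test_that("uninformative meta-features degrade to the mean predictor", {
  set.seed(108)
  d <- grouped_design(matrix(rnorm(60), 30, 2), rnorm(30), c(1, 2))
  expect_warning(
    m <- fit_stacking(d, base_families = c("intercept", "intercept"),
                      K = 5, seed = 8),
    "intercept")
  expect_true(all(m$meta_fit$beta == 0))
  p <- predict(m, d$X)
  expect_equal(stats::sd(p), 0, tolerance = 1e-10)
  expect_equal(p[1], mean(d$y))
})

test_that("predictions compose base refits with the meta-coefficients", {
  d <- random_design(50, 8, 2, seed = 19)
  m <- suppressWarnings(
    fit_stacking(d, base_families = c("grlasso", "lasso"), K = 5, seed = 6,
                 nlambda = 30))
  Znew <- vapply(m$refit_base_fits, predict, numeric(d$n), newdata = d$X)
  want <- m$meta_fit$intercept + as.numeric(Znew %*% m$meta_fit$beta)
  expect_equal(predict(m, d$X), want)
})

test_that("stacking is deterministic end to end", {
  d <- random_design(45, 8, 2, seed = 20)
  m1 <- suppressWarnings(fit_stacking(d, base_families = c("grlasso", "lasso"),
                                      K = 5, seed = 7, nlambda = 25))
  m2 <- suppressWarnings(fit_stacking(d, base_families = c("grlasso", "lasso"),
                                      K = 5, seed = 7, nlambda = 25))
  expect_identical(m1$meta_features, m2$meta_features)
  expect_identical(m1$meta_coefficients, m2$meta_coefficients)
  expect_identical(predict(m1, d$X), predict(m2, d$X))
})

test_that("the meta-learner is this package's lasso solver", {
  d <- random_design(40, 8, 2, seed = 21)
  m <- suppressWarnings(fit_stacking(d, base_families = c("grlasso", "lasso"),
                                     K = 4, seed = 8, nlambda = 25))
  md <- grouped_design(m$meta_features, d$y, seq_len(ncol(m$meta_features)),
                       column_names = colnames(m$meta_features))
  refit <- fit_penalized(md, m$meta_fit$config, tol = 1e-5)
  expect_equal(refit$beta, m$meta_fit$beta, tolerance = 1e-6)
  expect_equal(refit$intercept, m$meta_fit$intercept, tolerance = 1e-6)
})

test_that("base-learner diagnostics flag redundant candidates", {
  d <- random_design(50, 8, 2, seed = 22)
  cfg <- penalty_config("grlasso", lambda = 0.1)
  diag <- suppressWarnings(
    base_learner_diagnostics(d, list(cfg, cfg), K = 5, seed = 9))
  expect_equal(diag$residual_cor[1, 2], 1, tolerance = 1e-10)
  expect_length(diag$recommended, 1) # the duplicate is excluded
  expect_equal(nrow(diag$table), 2)
  expect_true(all(c("rmse", "mae", "r2") %in% colnames(diag$table)))
})

test_that("independent residuals have near-zero correlation", {
  # two synthetic 'learners' whose residuals are independent noise
  set.seed(23)
  n <- 4000
  y <- rnorm(n)
  folds <- make_folds(n, 5, seed = 1)
  z1 <- y + rnorm(n)
  z2 <- y + rnorm(n)
  rc <- stats::cor(cbind(y - z1, y - z2))
  expect_lt(abs(rc[1, 2]), 3 / sqrt(n))
})

test_that("stacking models survive a JSON round trip", {
  d <- random_design(40, 8, 2, seed = 24)
  m <- suppressWarnings(fit_stacking(d, base_families = c("grlasso", "lasso"),
                                     K = 4, seed = 10, nlambda = 25))
  path <- file.path(tempdir(), "model.json")
  write_stacking_json(m, path)
  m2 <- read_stacking_json(path)
  Xnew <- d$X[1:7, ]
  expect_equal(predict(m2, Xnew), predict(m, Xnew), tolerance = 1e-12)
  unlink(path)
})

test_that("the disjoint split mode trains each base on its own subset", {
  d <- random_design(60, 8, 2, seed = 25)
  m <- suppressWarnings(
    fit_stacking(d, base_families = c("grlasso", "lasso"), K = 5, seed = 11,
                 split_mode = "disjoint", nlambda = 25))
  expect_equal(max(m$fold_labels), 2) # one block per base learner
  expect_length(predict(m, d$X), d$n)
})
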