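# Stacking ensemble: out-of-fold meta-features from group-penalized base
# learners, a lasso meta-learner, prediction, and base-learner diagnostics.

#' Seeded K-fold partition
#'
#' Random partition of `1:n` into `K` folds whose sizes differ by at most
#' one; deterministic given `seed` and independent of the caller's RNG
#' state.
#'
#' @param n Number of observations.
#' @param K Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1:K`.
#' @export
make_folds <- function(n, K = 5, seed = 1) {
  if (K < 2) stop("'K' must be at least 2")
  if (K > n) stop("'K' cannot exceed n")
  sizes <- rep(floor(n / K), K) + (seq_len(K) <= n %% K)
  labels <- integer(n)
  with_seed(seed, {
    perm <- sample.int(n)
    labels[perm] <- rep(seq_len(K), times = sizes)
  })
  labels
}

# Tune-and-fit one base learner on a training design. A character spec is
# tuned by inner cross-validation; a penalty_config is fit directly.
fit_base_learner <- function(design, spec, inner_K, seed, nlambda,
                             n_secondary, tol, max_iter) {
  if (inherits(spec, "penalty_config")) {
    fam <- spec$family
    if (fam %in% SCALAR_FAMILIES) return(fit_penalized(design, spec,
                                                       tol = tol,
                                                       max_iter = max_iter))
    if (fam %in% GROUP_FAMILIES) return(fit_group_penalized(design, spec,
                                                            tol = tol,
                                                            max_iter = max_iter))
    shrink <- switch(fam, grsubset = "none", grsubset_grlasso = "grlasso",
                     grsubset_ridge = "ridge")
    path <- fit_group_subset(design, lambda1 = spec$lambda1,
                             lambda2 = spec$lambda2, shrink_family = shrink,
                             lambda0 = spec$lambda0, tol = tol,
                             max_iter = max_iter)
    return(path_fit(path, length(path$lambda)))
  }
  if (identical(spec, "intercept")) return(intercept_fit(design))
  cv <- cross_validate(design, spec, K = inner_K, seed = seed,
                       nlambda = nlambda, n_secondary = n_secondary,
                       tol = tol, max_iter = max_iter)
  cv$best_fit
}

#' Out-of-fold meta-feature matrix
#'
#' `Z[i, b]` is base learner `b`'s prediction for row `i` from a model fit
#' on the folds excluding row `i`'s fold, so the matrix has exactly `n`
#' rows and no entry is produced by a model whose training data contained
#' that row. Character base specs are tuned by inner cross-validation on
#' each training fold (seeded deterministically from `seed`); fixed
#' [penalty_config()] specs are fit directly.
#'
#' @param design A [grouped_design()].
#' @param base_configs List (or character vector) of base-learner specs:
#'   family names, `"intercept"`, or [penalty_config()] objects.
#' @param folds Fold labels from [make_folds()].
#' @param inner_K Inner CV folds for tuning (default 5).
#' @param seed Master seed for the inner CV fold assignments.
#' @param nlambda,n_secondary,tol,max_iter Tuning/solver controls.
#' @return `n x B` matrix of out-of-fold predictions, with base names as
#'   column names and a `"dropped"` attribute naming learners whose fits
#'   failed (dropped with a warning).
#' @export
oof_meta_features <- function(design, base_configs, folds, inner_K = 5,
                              seed = 1, nlambda = 100, n_secondary = NULL,
                              tol = 1e-5, max_iter = 10000) {
  if (is.character(base_configs)) base_configs <- as.list(base_configs)
  B <- length(base_configs)
  K <- max(folds)
  names_b <- vapply(seq_len(B), function(b) {
    s <- base_configs[[b]]
    if (is.character(s)) s else s$family
  }, character(1))
  Z <- matrix(NA_real_, design$n, B, dimnames = list(NULL, make.unique(names_b)))
  failed <- logical(B)
  for (b in seq_len(B)) {
    ok <- TRUE
    for (k in seq_len(K)) {
      idx <- which(folds == k)
      tr <- subset_design(design, which(folds != k))
      fit <- tryCatch(
        suppressWarnings(
          fit_base_learner(tr, base_configs[[b]], inner_K,
                           seed = derive_seed(seed, b, k), nlambda = nlambda,
                           n_secondary = n_secondary, tol = tol,
                           max_iter = max_iter)),
        error = function(e) e)
      if (inherits(fit, "error")) { ok <- FALSE; break }
      Z[idx, b] <- predict(fit, design$X[idx, , drop = FALSE])
    }
    failed[b] <- !ok
  }
  if (any(failed)) {
    warning("dropping failed base learner(s): ",
            paste(names_b[failed], collapse = ", "))
  }
  out <- Z[, !failed, drop = FALSE]
  attr(out, "dropped") <- names_b[failed]
  out
}

#' Fit a stacking ensemble of group-penalized base learners
#'
#' The StackingGroup estimator: each base learner's out-of-fold predictions
#' on a seeded K-fold partition form the meta-feature matrix `Z`; a lasso
#' meta-learner (this package's own solver, with an unpenalized intercept
#' and lambda chosen by inner CV) is fit to `(Z, y)`; and every base
#' learner is refit on the full data for prediction time. Base-learner
#' hyperparameters are tuned by inner cross-validation within each training
#' fold, so no fold's responses leak into its own meta-features.
#'
#' The default base learners are the group-subset + group-lasso estimator,
#' the group lasso, and group SCAD; `"lasso"` can be added as a fourth.
#'
#' @param design A [grouped_design()].
#' @param base_families Character vector (length >= 2) of base-learner
#'   families.
#' @param K Outer fold count (default 5).
#' @param seed Master seed; all fold assignments and inner CVs derive from
#'   it, so results are fully reproducible.
#' @param split_mode `"kfold"` (standard out-of-fold stacking) or
#'   `"disjoint"` (each base learner is trained on its own disjoint subset
#'   of the data; a fidelity mode, see the vignette).
#' @param inner_K,nlambda,n_secondary,tol,max_iter Tuning/solver controls.
#' @return A `"stacking_model"` with the meta-feature matrix, fold labels,
#'   meta-learner fit and coefficients, and full-data base refits.
#' @export
fit_stacking <- function(design,
                         base_families = c("grsubset_grlasso", "grlasso",
                                           "grscad"),
                         K = 5, seed = 1,
                         split_mode = c("kfold", "disjoint"),
                         inner_K = 5, nlambda = 100, n_secondary = NULL,
                         tol = 1e-5, max_iter = 10000) {
  split_mode <- match.arg(split_mode)
  if (length(base_families) < 2) stop("need at least 2 base learners")
  B0 <- length(base_families)
  if (split_mode == "kfold") {
    folds <- make_folds(design$n, K, seed)
    Z <- oof_meta_features(design, base_families, folds, inner_K = inner_K,
                           seed = seed, nlambda = nlambda,
                           n_secondary = n_secondary, tol = tol,
                           max_iter = max_iter)
  } else {
    # disjoint fidelity mode: base b is trained only on its own subset
    folds <- make_folds(design$n, B0, seed)
    Z <- matrix(NA_real_, design$n, B0,
                dimnames = list(NULL, make.unique(base_families)))
    for (b in seq_len(B0)) {
      tr <- subset_design(design, which(folds == b))
      fit <- suppressWarnings(
        fit_base_learner(tr, base_families[[b]], inner_K,
                         seed = derive_seed(seed, b, 0), nlambda = nlambda,
                         n_secondary = n_secondary, tol = tol,
                         max_iter = max_iter))
      Z[, b] <- predict(fit, design$X)
    }
    attr(Z, "dropped") <- character(0)
  }
  dropped <- attr(Z, "dropped")
  if (ncol(Z) < 2) stop("fewer than 2 base learners survived fitting")
  kept <- setdiff(make.unique(base_families), dropped)

  meta_design <- grouped_design(Z, design$y, groups = seq_len(ncol(Z)),
                                column_names = colnames(Z))
  meta_cv <- cross_validate(meta_design, "lasso", K = inner_K,
                            seed = derive_seed(seed, 0, 0),
                            nlambda = nlambda, tol = tol,
                            max_iter = max_iter)
  meta_fit <- meta_cv$best_fit
  if (all(meta_fit$beta == 0))
    warning("meta-learner degenerated to the intercept (predicts the mean)")

  refits <- lapply(seq_along(kept), function(b) {
    suppressWarnings(
      fit_base_learner(design, base_families[[match(kept[b],
                                                    make.unique(base_families))]],
                       inner_K, seed = derive_seed(seed, b, K + 1L),
                       nlambda = nlambda, n_secondary = n_secondary,
                       tol = tol, max_iter = max_iter))
  })
  names(refits) <- kept
  structure(
    list(base_families = kept, dropped = dropped, K = K, seed = seed,
         split_mode = split_mode, fold_labels = folds, meta_features = Z,
         meta_fit = meta_fit,
         meta_coefficients = c(intercept = meta_fit$intercept,
                               meta_fit$beta),
         refit_base_fits = refits, p = design$p,
         column_names = design$column_names),
    class = "stacking_model")
}

#' @export
print.stacking_model <- function(x, ...) {
  cat("<stacking_model> bases:", paste(x$base_families, collapse = ", "),
      "\n  meta coefficients:",
      paste(format(x$meta_coefficients, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Predict from a stacking model
#'
#' Each full-data base refit predicts on the new rows; the meta-learner's
#' coefficients combine those predictions.
#'
#' @param object A `"stacking_model"`.
#' @param newdata Numeric matrix with the training `p` columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.stacking_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) stop("newdata has wrong number of columns")
  Znew <- vapply(object$refit_base_fits, predict, numeric(nrow(newdata)),
                 newdata = newdata)
  if (nrow(newdata) == 1) Znew <- matrix(Znew, nrow = 1)
  predict(object$meta_fit, Znew)
}

#' Base-learner diagnostics for stacking
#'
#' Computes each candidate's out-of-fold RMSE, MAE and R-squared on a
#' shared fold partition, plus the pairwise correlation matrix of
#' out-of-fold residuals, and recommends a subset: starting from the
#' lowest-RMSE candidate, each further candidate is added if its RMSE is
#' within a factor `rmse_cap` of the best and its residual correlation
#' with every already-selected candidate is below `cor_cap`. If fewer than
#' two candidates qualify, the two lowest-RMSE candidates are recommended.
#'
#' @param design A [grouped_design()].
#' @param candidate_families Character vector (length >= 2).
#' @param K,seed Fold partition controls.
#' @param rmse_cap RMSE cap factor (default 1.25).
#' @param cor_cap Residual-correlation threshold (default 0.95).
#' @param ... Passed to [oof_meta_features()].
#' @return A list with `table` (per-candidate metrics), `residual_cor`, and
#'   `recommended`.
#' @export
base_learner_diagnostics <- function(design, candidate_families, K = 5,
                                     seed = 1, rmse_cap = 1.25,
                                     cor_cap = 0.95, ...) {
  if (length(candidate_families) < 2) stop("need at least 2 candidates")
  folds <- make_folds(design$n, K, seed)
  Z <- oof_meta_features(design, candidate_families, folds, seed = seed, ...)
  y <- design$y
  tab <- data.frame(
    family = colnames(Z),
    rmse = apply(Z, 2, function(z) rmse(y, z)),
    mae = apply(Z, 2, function(z) mae(y, z)),
    r2 = apply(Z, 2, function(z) r_squared(y, z)),
    row.names = NULL)
  resid <- y - Z
  rc <- stats::cor(resid)
  ord <- order(tab$rmse)
  best <- tab$rmse[ord[1]]
  selected <- colnames(Z)[ord[1]]
  for (j in ord[-1]) {
    fam <- colnames(Z)[j]
    if (tab$rmse[j] <= rmse_cap * best &&
        all(abs(rc[fam, selected]) < cor_cap))
      selected <- c(selected, fam)
  }
  if (length(selected) == 0) selected <- colnames(Z)[ord[seq_len(2)]]
  list(table = tab, residual_cor = rc, recommended = selected)
}

#' Serialize a stacking model to JSON
#'
#' Writes the base configurations, fold labels, meta-learner coefficients
#' and full-data base coefficients to a JSON document that
#' [read_stacking_json()] restores to a predict-capable model.
#'
#' @param model A `"stacking_model"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stacking_json <- function(model, path) {
  ser_fit <- function(f) list(
    family = f$family, intercept = f$intercept, beta = as.numeric(f$beta),
    lambda = f$config$lambda, gamma = f$config$gamma,
    lambda2 = f$config$lambda2, lambda0 = f$config$lambda0,
    lambda1 = f$config$lambda1)
  doc <- list(
    package = "grpstack", object = "stacking_model",
    base_families = model$base_families, K = model$K, seed = model$seed,
    split_mode = model$split_mode, fold_labels = model$fold_labels,
    column_names = model$column_names, p = model$p,
    meta = ser_fit(model$meta_fit),
    bases = lapply(model$refit_base_fits, ser_fit))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a stacking model from JSON
#'
#' @param path File written by [write_stacking_json()].
#' @return A predict-capable `"stacking_model"`.
#' @export
read_stacking_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$object, "stacking_model"))
    stop("not a stacking_model JSON document")
  de_fit <- function(f, nm) {
    cfg <- structure(list(family = f$family, lambda = f$lambda,
                          gamma = f$gamma, lambda2 = f$lambda2,
                          lambda0 = f$lambda0, lambda1 = f$lambda1,
                          weights = NULL), class = "penalty_config")
    beta <- stats::setNames(as.numeric(f$beta), nm)
    new_coef_fit(intercept = f$intercept, beta = beta,
                 groups = seq_along(beta), group_labels =
                   as.character(seq_along(beta)), objective = NA_real_,
                 converged = TRUE, iterations = NA_integer_, config = cfg)
  }
  bases <- lapply(doc$bases, de_fit, nm = doc$column_names)
  meta <- de_fit(doc$meta, nm = names(doc$bases))
  structure(
    list(base_families = doc$base_families, dropped = character(0),
         K = doc$K, seed = doc$seed, split_mode = doc$split_mode,
         fold_labels = doc$fold_labels, meta_features = NULL,
         meta_fit = meta,
         meta_coefficients = c(intercept = meta$intercept, meta$beta),
         refit_base_fits = bases, p = doc$p,
         column_names = doc$column_names),
    class = "stacking_model")
}
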