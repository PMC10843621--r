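---
title: "Stacked ensembles of group-penalized regression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensembles of group-penalized regression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grpstack)
```

## The problem

In many regression problems the predictors carry a natural partition into
groups — dummy codes of one categorical factor, polynomial terms of one
continuous covariate, genes in one pathway — and the scientific question is
which *groups* matter, not which individual columns. With the linear model

$$ y = \sum_{g=1}^{G} X_g \beta_g + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma^2 I_n), $$

where $X_g$ holds group $g$'s $m_g$ columns, group-aware penalties select
or zero whole coefficient blocks $\beta_g$ at once. Different penalties
make different bias/sparsity trade-offs, and no single one dominates:
convex group penalties (group lasso) overshrink large signals and
overselect; nonconvex ones (group SCAD, group MCP) are nearly unbiased for
large signals but nonconvex to optimize; $\ell_0$ group-subset selection
charges a fixed price per active group and pairs naturally with a little
extra shrinkage. `grpstack` implements all of these behind one interface
and then *stacks* them: a lasso meta-learner is trained on the base
learners' out-of-fold predictions, so the data decide, fold by fold, which
estimator family to trust.

## Objective convention

All solvers minimize

$$ \frac{1}{2n}\lVert y - X\beta \rVert_2^2 + P(\beta). $$

Objectives written with an un-normalized residual sum of squares and no
half correspond to $\lambda_{\text{unnorm}} = 2n\,\lambda$ on this scale;
the $1/(2n)$ convention keeps $\lambda$ grids comparable across sample
sizes and matches common path-fitting software. Group penalties are scaled
by $\sqrt{m_g}$ by default (`group_multiplier = TRUE`), the dominant
convention, so that larger groups pay a proportionally larger price; the
flag disables it for strict textbook objectives.

## Penalties and their proximal operators

The scalar families are the lasso $\lambda|\beta|$, the elastic net
$\lambda_1|\beta| + \lambda_2\beta^2$, the adaptive lasso
$\lambda w_j |\beta_j|$, MCP

$$ P_\lambda(\beta) = \begin{cases}
   \lambda|\beta| - \beta^2/(2\gamma), & |\beta| \le \gamma\lambda \\
   \gamma\lambda^2/2, & |\beta| > \gamma\lambda,
 \end{cases} \qquad \gamma > 1, $$

and SCAD, which is $\lambda|\beta|$ up to $\lambda$, a quadratic blend on
$(\lambda, \gamma\lambda)$, and constant $(\gamma+1)\lambda^2/2$ beyond
$\gamma\lambda$, with $\gamma > 2$. Group versions apply the same scalar
rules to the block norm $\lVert\beta_g\rVert_2$. Coordinate descent only
ever needs the exact minimizer of the one-dimensional (or radial)
penalized quadratic; `scalar_threshold()` and `group_threshold()` expose
those operators directly, and the test suite checks them against
brute-force minimization over randomized draws. Defaults for the
nonconvexity parameters are the field-standard SCAD $\gamma = 3.7$ and MCP
$\gamma = 3$.

## Solvers

`fit_penalized()` / `fit_path()` run cyclic coordinate descent with warm
starts down a decreasing, log-spaced $\lambda$ grid (100 points from
$\lambda_{\max}$, the smallest value that zeroes the model, to
$10^{-4}\lambda_{\max}$), with an active-set strategy: cycles over the
current support until stable, then one full sweep to admit violators.
Nonconvex single-configuration fits are warm-started along an internal
path from $\lambda_{\max}$ to avoid poor local minima.

`fit_group_penalized()` uses block coordinate descent. Each group block is
centered, scaled, and orthonormalized (SVD-based, so $X_g'X_g/n = I$;
rank-deficient blocks are reduced to their intrinsic rank with a warning),
which makes every block update a closed-form thresholding step;
coefficients are mapped back to the original basis afterwards. The
intercept is never penalized and is handled by centering.

Convergence is declared when the largest absolute coefficient change in a
sweep falls below `tol * (1 + max|beta|)`; defaults are `tol = 1e-7` and
`max_iter = 10000` for direct fits, and `tol = 1e-5` inside
cross-validation where path-level accuracy is what matters. Non-converged
fits are returned with `converged = FALSE` and a warning, never an error;
the stacking layer treats them as valid.

## Group-subset selection

`fit_group_subset()` solves the $\ell_0$-type problem

$$ \min_v \frac{1}{2n}\lVert y - \textstyle\sum_k X_k v_k \rVert^2
   + \sum_k \lambda_0\, m_k\, 1(v_k \ne 0)
   + \sum_k \lambda_{1k} \lVert v_k \rVert_2, $$

(or a ridge term $\lambda_2\lVert v_k\rVert^2$), by block coordinate
descent on a proximal majorization: with
$\bar c_k = \lambda_{\max}(X_k'X_k/n)$ the block Lipschitz constant, the
surrogate for block $k$ is the usual quadratic upper bound of the loss
around the current iterate, and its minimizer is a gradient step followed
by group-soft-thresholding (or ridge scaling) and an accept/reject test
against the fixed cost $\lambda_0 m_k$. Under this construction the
entering threshold of an inactive group $k$ is exactly
$(\lVert \nabla_k L \rVert - \lambda_{1k})_+^2 / (2 m_k \bar c_k)$, which
gives the adaptive grid: the first $\lambda_0$ is the largest such
threshold at $v = 0$ (so the first fit is the empty model), and each next
value is $\alpha$ times the largest threshold among currently inactive
groups, guaranteeing at least one new group enters per grid point
(`next_lambda0()`). Per-group selection cost proportional to $m_k$ and
shrinkage weights $\lambda_{1k} = \lambda_1\sqrt{m_k}$ keep the formula
and the block updates mutually consistent; the gradient in the entering
threshold is always the block-restricted one, the only reading under
which a per-group threshold is well defined. We default to
$\alpha = 0.9$, which in practice admits one group per grid point and so
produces the finest support path; the grid stops when all groups are
active or `grid_size` points have been generated. On designs with
orthonormal, mutually orthogonal groups the objective separates and the
block update is exact, which is what the enumeration tests exploit.

## Tuning

`cross_validate()` performs seeded K-fold CV (default $K = 5$): the
primary grid is anchored at the full-data $\lambda_{\max}$ so every fold
scores the same grid (for the subset families, the full-data adaptive
$\lambda_0$ grid is reused across folds); fold paths are warm-started;
the score is held-out RMSE; ties go to the larger penalty and then to the
earlier (more convex) secondary value. No one-standard-error rule is
applied. Secondary parameters default to fast fixed values — SCAD
$\gamma = 3.7$, MCP $\gamma = 3$ — because the joint
$30 \times 100$ search rarely changes the selected model on the designs
studied here while multiplying cost by 30; `n_secondary = 30` restores
the full joint search with the $\gamma$ grid log-spaced on
$[2 + 10^{-4}, 100]$. For the group-subset + group-lasso combination the
shrinkage level $\lambda_1$ is searched over a short log-spaced grid
(5 points on $[0.01, 0.5] \times \lambda_{1,\max}$ by default): values
below that range leave the selected blocks essentially unshrunk and only
slow convergence, values above it zero everything through shrinkage
alone. Adaptive-lasso weights are $w_j = 1/(|\hat\beta_j^{ridge}| +
10^{-8})$ with the ridge level chosen by generalized cross-validation —
GCV rather than fold-based CV so the weights are deterministic and
well-defined when $p > n$ — computed once per training design.

## The stacking ensemble

`fit_stacking()` implements the two-layer ensemble. Layer 1: each base
learner (defaults: group-subset + group-lasso, group lasso, group SCAD)
is tuned by *inner* 5-fold CV inside each outer training fold and
predicts the held-out fold, producing an $n \times B$ out-of-fold
meta-feature matrix $Z$ — the same size as the original data, with no
entry produced by a model that saw that row. Layer 2: this package's own
lasso solver (unpenalized intercept, $\lambda$ by inner CV) is fit to
$(Z, y)$. For prediction, every base learner is refit on the full
training data and the meta-coefficients combine their predictions.
Nested inner tuning is the only leak-free reading of the two-layer
protocol, and the no-leakage property is asserted directly in the tests
(perturbing $y_i$ never changes row $i$'s meta-features). All fold
assignments and inner seeds derive deterministically from one master
seed, so the whole ensemble is bit-reproducible.

An alternative reading of the protocol — disjoint sub-datasets per base
learner rather than shared K-fold OOF — is available as
`split_mode = "disjoint"` for fidelity experiments; its meta-features are
partly in-sample for the owning base learner, which is why it is not the
default.

`base_learner_diagnostics()` supports base-learner choice: per-candidate
OOF RMSE/MAE/$R^2$ and the pairwise correlation matrix of OOF residuals,
with a greedy recommendation (best RMSE first; add candidates within a
factor 1.25 of the best RMSE whose residual correlation with the selected
set is below 0.95 — both caps are package defaults, since the underlying
criterion of "strong, cheap, and different" is qualitative).

## The synthetic designs

`simulate_grouped()` draws rows of $X$ from a zero-mean Gaussian with
unit variances, correlation $\rho$ inside each group and zero across
groups, and $y = X\beta + \varepsilon$, $\varepsilon \sim N(0,
\sigma^2)$. The study conditions are fixed by the presets: groups of 20,
$\rho = 0.5$, $\sigma^2 = 10$, and the alternating pattern in which every
odd group is all ones and every even group all zeros; small-sample
presets use $n = 200$ with $p \in \{500, 1000, 1500, 2000\}$ and
large-sample presets $p = 100$ with $n \in \{500, 1000, 1500, 2000\}$.
An equicorrelation level of 0.5 can be read as applying within groups
only or to every pair of columns; we default to within-group correlation
(the convention of group-penalty simulation studies, which also makes the
group structure identifiable in the covariance) and expose
`correlation_scheme = "global_equicorrelated"` for the other reading. Evaluation is on an independent test set of the same size as
the training set, since $R^2$/MAE/RMSE are presented as model-evaluation
metrics and the real-data protocol is a 70/30 holdout; the general
$R^2 = 1 - SSE/SST$ form is used, which is valid (and possibly negative)
out of sample. Train and test sets come from one seeded stream consumed
in a documented order; replicate $r$ uses `seed + r - 1`.

What the generator does *not* emulate: heavy tails, heteroscedasticity,
non-Gaussian or binary responses, overlapping groups, and correlation
across groups (except in the global scheme). Passing tests on these
designs therefore demonstrate correctness of the estimators and the
claimed ordering of methods under the stated Gaussian group-structured
law, not robustness to real-data pathologies.

## A worked example

```{r example, eval = FALSE}
data <- simulate_grouped(sim_preset("table7_n1000", seed = 1))
model <- fit_stacking(data$train, K = 5, seed = 1)
pred <- predict(model, data$test$X)
evaluate_predictions(data$test$y, pred)
model$meta_coefficients
```

On this large-sample design the ensemble's test RMSE is close to the
noise floor $\sigma = \sqrt{10} \approx 3.16$, and the meta-coefficients
show which base learner carries the prediction. On the small-sample
designs ($p \gg n$) the group-subset + group-lasso base dominates and the
convex group lasso, which must overshrink to control variance, receives
little meta-weight — the ensemble's advantage is precisely that this
choice is made by held-out evidence rather than a priori.

## Numerical choices and degenerate inputs

* Zero-variance columns get scale 1 (they stay zero and are never
  selected); all-zero group blocks have $\bar c_k = 0$ and are skipped by
  the subset solver.
* At the adaptive-grid anchor the accept/reject comparison is an exact
  mathematical tie; a relative $10^{-10}$ guard keeps the anchor model
  empty rather than letting floating-point jitter decide.
* Sweep order is cyclic in group order; within ties of the entering
  threshold the lowest group index enters, for determinism.
* A constant response yields $\lambda_{\max} = 0$ with a warning;
  $R^2$ against a constant truth is an error rather than a NaN.
* Problem sizes in the test suite are scaled so the full suite runs in a
  few minutes on one core: operator checks at $n$ of a few dozen,
  enumeration at $G \le 4$, ensemble checks on the $p = 500$ and
  $p = 100$ presets with 10 replicates.

## Limitations

Continuous responses only; no overlapping groups (the group-specific
decomposition that would support them is not exposed); no screening
rules, so the $p = 2000$ designs take minutes rather than seconds per
replicate; and Monte Carlo standard errors on 10 replicates leave roughly
percent-level uncertainty on the reported means.
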