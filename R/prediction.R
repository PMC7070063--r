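#' Model configuration for niche prediction
#'
#' Bundles the hyperparameters of the four predictors. The tree-ensemble
#' defaults are the settings used throughout the analyses: gradient
#' boosting with 10000 stages, learning rate 0.001, interaction depth 2 and
#' a minimum of 1 observation per terminal node; random forests with 2000
#' trees; ridge regression with the penalty tuned by inner cross-validation
#' on a log-spaced grid.
#'
#' @param model one of `"ridge"`, `"random_forest"`, `"gradient_boosting"`,
#'   `"phylo"`.
#' @param ridge_lambda_grid penalty grid (on the standardized-feature
#'   scale).
#' @param ridge_inner_folds inner-CV folds for lambda selection.
#' @param rf_trees,rf_min_node random-forest size and minimum node size.
#' @param gbm_trees,gbm_shrinkage,gbm_depth,gbm_min_obs boosting stages,
#'   learning rate, splits per tree and minimum observations per leaf.
#' @param cv_folds outer cross-validation folds.
#' @param seed integer seed for fold assignment and stochastic models.
#' @return a validated list of class `model_config`.
#' @export
model_config <- function(model = c("ridge", "random_forest",
                                   "gradient_boosting", "phylo"),
                         ridge_lambda_grid = 10^seq(-4, 4, length.out = 100),
                         ridge_inner_folds = 5,
                         rf_trees = 2000, rf_min_node = 5,
                         gbm_trees = 10000, gbm_shrinkage = 0.001,
                         gbm_depth = 2, gbm_min_obs = 1,
                         cv_folds = 10, seed = 1) {
  model <- match.arg(model)
  stopifnot(rf_trees >= 1, gbm_trees >= 0, gbm_shrinkage >= 0,
            gbm_depth >= 1, gbm_min_obs >= 1, cv_folds >= 2,
            ridge_inner_folds >= 2, all(ridge_lambda_grid >= 0))
  structure(list(model = model, ridge_lambda_grid = ridge_lambda_grid,
                 ridge_inner_folds = ridge_inner_folds,
                 rf_trees = rf_trees, rf_min_node = rf_min_node,
                 gbm_trees = gbm_trees, gbm_shrinkage = gbm_shrinkage,
                 gbm_depth = gbm_depth, gbm_min_obs = gbm_min_obs,
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "model_config")
}

#' Random near-equal partition into folds
#'
#' @param n number of observations.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), sizes differing by at most 1.
#' @export
make_folds <- function(n, k, seed = 1) {
  if (n < k) stop("fewer observations than folds")
  set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- rep(seq_len(k), times = sizes)
  fold[sample.int(n)]
}

.ridge_svd_predict <- function(Xtr, ytr, Xte, lambdas) {
  # returns matrix nrow(Xte) x length(lambdas)
  sv <- svd(Xtr)
  uy <- crossprod(sv$u, ytr)            # d-vector
  XteV <- Xte %*% sv$v                  # m x d
  out <- matrix(0, nrow(Xte), length(lambdas))
  for (l in seq_along(lambdas)) {
    shrink <- sv$d / (sv$d^2 + lambdas[l])
    shrink[sv$d < 1e-10] <- 0
    if (lambdas[l] == 0) shrink <- ifelse(sv$d < 1e-10, 0, 1 / sv$d)
    out[, l] <- XteV %*% (shrink * uy)
  }
  out
}

#' Ridge regression with inner-CV penalty selection
#'
#' L2-penalized least squares. Features are standardized with training-set
#' statistics (constant columns dropped); the response is centered. When
#' `lambda` is NULL the penalty is picked from `lambda_grid` by inner
#' cross-validation on the training set only, minimizing mean squared
#' error, then the model is refit on the full training set. Solved in SVD
#' form, so `lambda = 0` gives the (minimum-norm) ordinary least squares
#' fit exactly.
#'
#' @param Xtr,ytr training features and response.
#' @param Xte test features.
#' @param lambda fixed penalty, or NULL to tune.
#' @param lambda_grid candidate penalties.
#' @param inner_folds inner-CV folds.
#' @param seed seed for the inner folds.
#' @return list(predictions, lambda).
#' @export
ridge_fit_predict <- function(Xtr, ytr, Xte,
                              lambda = NULL,
                              lambda_grid = 10^seq(-4, 4, length.out = 100),
                              inner_folds = 5, seed = 1) {
  stopifnot(is.matrix(Xtr), is.matrix(Xte), nrow(Xtr) == length(ytr))
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all features constant in training set")
  Xtr_s <- scale(Xtr[, keep, drop = FALSE], center = mu[keep],
                 scale = sdv[keep])
  Xte_s <- scale(Xte[, keep, drop = FALSE], center = mu[keep],
                 scale = sdv[keep])
  ybar <- mean(ytr)
  yc <- ytr - ybar
  if (is.null(lambda)) {
    fold <- make_folds(nrow(Xtr_s), inner_folds, seed)
    err <- matrix(NA_real_, inner_folds, length(lambda_grid))
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      pr <- .ridge_svd_predict(Xtr_s[tr, , drop = FALSE], yc[tr],
                               Xtr_s[!tr, , drop = FALSE], lambda_grid)
      err[f, ] <- colMeans((pr - yc[!tr])^2)
    }
    lambda <- lambda_grid[which.min(colMeans(err))]
  }
  pred <- .ridge_svd_predict(Xtr_s, yc, Xte_s, lambda)[, 1] + ybar
  list(predictions = as.numeric(pred), lambda = lambda)
}

#' Gradient-boosting regression (squared-error loss)
#'
#' Stagewise boosted regression trees: `gbm_trees` stages of learning rate
#' `gbm_shrinkage`, each tree grown best-first to `gbm_depth` splits with at
#' least `gbm_min_obs` observations per leaf. No row or feature
#' subsampling, so the fit is deterministic given the data.
#'
#' @param Xtr,ytr training features and response.
#' @param Xte test features.
#' @param cfg a `model_config`.
#' @return numeric vector of test predictions.
#' @export
gbm_fit_predict <- function(Xtr, ytr, Xte, cfg = model_config("gradient_boosting")) {
  stopifnot(is.matrix(Xtr), is.matrix(Xte), nrow(Xtr) == length(ytr))
  fit <- .gbm_boost(Xtr, as.numeric(ytr), Xte,
                    as.integer(cfg$gbm_trees), cfg$gbm_shrinkage,
                    as.integer(cfg$gbm_depth), as.integer(cfg$gbm_min_obs))
  as.numeric(fit$test)
}

#' Random-forest regression with out-of-bag validation
#'
#' Fits a regression forest (default 2000 trees, p/3 features per split,
#' minimum node size 5) and validates with out-of-bag predictions: each
#' observation is predicted by averaging only the trees whose bootstrap
#' sample excluded it. Observations in-bag for every tree (vanishingly rare
#' at 2000 trees) are flagged and dropped from the evaluation.
#'
#' @param features observation x feature matrix.
#' @param target numeric response.
#' @param cfg a `model_config` (fields `rf_trees`, `rf_min_node`, `seed`).
#' @param mtry features tried per split (default `max(floor(p/3), 1)`).
#' @return object of class `prediction_result`.
#' @export
forest_oob_predict <- function(features, target,
                               cfg = model_config("random_forest"),
                               mtry = NULL) {
  stopifnot(is.matrix(features), nrow(features) == length(target))
  if (cfg$rf_trees < 100) stop("n_trees must be >= 100")
  if (is.null(mtry)) mtry <- max(floor(ncol(features) / 3), 1)
  set.seed(cfg$seed)
  fit <- .rf_oob(features, as.numeric(target), as.integer(cfg$rf_trees),
                 as.integer(mtry), as.integer(cfg$rf_min_node), 30L)
  pred <- fit$oob
  if (anyNA(pred))
    warning(sum(is.na(pred)), " observation(s) in-bag for all trees")
  ok <- !is.na(pred)
  ev <- evaluate_prediction(target[ok], pred[ok])
  res <- data.frame(id = .row_ids(features), observed = target,
                    predicted = pred, fold = NA_integer_,
                    stringsAsFactors = FALSE)
  structure(list(result = res, rho = ev$rho, p = ev$p, config = cfg),
            class = "prediction_result")
}

.row_ids <- function(m) {
  if (is.null(rownames(m))) paste0("obs", seq_len(nrow(m))) else rownames(m)
}

#' Brownian-motion prediction of tip traits from a phylogeny
#'
#' Generalized-least-squares (phylogenetic kriging) estimate of unobserved
#' tip values under a Brownian-motion model:
#' `E[y_test | y_train] = mu + C_to C_oo^-1 (y_train - mu)` with C the
#' shared-path-length covariance of the tree and mu the GLS root-state
#' estimate from the training tips. A held-out tip at distance zero from an
#' observed tip inherits that tip's value; on a star tree the prediction is
#' the training mean.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param observed named numeric vector of trait values for observed tips.
#' @param test_tips character vector of tips to predict.
#' @return named numeric vector of predictions for `test_tips`.
#' @export
phylo_predict <- function(tree, observed, test_tips) {
  stopifnot(inherits(tree, "phylo"), !is.null(names(observed)))
  if (!all(c(names(observed), test_tips) %in% tree$tip.label))
    stop("tips missing from tree")
  if (length(intersect(names(observed), test_tips)))
    stop("test tips overlap observed tips")
  C <- ape::vcv(tree)
  o <- names(observed)
  Coo <- C[o, o, drop = FALSE]
  Cto <- C[test_tips, o, drop = FALSE]
  sol <- tryCatch(solve(Coo, cbind(1, observed)),
                  error = function(e) NULL)
  if (is.null(sol)) {
    warning("singular phylogenetic covariance; adding diagonal jitter")
    Coo <- Coo + diag(1e-8 * mean(diag(Coo)), nrow(Coo))
    sol <- solve(Coo, cbind(1, observed))
  }
  mu <- sum(sol[, 2]) / sum(sol[, 1])   # GLS root state: (1'C^-1 y)/(1'C^-1 1)
  resid <- solve(Coo, observed - mu)
  pred <- as.numeric(mu + Cto %*% resid)
  stats::setNames(pred, test_tips)
}

#' Spearman evaluation of predictions
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @return list(rho, p) — Spearman rank correlation (mid-ranks) and the
#'   large-sample approximation p-value.
#' @export
evaluate_prediction <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("constant vector: Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(observed, predicted,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' K-fold cross-validated niche prediction
#'
#' Randomly partitions observations into `cv_folds` near-equal subsets; each
#' subset is predicted once by a model trained on the others, so every
#' observation receives exactly one out-of-fold prediction. Supported
#' models: ridge regression, gradient boosting, and Brownian-motion
#' phylogenetic prediction (which needs `tree`). Random forests are
#' validated out-of-bag instead — see [forest_oob_predict()].
#'
#' @param features observation x feature matrix (rownames = ids). For
#'   `model = "phylo"`, rownames must be tree tips (features are unused).
#' @param target numeric response aligned with the rows.
#' @param cfg a `model_config`.
#' @param tree `phylo` object, required for the phylo model.
#' @return object of class `prediction_result`: list with `result`
#'   (data.frame id/observed/predicted/fold), `rho`, `p`, `config`.
#' @export
kfold_cv <- function(features, target, cfg = model_config("ridge"),
                     tree = NULL) {
  stopifnot(is.matrix(features), nrow(features) == length(target))
  if (anyNA(target)) stop("missing target values")
  n <- nrow(features)
  if (n < cfg$cv_folds) stop("fewer observations than folds")
  if (cfg$model == "random_forest")
    stop("random forests are validated out-of-bag: use forest_oob_predict()")
  if (cfg$model == "phylo" && is.null(tree))
    stop("phylo model requires a tree")
  ids <- .row_ids(features)
  fold <- make_folds(n, cfg$cv_folds, cfg$seed)
  pred <- rep(NA_real_, n)
  for (f in seq_len(cfg$cv_folds)) {
    te <- fold == f
    pred[te] <- switch(
      cfg$model,
      ridge = ridge_fit_predict(features[!te, , drop = FALSE], target[!te],
                                features[te, , drop = FALSE],
                                lambda_grid = cfg$ridge_lambda_grid,
                                inner_folds = cfg$ridge_inner_folds,
                                seed = cfg$seed + f)$predictions,
      gradient_boosting = gbm_fit_predict(features[!te, , drop = FALSE],
                                          target[!te],
                                          features[te, , drop = FALSE], cfg),
      phylo = phylo_predict(tree,
                            stats::setNames(target[!te], ids[!te]),
                            ids[te])[ids[te]]
    )
  }
  ev <- evaluate_prediction(target, pred)
  res <- data.frame(id = ids, observed = target, predicted = pred,
                    fold = fold, stringsAsFactors = FALSE)
  structure(list(result = res, rho = ev$rho, p = ev$p, config = cfg),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("Cross-validated prediction (", x$config$model, "): rho =",
      format(x$rho, digits = 3), ", p =", format(x$p, digits = 3), "\n")
  invisible(x)
}

#' Permutation control for cross-validated predictions
#'
#' Shuffles the target and reruns the cross-validation; with clean folds
#' the out-of-fold correlation should hover around zero. Returns the
#' absolute out-of-fold rho of each permutation (ridge by default — the
#' leakage guard is model-agnostic and ridge keeps the run cheap).
#'
#' @param features observation x feature matrix.
#' @param target numeric response.
#' @param cfg a `model_config`.
#' @param n_perm number of target permutations.
#' @param seed seed for the permutations.
#' @return numeric vector of |rho| values, length `n_perm`.
#' @export
permutation_control <- function(features, target, cfg = model_config("ridge"),
                                n_perm = 100, seed = 1) {
  set.seed(seed)
  perms <- replicate(n_perm, sample(target), simplify = FALSE)
  vapply(perms, function(y) abs(kfold_cv(features, y, cfg)$rho), numeric(1))
}

#' Rerun niche space and prediction within one taxon
#'
#' Restricts the clusters to those carrying a given taxon label, rebuilds
#' the abundance dissimilarity and niche space on the subset, re-applies the
#' prevalence filter within the subset, and cross-validates the prediction
#' of a chosen axis.
#'
#' @param features cluster x gene-label count matrix (pre-filter).
#' @param abundances cluster x sample abundance matrix.
#' @param taxon_labels named character vector (cluster id -> taxon).
#' @param taxon the taxon label to restrict to.
#' @param cfg a `model_config`.
#' @param axis which niche-space axis to predict (default `"PC1"`).
#' @param k axes retained in the subset ordination.
#' @param min_frac prevalence-filter fraction, re-applied within the subset.
#' @param tree optional `phylo` for the phylo model.
#' @return list(space, prediction) for the taxon subset.
#' @export
taxon_restricted_run <- function(features, abundances, taxon_labels, taxon,
                                 cfg = model_config("ridge"), axis = "PC1",
                                 k = 10, min_frac = 0.10, tree = NULL) {
  ids <- names(taxon_labels)[taxon_labels == taxon]
  ids <- intersect(rownames(abundances), ids)
  if (length(ids) < cfg$cv_folds)
    stop("taxon subset smaller than the number of folds")
  ab <- abundances[ids, , drop = FALSE]
  D <- abundance_dissimilarity(ab)
  space <- pcoa_cailliez(D, k = k)
  X <- prevalence_filter(features[ids, , drop = FALSE], min_frac)
  target <- space$coordinates[, axis]
  if (cfg$model == "phylo" && !is.null(tree))
    tree <- ape::keep.tip(tree, ids)
  pred <- kfold_cv(X, target, cfg, tree = tree)
  list(space = space, prediction = pred)
}
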