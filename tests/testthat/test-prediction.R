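test_that("make_folds gives near-equal, seeded partitions", {
  f <- make_folds(25, 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) %in% 2:3))
  expect_equal(sum(table(f)), 25)
  expect_identical(f, make_folds(25, 10, seed = 3))
  expect_false(identical(f, make_folds(25, 10, seed = 4)))
  expect_error(make_folds(5, 10), "fewer")
})

test_that("ridge shrinks to the training mean and recovers OLS at 0", {
  set.seed(8)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- X %*% c(1, -2, 0.5, 0, 1) + rnorm(40, 0, 0.1)
  # lambda -> infinity: predictions ~ training mean
  big <- ridge_fit_predict(X[1:30, ], y[1:30], X[31:40, ], lambda = 1e12)
  expect_equal(big$predictions, rep(mean(y[1:30]), 10), tolerance = 1e-6)
  # lambda = 0 on a full-rank tall design: equals lm()
  ols <- ridge_fit_predict(X[1:30, ], y[1:30], X[31:40, ], lambda = 0)
  fit <- lm(y ~ ., data = data.frame(y = y[1:30], X[1:30, ]))
  ref <- predict(fit, newdata = data.frame(X[31:40, ]))
  expect_equal(ols$predictions, unname(ref), tolerance = 1e-6)
})

test_that("ridge handles duplicated columns gracefully", {
  set.seed(9)
  X <- matrix(rnorm(60), 60, 1)
  y <- X[, 1] + rnorm(60, 0, 0.05)
  Xdup <- cbind(X, X)
  p1 <- ridge_fit_predict(X[1:50, , drop = FALSE], y[1:50],
                          X[51:60, , drop = FALSE], lambda = 1)
  # duplicating the feature splits its weight; doubling lambda restores the
  # effective penalty, so predictions coincide (L2 property)
  p2 <- ridge_fit_predict(Xdup[1:50, ], y[1:50], Xdup[51:60, ], lambda = 2)
  expect_true(all(is.finite(p2$predictions)))
  expect_equal(p1$predictions, p2$predictions, tolerance = 1e-6)
})

test_that("cross-validated ridge recovers a noiseless linear target", {
  set.seed(12)
  X <- matrix(rnorm(100 * 10), 100, 10)
  y <- as.numeric(2.5 * X[, 4])
  res <- kfold_cv(X, y, model_config("ridge", seed = 2))
  expect_gte(res$rho, 0.99)
  expect_true(all(table(res$result$fold) == 10))
  # every observation predicted exactly once, out of fold
  expect_false(anyNA(res$result$predicted))
  res2 <- kfold_cv(X, y, model_config("ridge", seed = 2))
  expect_identical(res$result$predicted, res2$result$predicted)
})

test_that("gbm limits: zero stages and zero learning rate give the mean", {
  set.seed(13)
  X <- matrix(rnorm(50 * 3), 50, 3)
  y <- rnorm(50)
  cfg0 <- model_config("gradient_boosting", gbm_trees = 0)
  expect_equal(gbm_fit_predict(X[1:40, ], y[1:40], X[41:50, ], cfg0),
               rep(mean(y[1:40]), 10))
  cfg_lr0 <- model_config("gradient_boosting", gbm_trees = 50,
                          gbm_shrinkage = 0)
  expect_equal(gbm_fit_predict(X[1:40, ], y[1:40], X[41:50, ], cfg_lr0),
               rep(mean(y[1:40]), 10))
})

test_that("gbm learns an additive two-feature target", {
  set.seed(14)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4)
  y <- X[, 1] + 2 * X[, 2] + rnorm(n, 0, 0.2)
  tr <- 1:250; te <- 251:300
  pred <- gbm_fit_predict(X[tr, ], y[tr], X[te, ])
  expect_gte(cor(pred, y[te], method = "spearman"), 0.8)
})

test_that("random forest OOB: constant target, determinism, signal", {
  set.seed(15)
  X <- matrix(rnorm(60 * 4), 60, 4)
  expect_error(forest_oob_predict(X, rep(1, 60),
                                  model_config("random_forest")),
               "constant")
  cfgS <- model_config("random_forest", rf_trees = 150, seed = 7)
  y <- rnorm(60)
  r1 <- forest_oob_predict(X, y, cfgS)
  r2 <- forest_oob_predict(X, y, cfgS)
  expect_identical(r1$result$predicted, r2$result$predicted)
  # strong single-feature signal at n = 200
  n <- 200
  X2 <- matrix(rnorm(n * 5), n, 5)
  y2 <- X2[, 3] + rnorm(n, 0, 0.2)
  res <- forest_oob_predict(X2, y2, model_config("random_forest",
                                                 rf_trees = 500, seed = 8))
  expect_gte(res$rho, 0.8)
})

test_that("phylo_predict: zero-distance tip, star tree, BM oracle", {
  # held-out tip at distance 0 from an observed tip
  tr <- ape::read.tree(text = "((A:0.0000001,B:0.0000001):1,C:1.0000001);")
  pred <- phylo_predict(tr, c(A = 3.7, C = -1), "B")
  expect_equal(unname(pred), 3.7, tolerance = 1e-4)
  # star tree: prediction is the mean of observed values
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  ps <- phylo_predict(star, c(A = 1, B = 2, C = 6), "D")
  expect_equal(unname(ps), 3, tolerance = 1e-9)
  # oracle equivalence on a 100-tip tree
  set.seed(16)
  big <- ape::rtree(100)
  y <- as.numeric(t(chol(ape::vcv(big))) %*% rnorm(100))
  names(y) <- big$tip.label
  test_tips <- big$tip.label[1:20]
  obs <- y[setdiff(big$tip.label, test_tips)]
  expect_equal(unname(phylo_predict(big, obs, test_tips)),
               bm_conditional_oracle(big, obs, test_tips), tolerance = 1e-8)
  expect_error(phylo_predict(big, obs, "no_such_tip"), "missing")
})

test_that("evaluate_prediction matches the rank-correlation oracle", {
  expect_equal(evaluate_prediction(1:5, 1:5)$rho, 1)
  expect_equal(evaluate_prediction(1:5, 5:1)$rho, -1)
  set.seed(17)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(evaluate_prediction(a, b)$rho, spearman_oracle(a, b),
               tolerance = 1e-12)
  expect_error(evaluate_prediction(rep(1, 5), 1:5), "constant")
})

test_that("phylo model slots into the shared cross-validation folds", {
  set.seed(18)
  tr <- ape::rtree(40)
  y <- as.numeric(t(chol(ape::vcv(tr))) %*% rnorm(40))
  X <- matrix(0, 40, 1, dimnames = list(tr$tip.label, "unused"))
  res <- kfold_cv(X, y, model_config("phylo", cv_folds = 5, seed = 3),
                  tree = tr)
  expect_gt(res$rho, 0.3)  # BM trait is phylogenetically predictable
  expect_true(all(table(res$result$fold) == 8))
})

test_that("taxon-restricted runs rebuild the space on the subset", {
  w <- small_world(seed = 61, n_taxa = 60, n_samples = 25, n_genes = 80)
  taxa <- setNames(rep(c("cladeA", "cladeB"), each = 30),
                   rownames(w$abundance))
  run <- taxon_restricted_run(w$gene_matrix, w$abundance, taxa, "cladeA",
                              model_config("ridge", cv_folds = 5, seed = 2))
  expect_equal(length(run$space$ids), 30)
  expect_equal(nrow(run$prediction$result), 30)
  expect_error(taxon_restricted_run(w$gene_matrix, w$abundance, taxa,
                                    "cladeA",
                                    model_config("ridge", cv_folds = 40)),
               "smaller")
})
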