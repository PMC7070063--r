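test_that("pcoa recovers a 1-D configuration exactly", {
  D <- line_dist(c(0, 1, 2))
  sp <- pcoa_cailliez(D, k = 3)
  expect_equal(sp$correction, 0)
  expect_equal(ncol(sp$coordinates), 1L)  # only one positive eigenvalue
  expect_equal(as.numeric(dist(sp$coordinates[, 1])),
               as.numeric(dist(c(0, 1, 2))), tolerance = 1e-9)
  expect_equal(unname(sp$variance_explained[1]), 1.0)
})

test_that("equilateral triangle gives two equal positive eigenvalues", {
  D <- matrix(0.6, 3, 3); diag(D) <- 0
  dimnames(D) <- list(letters[1:3], letters[1:3])
  sp <- pcoa_cailliez(D, k = 3)
  ev <- sp$eigenvalues[sp$eigenvalues > 1e-10]
  expect_length(ev, 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  expect_equal(unname(variance_explained(sp$eigenvalues)[1:2]), c(0.5, 0.5),
               tolerance = 1e-9)
})

test_that("Cailliez correction makes random matrices Euclidean and is tight", {
  for (s in 1:5) {
    D <- random_dist(12, seed = 300 + s)
    sp <- pcoa_cailliez(D, k = 12)
    expect_gte(min(sp$eigenvalues), -1e-8)
    expect_gt(sp$correction, 0)
    # full-dimensional embedding reconstructs D + c off-diagonal
    pos <- sp$eigenvalues > 1e-8
    eg <- eigen(magniche:::.gower_center(-0.5 * (D + sp$correction *
                                                   (1 - diag(12)))^2),
                symmetric = TRUE)
    emb <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]))
    rec <- as.matrix(dist(emb))
    expect_equal(rec[upper.tri(rec)],
                 (D + sp$correction)[upper.tri(D)], tolerance = 1e-6)
  }
})

test_that("pcoa_cailliez agrees with the reference PCoA implementation", {
  skip_if_not_installed("ape")
  D <- random_dist(15, seed = 77)
  sp <- pcoa_cailliez(D, k = 5)
  ref <- ape::pcoa(as.dist(D), correction = "cailliez")
  # the reference reports its additive constant only inside its note text
  nums <- as.numeric(regmatches(ref$note,
                                gregexpr("[0-9]+\\.[0-9]+", ref$note))[[1]])
  expect_true(any(abs(nums - sp$correction) < 1e-6))
  # same corrected spectrum
  ev_ref <- ref$values$Corr_eig[seq_len(5)]
  expect_equal(sp$eigenvalues[1:5], ev_ref, tolerance = 1e-6)
  # same corrected coordinates up to sign
  for (a in 1:5)
    expect_equal(abs(sp$coordinates[, a]),
                 abs(ref$vectors.cor[rownames(D), a]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pcoa_cailliez applies zero correction to Euclidean input", {
  set.seed(9)
  pts <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(pts))
  sp <- pcoa_cailliez(D, k = 9)
  expect_equal(sp$correction, 0)
  cmds <- cmdscale(D, k = 2)
  expect_equal(abs(sp$coordinates[, 1:2]), abs(cmds), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(pcoa_cailliez(D * NA), "missing")
})

test_that("variance_explained normalizes by positive eigenvalues", {
  expect_equal(variance_explained(c(3, 1, 0, -0.5)), c(0.75, 0.25, 0, 0))
  expect_error(variance_explained(c(-1, -2)), "positive")
  D <- random_dist(10, seed = 5)
  expect_lte(sum(variance_explained(pcoa_cailliez(D)$eigenvalues)), 1 + 1e-12)
})

test_that("env_arrows finds perfect-rank relationships", {
  # clusters interpolate between salinity-tracking and salinity-agnostic
  # profiles, so their salinity correlations are graded and PC1 orders them
  sal <- 1:12
  set.seed(4)
  other <- sample(12)  # non-monotone reference pattern
  t_b <- seq(0, 1, length.out = 8)
  ab <- t(sapply(t_b, function(t) (1 - t) * sal + t * other))
  dimnames(ab) <- list(paste0("B", 1:8), paste0("S", 1:12))
  meta <- data.frame(sample_id = colnames(ab), salinity = sal)
  sp <- pcoa_cailliez(abundance_dissimilarity(ab), k = 2)
  ar <- env_arrows(ab, meta, sp)
  expect_equal(abs(ar["salinity", "PC1"]), 1, tolerance = 1e-9)
  meta$flat <- 1
  expect_error(env_arrows(ab, meta, sp, variables = "flat"), "constant")
})

test_that("gradient_log_ratio handles groups, pairs, thresholds", {
  ab <- rbind(B1 = c(2, 2, 2, 2), B2 = c(exp(1), exp(1), 1, 1),
              B3 = c(0.004, 0.004, 0.004, 0.004))
  colnames(ab) <- c("H1", "H2", "L1", "L2")
  g <- gradient_log_ratio(ab, groups = list(num = c("H1", "H2"),
                                            den = c("L1", "L2")),
                          threshold = 0.01, pseudocount = 1e-9)
  expect_equal(g$value[1], 0)                      # equal means -> 0
  expect_equal(g$value[2], 1, tolerance = 1e-6)    # e-fold -> 1 (natural log)
  expect_equal(g$included, c(TRUE, TRUE, FALSE))   # B3 below 0.01 everywhere
  # paired mode: mean of per-pair log ratios
  p <- gradient_log_ratio(ab, pairs = data.frame(num = c("H1", "H2"),
                                                 den = c("L1", "L2")),
                          pseudocount = 1e-9)
  expect_equal(p$value[2], 1, tolerance = 1e-6)
  # antisymmetry under swapping numerator and denominator
  g_rev <- gradient_log_ratio(ab, groups = list(num = c("L1", "L2"),
                                                den = c("H1", "H2")),
                              pseudocount = 1e-9)
  expect_equal(g$value, -g_rev$value, tolerance = 1e-12)
  expect_error(gradient_log_ratio(ab, groups = list(num = character(0),
                                                    den = "L1")), "empty")
  expect_error(gradient_log_ratio(ab, pairs = data.frame(num = "H1",
                                                         den = "nope")),
               "pair")
})

test_that("toy 5-cluster inclusion set matches hand enumeration", {
  # threshold 0.05: included iff max abundance over the involved samples
  # exceeds 0.05 strictly
  ab <- rbind(B1 = c(0.2, 0.01), B2 = c(0.05, 0.05), B3 = c(0.051, 0),
              B4 = c(0, 0), B5 = c(0.04, 0.049))
  colnames(ab) <- c("S1", "S2")
  g <- gradient_log_ratio(ab, groups = list(num = "S1", den = "S2"),
                          threshold = 0.05)
  expect_equal(g$bacl_id[g$included], c("B1", "B3"))
})
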