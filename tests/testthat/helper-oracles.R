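# Independent oracles and small fixture builders shared across test files.

# Naive O(n^3) average-linkage agglomeration with an inclusive cut at
# height h: repeatedly merge the pair of clusters with the smallest mean
# inter-cluster distance while that distance is <= h.
naive_average_linkage <- function(d, h) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
  lab
}

# Partition equality up to relabeling.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Spearman rho by explicit rank-then-Pearson.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Conditional multivariate-normal prediction under Brownian motion on a
# tree: built from the full tip covariance, with the mean estimated by GLS
# from the observed tips (independent of the package's phylo_predict path
# apart from ape::vcv itself).
bm_conditional_oracle <- function(tree, observed, test_tips) {
  C <- ape::vcv(tree)
  o <- names(observed)
  Coo_inv <- solve(C[o, o])
  one <- rep(1, length(o))
  mu <- as.numeric((t(one) %*% Coo_inv %*% observed) /
                     (t(one) %*% Coo_inv %*% one))
  as.numeric(mu + C[test_tips, o, drop = FALSE] %*% Coo_inv %*% (observed - mu))
}

# Random symmetric "ANI-like" matrix with unit diagonal.
random_ani <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n, 0.9, 1), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("M%02d", 1:n), sprintf("M%02d", 1:n))
  a
}

# Random symmetric distance-like matrix with zero diagonal.
random_dist <- function(n, seed, max = 1) {
  set.seed(seed)
  d <- matrix(runif(n * n, 0, max), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(sprintf("E%02d", 1:n), sprintf("E%02d", 1:n))
  d
}

# Distance matrix of points on a line.
line_dist <- function(x) {
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(paste0("P", seq_along(x)), paste0("P", seq_along(x)))
  d
}

small_world <- function(seed = 11, beta = 0.5, n_taxa = 40, n_samples = 20,
                        n_genes = 80, ...) {
  simulate_world(synthetic_config(n_taxa = n_taxa, n_genes = n_genes,
                                  n_niche_genes = 12, n_samples = n_samples,
                                  beta = beta, seed = seed, ...))
}
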