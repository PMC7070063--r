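.node_depths <- function(tree) {
  nmax <- max(tree$edge)
  depth <- rep(NA_real_, nmax)
  root <- length(tree$tip.label) + 1L
  depth[root] <- 0
  tr <- stats::reorder(tree)  # cladewise: parent visited before child
  for (e in seq_len(nrow(tr$edge))) {
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + tr$edge.length[e]
  }
  depth
}

.tip_ancestry <- function(tree) {
  n <- length(tree$tip.label)
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  lapply(seq_len(n), function(i) {
    path <- i
    while (path[length(path)] != root) path <- c(path, parent[path[length(path)]])
    path
  })
}

.patristic_one <- function(tree) {
  n <- length(tree$tip.label)
  depth <- .node_depths(tree)
  anc <- .tip_ancestry(tree)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    ai <- anc[[i]]
    for (j in (i + 1):n) {
      common <- intersect(ai, anc[[j]])
      lca <- common[which.max(depth[common])]
      D[i, j] <- D[j, i] <- depth[i] + depth[j] - 2 * depth[lca]
    }
  }
  D
}

#' Patristic distances, with an inter-domain constant
#'
#' Tip-to-tip distances as the sum of branch lengths along the path between
#' two tips (depth(i) + depth(j) - 2 depth(LCA)). When separate trees are
#' supplied per domain (e.g. one bacterial, one archaeal tree), pairs from
#' different domains get the fixed constant `inter_domain` — chosen higher
#' than any within-domain distance, since no common tree connects them.
#'
#' @param trees a single `phylo` object, or a named list of `phylo` objects
#'   keyed by domain.
#' @param inter_domain distance assigned to cross-domain pairs.
#' @return symmetric distance matrix over all tips (lexicographic order).
#' @export
patristic_distances <- function(trees, inter_domain = 5) {
  if (inherits(trees, "phylo")) trees <- list(domain = trees)
  stopifnot(is.list(trees), all(vapply(trees, inherits, logical(1), "phylo")))
  tips <- unlist(lapply(trees, function(t) t$tip.label), use.names = FALSE)
  if (anyDuplicated(tips)) stop("tip labels duplicated across trees")
  tips <- sort(tips)
  D <- matrix(inter_domain, length(tips), length(tips),
              dimnames = list(tips, tips))
  for (tr in trees) {
    Dk <- .patristic_one(tr)
    D[rownames(Dk), colnames(Dk)] <- Dk
  }
  diag(D) <- 0
  D
}

.rank_matrix <- function(D) {
  n <- nrow(D)
  ut <- upper.tri(D)
  R <- matrix(0, n, n)
  R[ut] <- rank(D[ut])
  R + t(R)
}

.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

.check_mantel_input <- function(...) {
  mats <- list(...)
  n <- nrow(mats[[1]])
  for (D in mats) {
    if (!is.matrix(D) || nrow(D) != n || ncol(D) != n)
      stop("distance matrices must be square and of equal size")
    if (max(abs(D - t(D))) > 1e-9) stop("distance matrix not symmetric")
  }
  if (!is.null(rownames(mats[[1]]))) {
    for (D in mats[-1]) {
      if (!is.null(rownames(D)) &&
          !identical(rownames(D), rownames(mats[[1]])))
        stop("distance matrices must share the same entity order")
    }
  }
  n
}

#' Mantel permutation test (Spearman)
#'
#' Statistic: Spearman rank correlation between the n(n-1)/2 upper-triangle
#' entries of two distance matrices. Null distribution: rows and columns of
#' `Dx` permuted simultaneously. One-sided (positive association), with the
#' add-one rule p = (1 + #\{perm rho >= observed rho\}) / (1 + n_perm), so the
#' minimum attainable p is 1/(n_perm + 1).
#'
#' @param Dx,Dy symmetric distance matrices over the same entities.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param exhaustive if TRUE (n <= 7), enumerate all n! relabelings instead
#'   of sampling; p is then the exact fraction with rho >= observed.
#' @return object of class `mantel_result`: list(statistic, p, n_perm).
#' @export
mantel <- function(Dx, Dy, n_perm = 10000, seed = 1, exhaustive = FALSE) {
  n <- .check_mantel_input(Dx, Dy)
  if (n < 4) stop("need at least 4 entities")
  ut <- upper.tri(Dx)
  Rx <- .rank_matrix(Dx)
  ry <- rank(Dy[ut])
  obs <- stats::cor(Rx[ut], ry)
  ryc <- ry - mean(ry)
  deny <- sqrt(sum(ryc^2))
  stat_for <- function(idx) {
    rx <- Rx[idx, idx][ut]
    rxc <- rx - mean(rx)
    sum(rxc * ryc) / (sqrt(sum(rxc^2)) * deny)
  }
  if (exhaustive) {
    if (n > 7) stop("exhaustive enumeration limited to n <= 7")
    perms <- .all_perms(n)
    stats_perm <- vapply(perms, stat_for, numeric(1))
    p <- mean(stats_perm >= obs - 1e-12)
    n_used <- length(perms)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    set.seed(seed)
    stats_perm <- vapply(seq_len(n_perm), function(i) stat_for(sample.int(n)),
                         numeric(1))
    p <- (1 + sum(stats_perm >= obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(statistic = obs, p = p, n_perm = n_used),
            class = "mantel_result")
}

#' Partial Mantel permutation test (Spearman)
#'
#' Partial rank correlation of the upper triangles of `Dx` and `Dy`
#' controlling for `Dz`:
#' rho_xy.z = (rho_xy - rho_xz rho_yz) / sqrt((1 - rho_xz^2)(1 - rho_yz^2)).
#' The null permutes `Dx`'s rows and columns (raw-matrix method) and
#' recomputes the partial statistic; one-sided add-one p as in [mantel()].
#'
#' @inheritParams mantel
#' @param Dz conditioning distance matrix.
#' @return object of class `mantel_result`.
#' @export
partial_mantel <- function(Dx, Dy, Dz, n_perm = 10000, seed = 1) {
  n <- .check_mantel_input(Dx, Dy, Dz)
  if (n < 4) stop("need at least 4 entities")
  if (n_perm < 1) stop("n_perm must be >= 1")
  ut <- upper.tri(Dx)
  Rx <- .rank_matrix(Dx)
  ry <- rank(Dy[ut])
  rz <- rank(Dz[ut])
  r_yz <- stats::cor(ry, rz)
  partial <- function(rx) {
    r_xy <- stats::cor(rx, ry)
    r_xz <- stats::cor(rx, rz)
    den <- (1 - r_xz^2) * (1 - r_yz^2)
    if (den <= 1e-12) stop("degenerate partial correlation (|rho| = 1)")
    (r_xy - r_xz * r_yz) / sqrt(den)
  }
  obs <- partial(Rx[ut])
  set.seed(seed)
  stats_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    partial(Rx[idx, idx][ut])
  }, numeric(1))
  p <- (1 + sum(stats_perm >= obs - 1e-12)) / (1 + n_perm)
  structure(list(statistic = obs, p = p, n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel statistic (Spearman) =", format(x$statistic, digits = 4),
      " p =", format(x$p, digits = 4),
      " (", x$n_perm, "permutations )\n")
  invisible(x)
}
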