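#' Quality-gate genome bins into MAGs
#'
#' Retains bins with estimated completeness >= 75% and estimated
#' contamination <= 5% (both inclusive), the usual "substantially complete,
#' low contamination" criterion for calling a bin a metagenome-assembled
#' genome (MAG).
#'
#' @param quality data.frame with columns `mag_id`, `completeness` (percent,
#'   0-100) and `contamination` (percent, >= 0). Extra columns are carried
#'   through.
#' @param min_completeness completeness threshold in percent (inclusive).
#' @param max_contamination contamination threshold in percent (inclusive).
#' @return the retained rows of `quality`, in input order.
#' @export
qc_gate <- function(quality, min_completeness = 75, max_contamination = 5) {
  stopifnot(is.data.frame(quality),
            all(c("mag_id", "completeness", "contamination") %in% names(quality)))
  if (any(quality$completeness < 0) || any(quality$completeness > 100))
    stop("completeness must be within [0, 100]")
  if (any(quality$contamination < 0))
    stop("contamination must be non-negative")
  keep <- quality$completeness >= min_completeness &
    quality$contamination <= max_contamination
  quality[keep, , drop = FALSE]
}

.check_ani <- function(ani, tol = 1e-9) {
  if (!is.matrix(ani) || nrow(ani) != ncol(ani))
    stop("ani must be a square matrix")
  if (is.null(rownames(ani)) || is.null(colnames(ani)))
    stop("ani must carry mag ids as dimnames")
  if (!identical(rownames(ani), colnames(ani)))
    stop("ani row and column ids differ")
  if (max(abs(ani - t(ani))) > tol)
    stop("ani matrix asymmetric beyond tolerance ", tol)
  if (max(abs(diag(ani) - 1)) > tol)
    stop("ani matrix must have unit diagonal")
  invisible(TRUE)
}

#' Cluster MAGs into species-level clusters by average-linkage ANI
#'
#' Agglomerates MAGs on the distance d = 1 - ANI with average linkage and
#' cuts the dendrogram at height 1 - threshold (inclusive: groups whose
#' merge height is <= 1 - threshold stay together). At the default
#' threshold of 0.965 this reproduces species-level dereplication at 96.5%
#' average nucleotide identity.
#'
#' Cluster ids are assigned deterministically: MAGs are processed in
#' lexicographic id order and clusters numbered by their lexicographically
#' smallest member.
#'
#' @param ani symmetric numeric matrix of ANI values in \[0, 1\] with mag ids
#'   as dimnames and unit diagonal.
#' @param threshold ANI identity level defining species clusters.
#' @return named integer vector: cluster label per mag_id (names sorted
#'   lexicographically).
#' @export
cluster_mags <- function(ani, threshold = 0.965) {
  .check_ani(ani)
  ord <- order(rownames(ani))
  ani <- ani[ord, ord, drop = FALSE]
  n <- nrow(ani)
  if (n == 1L) {
    lab <- 1L
    names(lab) <- rownames(ani)
    return(lab)
  }
  d <- stats::as.dist(1 - ani)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, h = 1 - threshold)
  # renumber clusters by lexicographically smallest member (names are sorted)
  lab <- match(raw, unique(raw))
  names(lab) <- rownames(ani)
  lab
}

#' Pick the representative MAG of a cluster
#'
#' The member with the highest completeness after subtracting its
#' contamination; ties broken by lexicographic mag_id.
#'
#' @param members data.frame with columns `mag_id`, `completeness`,
#'   `contamination` for the MAGs of one cluster.
#' @return the representative mag_id (character scalar).
#' @export
select_representative <- function(members) {
  if (nrow(members) == 0L) stop("empty cluster has no representative")
  score <- members$completeness - members$contamination
  ord <- order(-score, members$mag_id)
  as.character(members$mag_id[ord[1L]])
}

#' Representative MAG for every cluster
#'
#' @param labels named integer vector from [cluster_mags()].
#' @param quality data.frame with `mag_id`, `completeness`, `contamination`.
#' @return named character vector: representative mag_id per cluster label.
#' @export
cluster_representatives <- function(labels, quality) {
  stopifnot(all(names(labels) %in% quality$mag_id))
  q <- quality[match(names(labels), quality$mag_id), , drop = FALSE]
  reps <- vapply(split(seq_along(labels), labels), function(idx) {
    select_representative(q[idx, , drop = FALSE])
  }, character(1))
  reps
}

#' Flag clusters with cross-cluster ANI above a cutoff
#'
#' A cluster is excluded when any of its MAGs has ANI strictly greater than
#' `cutoff` to any MAG of a different cluster, a guard against non-specific
#' read/contig quantification between near-identical species.
#'
#' @param ani symmetric ANI matrix (mag ids as dimnames).
#' @param labels named integer vector from [cluster_mags()].
#' @param cutoff exclusion ANI cutoff (strict inequality).
#' @return sorted integer vector of excluded cluster labels.
#' @export
exclusion_filter <- function(ani, labels, cutoff = 0.95) {
  .check_ani(ani)
  ids <- names(labels)
  stopifnot(all(ids %in% rownames(ani)))
  a <- ani[ids, ids, drop = FALSE]
  same <- outer(labels, labels, "==")
  bad <- (a > cutoff) & !same
  excl <- sort(unique(labels[rowSums(bad) > 0]))
  as.integer(excl)
}

#' Rarefaction of cluster discovery over samples
#'
#' For each subset size k = 1..n_samples draws `n_perm` random k-subsets of
#' samples (without replacement within a subset) and counts the distinct
#' clusters present in the union.
#'
#' @param incidence binary sample x cluster matrix (rownames = sample ids).
#' @param n_perm number of random samplings per subset size.
#' @param seed integer seed.
#' @return an `n_perm` x `n_samples` integer matrix; column k holds the
#'   distinct-cluster counts of the k-sample draws.
#' @export
rarefaction <- function(incidence, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  inc <- as.matrix(incidence) > 0
  ns <- nrow(inc)
  set.seed(seed)
  out <- matrix(NA_integer_, n_perm, ns)
  for (k in seq_len(ns)) {
    for (p in seq_len(n_perm)) {
      rows <- sample.int(ns, k)
      out[p, k] <- sum(colSums(inc[rows, , drop = FALSE]) > 0)
    }
  }
  colnames(out) <- seq_len(ns)
  out
}
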