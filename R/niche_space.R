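.gower_center <- function(M) {
  n <- nrow(M)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% M %*% J
}

#' Principal coordinates analysis with Cailliez correction
#'
#' Classical metric scaling of a dissimilarity matrix. If the configuration
#' is not Euclidean (the double-centered Gower matrix has a negative
#' eigenvalue beyond tolerance), the Cailliez additive constant c — the
#' smallest constant that, added to every off-diagonal dissimilarity, makes
#' the configuration Euclidean — is obtained as the largest real eigenvalue
#' of the standard 2n x 2n companion matrix, and the analysis is repeated on
#' D + c.
#'
#' Axes are ordered by decreasing eigenvalue and the sign of each axis is
#' fixed so that its largest-magnitude score is positive (PCoA signs are
#' otherwise arbitrary).
#'
#' @param D symmetric dissimilarity matrix, zero diagonal, no missing
#'   entries.
#' @param k number of axes to retain (default 10; capped at the number of
#'   positive eigenvalues).
#' @param tol negative-eigenvalue tolerance triggering the correction.
#' @return object of class `niche_space`: list with `coordinates`
#'   (entity x axis matrix, columns `PC1..PCk`), `eigenvalues` (all, after
#'   correction), `variance_explained` (fractions for retained axes),
#'   `correction` (the constant c, 0 if none needed), `ids`.
#' @export
pcoa_cailliez <- function(D, k = 10, tol = 1e-8) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D)) stop("D must be square")
  if (any(!is.finite(D))) stop("D contains missing or non-finite entries")
  if (max(abs(D - t(D))) > 1e-9) stop("D must be symmetric")
  if (max(abs(diag(D))) > 1e-9) stop("D must have a zero diagonal")
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("E", seq_len(n))

  delta1 <- .gower_center(-0.5 * D^2)
  ev <- eigen(delta1, symmetric = TRUE, only.values = TRUE)$values
  cc <- 0
  if (min(ev) < -tol) {
    delta2 <- .gower_center(-0.5 * D)
    companion <- rbind(cbind(matrix(0, n, n), 2 * delta1),
                       cbind(-diag(n), -4 * delta2))
    cc <- max(Re(eigen(companion, only.values = TRUE)$values))
    D <- D + cc
    diag(D) <- 0
    delta1 <- .gower_center(-0.5 * D^2)
  }
  eg <- eigen(delta1, symmetric = TRUE)
  lambda <- eg$values
  if (min(lambda) < -1e-6 * max(abs(lambda)))
    warning("negative eigenvalue persists after Cailliez correction: ",
            min(lambda))
  pos <- which(lambda > tol * max(abs(lambda), 1))
  if (!length(pos)) stop("no positive eigenvalues: degenerate configuration")
  k_eff <- min(k, length(pos))
  scores <- eg$vectors[, pos[seq_len(k_eff)], drop = FALSE] %*%
    diag(sqrt(lambda[pos[seq_len(k_eff)]]), k_eff)
  # orient each axis: largest-|score| positive
  for (j in seq_len(k_eff)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(ids, paste0("PC", seq_len(k_eff)))
  structure(list(coordinates = scores,
                 eigenvalues = lambda,
                 variance_explained = variance_explained(lambda)[seq_len(k_eff)],
                 correction = cc,
                 ids = ids),
            class = "niche_space")
}

#' @export
print.niche_space <- function(x, ...) {
  cat("Virtual niche space:", length(x$ids), "entities,",
      ncol(x$coordinates), "axes retained\n")
  cat("Cailliez constant:", format(x$correction, digits = 4), "\n")
  cat("Variance explained:",
      paste(format(100 * x$variance_explained, digits = 3), collapse = " "),
      "%\n")
  invisible(x)
}

#' Fraction of variation per ordination axis
#'
#' Each eigenvalue divided by the sum of positive eigenvalues.
#'
#' @param eigenvalues numeric vector of PCoA eigenvalues (decreasing).
#' @return per-axis fractions for the positive eigenvalues (others get 0).
#' @export
variance_explained <- function(eigenvalues) {
  pos <- eigenvalues > 0
  if (!any(pos)) stop("no positive eigenvalues")
  out <- ifelse(pos, eigenvalues, 0) / sum(eigenvalues[pos])
  out
}

#' Environmental arrows for a niche space
#'
#' Two-stage Spearman procedure: first the correlation of each cluster's
#' abundance profile with each environmental variable across samples
#' (pairwise-complete over missing values); then, per ordination axis, the
#' correlation over clusters between those coefficients and the axis
#' scores. The resulting endpoints lie in \[-1, 1\].
#'
#' @param abundances cluster x sample abundance matrix.
#' @param metadata data.frame with a `sample_id` column plus numeric
#'   environmental variables.
#' @param space a `niche_space` object for the same clusters.
#' @param variables which metadata columns to use (default: all numeric
#'   columns except `sample_id` and `mapped_read_pairs`).
#' @return variable x axis matrix of arrow endpoints.
#' @export
env_arrows <- function(abundances, metadata, space, variables = NULL) {
  stopifnot(is.matrix(abundances), inherits(space, "niche_space"))
  if (!all(rownames(abundances) == space$ids))
    stop("abundance rows and niche-space ids must agree")
  meta <- metadata[match(colnames(abundances), metadata$sample_id), ,
                   drop = FALSE]
  if (any(is.na(meta$sample_id))) stop("metadata missing for some samples")
  if (is.null(variables)) {
    num <- vapply(meta, is.numeric, logical(1))
    variables <- setdiff(names(meta)[num], c("sample_id", "mapped_read_pairs"))
  }
  axes <- colnames(space$coordinates)
  arrows <- matrix(NA_real_, length(variables), length(axes),
                   dimnames = list(variables, axes))
  for (v in variables) {
    x <- meta[[v]]
    ok <- !is.na(x)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0)
      stop("environmental variable constant or too sparse: ", v)
    rv <- apply(abundances[, ok, drop = FALSE], 1, function(ab)
      suppressWarnings(stats::cor(ab, x[ok], method = "spearman")))
    for (a in axes)
      arrows[v, a] <- suppressWarnings(
        stats::cor(rv, space$coordinates[, a], method = "spearman"))
  }
  arrows
}

#' A priori niche gradient as an abundance log-ratio
#'
#' Two modes. Group mode (`groups`): natural log of the ratio of mean
#' abundances over a high group and a low group of samples, e.g. high- vs
#' low-salinity surface samples. Paired mode (`pairs`): the mean over sample
#' pairs of the log ratio within each pair, e.g. surface/mid depth pairs or
#' 3.0/0.8 um filter pairs. A pseudocount is added to numerator and
#' denominator (means in group mode, individual values in paired mode)
#' because zero abundances occur below the detection limit.
#'
#' Clusters are flagged `included` when their maximum abundance across the
#' samples involved exceeds `threshold` (strict), mirroring the
#' low-abundance exclusion applied before prediction.
#'
#' @param abundances cluster x sample abundance matrix.
#' @param groups list(num = sample ids, den = sample ids), or NULL.
#' @param pairs data.frame with columns `num`, `den` of sample ids, or NULL.
#' @param threshold inclusion threshold in coverage per million read-pairs.
#' @param pseudocount additive constant guarding against log(0).
#' @param name gradient name.
#' @return data.frame (class `niche_gradient`) with columns `bacl_id`,
#'   `value`, `included`.
#' @export
gradient_log_ratio <- function(abundances, groups = NULL, pairs = NULL,
                               threshold = 0.01, pseudocount = 0.001,
                               name = "gradient") {
  stopifnot(is.matrix(abundances), xor(is.null(groups), is.null(pairs)))
  eps <- pseudocount
  if (!is.null(groups)) {
    if (!length(groups$num) || !length(groups$den))
      stop("empty sample group")
    miss <- setdiff(c(groups$num, groups$den), colnames(abundances))
    if (length(miss)) stop("samples not in abundance matrix: ",
                           paste(miss, collapse = ", "))
    num <- rowMeans(abundances[, groups$num, drop = FALSE])
    den <- rowMeans(abundances[, groups$den, drop = FALSE])
    value <- log((num + eps) / (den + eps))
    relevant <- unique(c(groups$num, groups$den))
  } else {
    miss <- setdiff(c(pairs$num, pairs$den), colnames(abundances))
    if (length(miss)) stop("pair member(s) not in abundance matrix: ",
                           paste(miss, collapse = ", "))
    lr <- sapply(seq_len(nrow(pairs)), function(i)
      log((abundances[, pairs$num[i]] + eps) /
            (abundances[, pairs$den[i]] + eps)))
    value <- rowMeans(lr)
    relevant <- unique(c(pairs$num, pairs$den))
  }
  maxab <- apply(abundances[, relevant, drop = FALSE], 1, max)
  out <- data.frame(bacl_id = rownames(abundances),
                    value = as.numeric(value),
                    included = maxab > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  attr(out, "threshold") <- threshold
  attr(out, "pseudocount") <- eps
  class(out) <- c("niche_gradient", "data.frame")
  out
}
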