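#' Contig coverage from an estimated fragment count
#'
#' Approximate per-contig coverage: estimated count times the nominal
#' read-pair length of 200 bp, divided by contig length.
#'
#' @param count estimated read-pair count(s) assigned to the contig, >= 0.
#' @param length contig length(s) in bp, > 0.
#' @return coverage value(s).
#' @export
contig_coverage <- function(count, length) {
  if (any(length <= 0)) stop("contig length must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count * 200 / length
}

#' MAG abundance in one sample
#'
#' Length-weighted mean of contig coverages, normalised to coverage per
#' million mapped read-pairs.
#'
#' @param coverages per-contig coverage values.
#' @param lengths per-contig lengths in bp.
#' @param mapped_pairs total mapped read-pairs of the sample.
#' @return abundance (coverage per million read-pairs).
#' @export
mag_abundance <- function(coverages, lengths, mapped_pairs) {
  stopifnot(length(coverages) == length(lengths), length(coverages) >= 1)
  if (sum(lengths) <= 0) stop("total contig length must be positive")
  if (mapped_pairs <= 0) stop("mapped read-pairs must be positive")
  wmean <- sum(coverages * lengths) / sum(lengths)
  wmean / (mapped_pairs / 1e6)
}

#' Per-MAG abundance matrix from contig tables
#'
#' @param contig_tables named list (sample id -> data.frame with columns
#'   `contig_id`, `mag_id`, `length`, `est_count`).
#' @param mapped_pairs named numeric vector: mapped read-pairs per sample.
#' @return MAG x sample abundance matrix.
#' @export
mag_abundance_matrix <- function(contig_tables, mapped_pairs) {
  stopifnot(length(contig_tables) >= 1, !is.null(names(contig_tables)))
  samples <- names(contig_tables)
  stopifnot(all(samples %in% names(mapped_pairs)))
  mags <- sort(unique(contig_tables[[1]]$mag_id))
  out <- matrix(0, length(mags), length(samples),
                dimnames = list(mags, samples))
  for (s in samples) {
    tab <- contig_tables[[s]]
    cov <- contig_coverage(tab$est_count, tab$length)
    for (m in split(seq_len(nrow(tab)), tab$mag_id)) {
      out[tab$mag_id[m[1]], s] <-
        mag_abundance(cov[m], tab$length[m], mapped_pairs[[s]])
    }
  }
  zero_samples <- colnames(out)[colSums(out) == 0]
  if (length(zero_samples))
    message("samples with zero abundance for all MAGs: ",
            paste(zero_samples, collapse = ", "))
  out
}

#' Cluster abundance profiles
#'
#' The abundance profile of a cluster is the profile of its representative
#' MAG, taken verbatim (no averaging across members).
#'
#' @param representatives named character vector (cluster label ->
#'   representative mag_id), e.g. from [cluster_representatives()].
#' @param mag_abundances MAG x sample abundance matrix.
#' @return cluster x sample abundance matrix (rownames = cluster labels).
#' @export
bacl_abundance <- function(representatives, mag_abundances) {
  missing <- setdiff(representatives, rownames(mag_abundances))
  if (length(missing))
    stop("representative MAG(s) missing from abundance matrix: ",
         paste(missing, collapse = ", "))
  out <- mag_abundances[representatives, , drop = FALSE]
  rownames(out) <- names(representatives)
  out
}

#' Abundance-profile dissimilarity
#'
#' Pairwise (1 - rho)/2 Spearman dissimilarities between per-sample
#' abundance vectors, exactly as for gene profiles.
#'
#' @param abundances cluster x sample abundance matrix.
#' @return symmetric dissimilarity matrix in \[0, 1\].
#' @export
abundance_dissimilarity <- function(abundances) {
  profile_dissimilarity(abundances)
}
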