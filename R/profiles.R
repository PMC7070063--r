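#' Gene profile of a single MAG
#'
#' Counts occurrences of each orthologous-group label carrying the exact
#' suffix `"@NOG"` over the annotation rows of one genome. A gene annotated
#' with several retained labels increments each of them; labels with other
#' suffixes (e.g. `"@ko"`, `"@biNOG"`) are ignored.
#'
#' @param annotations data.frame with columns `gene_id` and `labels`, the
#'   latter a comma-separated string of group labels per gene. An empty
#'   data.frame yields an empty profile.
#' @return named numeric vector of counts per retained label.
#' @export
build_mag_profile <- function(annotations) {
  stopifnot(is.data.frame(annotations))
  if (nrow(annotations) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (!all(c("gene_id", "labels") %in% names(annotations)))
    stop("annotations need columns gene_id and labels")
  bad <- which(is.na(annotations$labels))
  if (length(bad))
    stop("malformed annotation rows (missing labels) at lines: ",
         paste(bad, collapse = ", "))
  labs <- unlist(strsplit(annotations$labels, ",", fixed = TRUE), use.names = FALSE)
  labs <- trimws(labs)
  labs <- labs[endsWith(labs, "@NOG")]
  if (!length(labs)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(labs)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Mean gene profile of a cluster
#'
#' Per-label arithmetic mean over member MAG profiles, treating labels
#' absent from a member as zero. Cluster profiles are therefore real-valued
#' even though MAG profiles are integer counts.
#'
#' @param profiles list of named numeric vectors (one per member MAG).
#' @return named numeric vector over the union of labels.
#' @export
bacl_profile <- function(profiles) {
  if (!length(profiles)) stop("cluster has no member profiles")
  labels <- sort(unique(unlist(lapply(profiles, names), use.names = FALSE)))
  if (!length(labels)) return(stats::setNames(numeric(0), character(0)))
  acc <- numeric(length(labels))
  for (p in profiles) {
    v <- numeric(length(labels))
    v[match(names(p), labels)] <- p
    acc <- acc + v
  }
  stats::setNames(acc / length(profiles), labels)
}

#' Stack profiles into an entity x label matrix
#'
#' @param profiles named list of profiles (entity id -> named numeric vector).
#' @return numeric matrix, entities as rows, union of labels as columns,
#'   absences filled with 0.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  labels <- sort(unique(unlist(lapply(profiles, names), use.names = FALSE)))
  m <- matrix(0, length(profiles), length(labels),
              dimnames = list(names(profiles), labels))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    m[i, match(names(p), labels)] <- p
  }
  m
}

#' Prevalence filter on gene profiles
#'
#' Keeps labels present (count > 0) in at least `min_frac` of all clusters
#' ("at least 10%" means a label must appear in >= ceiling(min_frac * n)
#' profiles). Returns the profiles restricted to the kept labels.
#'
#' @param profiles entity x label numeric matrix (see [profile_matrix()]).
#' @param min_frac minimum fraction of entities a label must occur in.
#' @return the column-restricted matrix.
#' @export
prevalence_filter <- function(profiles, min_frac = 0.10) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1)
  need <- ceiling(min_frac * nrow(profiles))
  keep <- colSums(profiles > 0) >= need
  profiles[, keep, drop = FALSE]
}

#' Spearman-based profile dissimilarity
#'
#' Pairwise dissimilarity (1 - rho) / 2 where rho is the Spearman rank
#' correlation (mid-ranks for ties) between two profile vectors over the
#' shared label set. Identical rankings give 0, perfectly reversed rankings
#' give 1. Pairs involving a constant vector have undefined rho; the entry
#' is set to NA and a warning names the offending entities.
#'
#' @param profiles entity x variable numeric matrix; rows are compared.
#' @return symmetric matrix of dissimilarities in \[0, 1\], zero diagonal.
#' @export
profile_dissimilarity <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2)
  const <- apply(profiles, 1, function(x) stats::sd(x) == 0 || !all(is.finite(x)))
  rho <- suppressWarnings(stats::cor(t(profiles), method = "spearman"))
  d <- (1 - rho) / 2
  if (any(const)) {
    warning("constant profile(s), dissimilarity undefined: ",
            paste(rownames(profiles)[const], collapse = ", "))
    d[const, ] <- NA_real_
    d[, const] <- NA_real_
  }
  diag(d) <- 0
  # numerical guard: rho can exceed [-1,1] by eps
  d[!is.na(d) & d < 0] <- 0
  d[!is.na(d) & d > 1] <- 1
  d
}
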