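# Plain-TSV interchange formats. All writers are plain write.table with
# fixed options so identical in-memory objects produce byte-identical files.

#' Write a square matrix as TSV with an id header column
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path input path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a square ANI matrix TSV (mag ids as header row and first column)
#' @param path input path.
#' @export
read_ani_tsv <- function(path) {
  m <- read_matrix_tsv(path)
  .check_ani(m)
  m
}

#' Read a MAG quality table TSV
#' @param path TSV with columns mag_id, sample_id, completeness,
#'   contamination.
#' @export
read_quality_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mag_id", "completeness", "contamination")
  if (!all(need %in% names(df)))
    stop("quality table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a sample metadata TSV
#' @param path TSV with sample_id, environmental variables and
#'   mapped_read_pairs.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata needs a sample_id column")
  if ("mapped_read_pairs" %in% names(df) && any(df$mapped_read_pairs <= 0))
    stop("mapped_read_pairs must be positive")
  df
}

#' Read a gene annotation TSV (mag_id, gene_id, comma-separated labels)
#' @param path input path.
#' @export
read_annotations_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("mag_id", "gene_id", "labels")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a per-sample contig count TSV
#' @param path TSV with contig_id, mag_id, length, est_count.
#' @export
read_contig_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "mag_id", "length", "est_count")
  if (!all(need %in% names(df)))
    stop("contig table must have columns: ", paste(need, collapse = ", "))
  if (any(df$length <= 0)) stop("contig lengths must be positive")
  df
}

#' Materialize a synthetic world as on-disk pipeline inputs
#'
#' Writes the exact formats consumed by the module readers: the Newick
#' tree, a gene annotation TSV (one row per gene copy, labelled
#' `G....@NOG`), the quality TSV, the square ANI TSV, the metadata TSV and
#' one contig count TSV per sample, plus ground-truth matrices under
#' `truth/` and a `manifest.tsv` mapping roles to paths. Round-trips
#' losslessly: profiles and abundances recomputed from the files by the
#' readers equal the world's matrices.
#'
#' @param world a `synthetic_world` with at least one taxon.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
materialize_inputs <- function(world, outdir) {
  stopifnot(inherits(world, "synthetic_world"))
  if (length(world$tree$tip.label) == 0 || nrow(world$gene_matrix) == 0)
    stop("empty world: nothing to materialize")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "contigs"), showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    name
  }
  manifest <- list()

  ape::write.tree(world$tree, file.path(outdir, "tree.nwk"))
  manifest$tree <- "tree.nwk"

  gm <- world$gene_matrix
  ann <- do.call(rbind, lapply(rownames(gm), function(taxon) {
    cnt <- gm[taxon, ]
    idx <- rep(which(cnt > 0), cnt[cnt > 0])
    if (!length(idx)) return(NULL)
    data.frame(mag_id = taxon,
               gene_id = sprintf("%s_g%05d", taxon, seq_along(idx)),
               labels = paste0(colnames(gm)[idx], "@NOG"),
               stringsAsFactors = FALSE)
  }))
  manifest$annotations <- wt(ann, "annotations.tsv")
  manifest$quality <- wt(world$quality_table, "quality.tsv")
  manifest$metadata <- wt(world$environment, "metadata.tsv")
  write_matrix_tsv(world$ani_matrix, file.path(outdir, "ani.tsv"))
  manifest$ani <- "ani.tsv"

  for (s in world$environment$sample_id) {
    wt(world_contig_counts(world, s), file.path("contigs", paste0(s, ".tsv")))
  }
  manifest$contigs <- "contigs"

  write_matrix_tsv(world$gene_matrix, file.path(outdir, "truth/gene_matrix.tsv"))
  write_matrix_tsv(world$niche_traits, file.path(outdir, "truth/niche_traits.tsv"))
  write_matrix_tsv(world$abundance, file.path(outdir, "truth/abundance.tsv"))
  manifest$truth_gene_matrix <- "truth/gene_matrix.tsv"
  manifest$truth_niche_traits <- "truth/niche_traits.tsv"
  manifest$truth_abundance <- "truth/abundance.tsv"

  mf <- data.frame(role = names(manifest),
                   path = unlist(manifest, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(mf, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(mf)
}

#' Build per-MAG gene profiles from an annotation table
#'
#' @param annotations data.frame from [read_annotations_tsv()].
#' @return named list of per-MAG profiles (see [build_mag_profile()]).
#' @export
mag_profiles_from_annotations <- function(annotations) {
  lapply(split(annotations[, c("gene_id", "labels")], annotations$mag_id),
         build_mag_profile)
}
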