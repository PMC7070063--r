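#' Configuration of the synthetic world
#'
#' Parameters of the ground-truth generator used to validate the pipeline
#' end to end. The defaults describe the desk-scale world exercised by the
#' acceptance checks: 300 taxa, 500 orthologous groups of which 40 carry
#' niche signal, 100 samples along a multivariate environmental gradient.
#'
#' `beta` is the fraction of niche-trait variance determined by gene
#' content; the remainder drifts as a Brownian trait on the tree. It is an
#' artifact knob for testing, not an empirical quantity.
#'
#' @param n_taxa number of extant taxa (tree tips / MAGs).
#' @param n_genes number of orthologous groups simulated.
#' @param n_niche_genes genes contributing to the niche traits.
#' @param n_samples number of environmental samples.
#' @param birth_rate,death_rate birth-death rates per unit time.
#' @param gene_gain_rate,gene_loss_rate per-branch-length gain/loss rates of
#'   the two-state gene presence process (loss may be 0).
#' @param beta fraction in \[0,1\] of niche-trait variance that is
#'   gene-determined.
#' @param noise_sd standard deviation of log-abundance noise. The default
#'   0.3 makes abundance profiles of near-identical taxa (same species
#'   cluster) rank-correlate at ~0.93, matching the high within-cluster
#'   profile reproducibility seen in real coverage data.
#' @param detection_limit coverage floor; abundances below it become 0.
#' @param contigs_per_genome integer range (min, max) of contigs per genome.
#' @param multi_copy_frac fraction of genes allowed counts > 1.
#' @param niche_gene_turnover rate multiplier for the designated niche
#'   genes. The default 5 makes their gain/loss fast relative to tree
#'   height, so their presence pattern decouples from vertical descent —
#'   emulating horizontally transferred or rapidly gained/lost
#'   niche-determining genes, the regime in which gene content can carry
#'   ecological signal beyond phylogeny. Set to 1 for fully
#'   phylogeny-coupled niche genes.
#' @param n_latent number of latent (unrecorded) environmental drivers.
#' @param peak peak expected log-abundance at a perfect trait-environment
#'   match.
#' @param seed integer random seed; the whole world is a deterministic
#'   function of the configuration.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_taxa = 300, n_genes = 500, n_niche_genes = 40,
                             n_samples = 100, birth_rate = 1, death_rate = 0.5,
                             gene_gain_rate = 0.3, gene_loss_rate = 0.7,
                             beta = 0.5, noise_sd = 0.3, detection_limit = 0.01,
                             contigs_per_genome = c(5L, 50L),
                             multi_copy_frac = 0.10,
                             niche_gene_turnover = 5, n_latent = 2,
                             peak = 2, seed = 1) {
  stopifnot(n_taxa >= 2, n_genes >= 2, n_niche_genes >= 2, n_samples >= 2,
            n_niche_genes <= n_genes,
            birth_rate > 0, death_rate >= 0,
            gene_gain_rate > 0, gene_loss_rate >= 0,
            beta >= 0, beta <= 1, noise_sd >= 0, detection_limit >= 0,
            length(contigs_per_genome) == 2,
            contigs_per_genome[1] >= 1,
            contigs_per_genome[2] >= contigs_per_genome[1],
            multi_copy_frac >= 0, multi_copy_frac <= 1,
            niche_gene_turnover > 0, n_latent >= 0)
  structure(list(n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes),
                 n_niche_genes = as.integer(n_niche_genes),
                 n_samples = as.integer(n_samples),
                 birth_rate = birth_rate, death_rate = death_rate,
                 gene_gain_rate = gene_gain_rate,
                 gene_loss_rate = gene_loss_rate,
                 beta = beta, noise_sd = noise_sd,
                 detection_limit = detection_limit,
                 contigs_per_genome = as.integer(contigs_per_genome),
                 multi_copy_frac = multi_copy_frac,
                 niche_gene_turnover = niche_gene_turnover,
                 n_latent = as.integer(n_latent), peak = peak,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate the ground-truth phylogeny
#'
#' Birth-death tree conditioned on `n_taxa` surviving tips (so the
#' simulation cannot go extinct), rescaled to unit root-to-tip height; the
#' per-branch-length gene gain/loss rates are therefore expressed per tree
#' height. Tips are relabelled `T001..Tnnn`.
#'
#' @param cfg a `synthetic_config`.
#' @param seed overrides `cfg$seed` if given.
#' @return a rooted ultrametric `phylo` object.
#' @export
simulate_tree <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  tr <- ape::rphylo(cfg$n_taxa, birth = cfg$birth_rate,
                    death = cfg$death_rate, fossils = FALSE)
  if (any(tr$edge.length <= 0)) tr$edge.length <- pmax(tr$edge.length, 1e-9)
  depth <- max(.node_depths(tr)[seq_len(cfg$n_taxa)])
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("T%03d", seq_len(cfg$n_taxa))
  tr
}

#' Simulate phylogenetically correlated gene content
#'
#' Each gene evolves as a two-state (absent/present) continuous-time Markov
#' chain along the branches, with the root state drawn at stationarity.
#' A fixed fraction of genes is allowed counts above 1: those genes get a
#' per-gene copy number (1 plus a Poisson mark) shared by every tip that
#' carries the gene, so that tips at zero phylogenetic distance have
#' identical rows.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param cfg a `synthetic_config`.
#' @param seed overrides `cfg$seed + 1` if given.
#' @return taxa x genes non-negative integer count matrix
#'   (columns `G0001..`).
#' @export
simulate_gene_content <- function(tree, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "synthetic_config"))
  g <- cfg$gene_gain_rate
  l <- cfg$gene_loss_rate
  if (g + l <= 0) stop("gain + loss rate must be positive")
  set.seed(seed)
  n <- length(tree$tip.label)
  ng <- cfg$n_genes
  pi1 <- g / (g + l)
  # niche genes evolve with a turnover multiplier (fast turnover decouples
  # their tip pattern from the tree, emulating laterally transferred genes)
  niche <- sort(sample.int(ng, cfg$n_niche_genes))
  mult <- rep(1, ng)
  mult[niche] <- cfg$niche_gene_turnover
  nmax <- max(tree$edge)
  state <- matrix(NA_integer_, nmax, ng)
  root <- n + 1L
  state[root, ] <- stats::rbinom(ng, 1L, pi1)
  tr <- stats::reorder(tree)  # cladewise: parent before child
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]; t <- tr$edge.length[e]
    decay <- exp(-(g + l) * mult * t)
    p1 <- ifelse(state[par, ] == 1L, pi1 + (1 - pi1) * decay,
                 pi1 * (1 - decay))
    state[child, ] <- stats::rbinom(ng, 1L, p1)
  }
  presence <- state[seq_len(n), , drop = FALSE]
  n_multi <- floor(cfg$multi_copy_frac * ng)
  copies <- rep(1L, ng)
  if (n_multi > 0) {
    multi <- sample.int(ng, n_multi)
    copies[multi] <- 1L + stats::rpois(n_multi, 1)
  }
  counts <- sweep(presence, 2, copies, "*")
  dimnames(counts) <- list(tree$tip.label, sprintf("G%04d", seq_len(ng)))
  attr(counts, "niche_genes") <- colnames(counts)[niche]
  counts
}

#' Simulate niche traits, environment and abundances
#'
#' Each niche trait is `sqrt(beta)` times a standardized linear combination
#' of the designated niche genes plus `sqrt(1 - beta)` times a standardized
#' Brownian trait on the tree. The trait space has `2 + n_latent`
#' dimensions: dimension 1 maps to the observed salinity gradient,
#' dimension 2 to the depth/temperature/oxygen/nutrient axis, and the rest
#' are latent drivers with no observed proxy (so low-rank ordination axes
#' need not correlate with any measured variable). Sample positions are a
#' permuted even grid per dimension over \[-2, 2\].
#'
#' Expected log-abundance of taxon t in sample s is
#' `peak - ||z_t - e_s||^2 / n_dims` (a Gaussian niche response on
#' standardized traits), plus Normal(0, noise_sd) noise; abundances below
#' `detection_limit` are recorded as 0.
#'
#' @param tree a rooted `phylo`.
#' @param gene_matrix taxa x genes count matrix.
#' @param cfg a `synthetic_config`.
#' @param seed overrides `cfg$seed + 2` if given.
#' @return list(niche_traits, environment, abundance, niche_genes,
#'   bm_component): traits and their Brownian parts are taxa x dims;
#'   environment is a data.frame of sample metadata; abundance is taxa x
#'   samples in coverage per million read-pairs.
#' @export
simulate_niche_and_abundance <- function(tree, gene_matrix, cfg,
                                         seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "synthetic_config"),
            cfg$n_niche_genes <= ncol(gene_matrix))
  if (cfg$beta < 0 || cfg$beta > 1) stop("beta must be in [0, 1]")
  set.seed(seed)
  n <- nrow(gene_matrix)
  ndim <- 2L + cfg$n_latent
  designated <- attr(gene_matrix, "niche_genes")
  variable <- colnames(gene_matrix)[apply(gene_matrix, 2, stats::sd) > 0]
  if (!is.null(designated)) {
    niche_genes <- intersect(designated, variable)
  } else {
    if (length(variable) < cfg$n_niche_genes)
      stop("not enough variable genes to carry niche signal")
    niche_genes <- sort(sample(variable, cfg$n_niche_genes))
  }
  if (length(niche_genes) < 2)
    stop("not enough variable niche genes to carry signal")
  G <- gene_matrix[, niche_genes, drop = FALSE]

  C <- ape::vcv(tree)[rownames(gene_matrix), rownames(gene_matrix)]
  L <- chol(C)
  std <- function(x) as.numeric(scale(x))
  traits <- bm_part <- matrix(0, n, ndim,
                              dimnames = list(rownames(gene_matrix),
                                              paste0("dim", seq_len(ndim))))
  for (d in seq_len(ndim)) {
    w <- stats::rnorm(ncol(G))
    gpart <- std(G %*% w)
    bm <- std(crossprod(L, stats::rnorm(n)))
    bm_part[, d] <- bm
    traits[, d] <- sqrt(cfg$beta) * gpart + sqrt(1 - cfg$beta) * bm
  }

  ns <- cfg$n_samples
  E <- sapply(seq_len(ndim), function(d)
    seq(-2, 2, length.out = ns)[sample.int(ns)])
  colnames(E) <- paste0("dim", seq_len(ndim))
  rownames(E) <- sprintf("S%03d", seq_len(ns))

  clip <- function(x, lo) pmax(x, lo)
  env <- data.frame(
    sample_id = rownames(E),
    salinity = clip(16 + 7 * E[, 1] + stats::rnorm(ns, 0, 0.5), 0.5),
    depth = clip(100 + 55 * E[, 2] + stats::rnorm(ns, 0, 5), 1),
    filter_fraction = rep(c(0.8, 3.0), length.out = ns),
    temperature = clip(11 - 4.5 * E[, 2] + stats::rnorm(ns, 0, 0.5), 0),
    oxygen = clip(8 - 2.8 * E[, 2] + stats::rnorm(ns, 0, 0.5), 0),
    nitrate = clip(5 + 2.2 * E[, 2] + stats::rnorm(ns, 0, 0.5), 0),
    phosphate = clip(0.8 + 0.35 * E[, 2] + stats::rnorm(ns, 0, 0.1), 0),
    silicate = clip(12 + 5 * E[, 2] + stats::rnorm(ns, 0, 1), 0),
    chlorophyll_a = clip(3 - 1.2 * E[, 2] + stats::rnorm(ns, 0, 0.3), 0),
    doc = clip(4 + 1.1 * E[, 1] + stats::rnorm(ns, 0, 0.4), 0),
    mapped_read_pairs = round(stats::runif(ns, 1e6, 5e6)),
    stringsAsFactors = FALSE)
  env$layer <- ifelse(env$depth < 100, "surface", "mid")
  env$sample_set <- "synthetic"

  sqd <- outer(rowSums(traits^2), rowSums(E^2), "+") - 2 * traits %*% t(E)
  logab <- cfg$peak - sqd / ndim +
    matrix(stats::rnorm(n * ns, 0, cfg$noise_sd), n, ns)
  abundance <- exp(logab)
  abundance[abundance < cfg$detection_limit] <- 0
  dimnames(abundance) <- list(rownames(gene_matrix), rownames(E))

  list(niche_traits = traits, environment = env, abundance = abundance,
       niche_genes = niche_genes,
       bm_component = bm_part, latent_grid = E)
}

#' Generate a complete synthetic world
#'
#' Runs the tree, gene-content and niche/abundance simulators and adds the
#' remaining pipeline inputs: per-taxon contigs (with length-weighted
#' coverage factors that conserve the taxon's abundance exactly), a MAG
#' quality table, and an ANI matrix derived as a noisy monotone decreasing
#' transform of patristic distance clipped to \[0.7, 1\] (so the 96.5%
#' species threshold induces non-trivial clusters).
#'
#' The world is a deterministic function of the configuration, including
#' its seed.
#'
#' @param cfg a `synthetic_config`.
#' @return object of class `synthetic_world`: list(tree, gene_matrix,
#'   niche_traits, environment, abundance, contig_table, quality_table,
#'   ani_matrix, niche_genes, bm_component, config).
#' @export
simulate_world <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  tree <- simulate_tree(cfg)
  genes <- simulate_gene_content(tree, cfg)
  na <- simulate_niche_and_abundance(tree, genes, cfg)

  set.seed(cfg$seed + 3L)
  n <- cfg$n_taxa
  taxa <- tree$tip.label

  # decay rate 15 puts the 96.5% ANI species boundary at patristic ~0.008,
  # i.e. <1% of tree height, so same-cluster tips are near-identical
  D <- patristic_distances(tree)[taxa, taxa]
  ani <- 0.7 + 0.3 * exp(-15 * D) +
    matrix(stats::rnorm(n * n, 0, 0.002), n, n)
  ani <- (ani + t(ani)) / 2
  ani <- pmin(pmax(ani, 0.7), 1)
  diag(ani) <- 1
  dimnames(ani) <- list(taxa, taxa)

  quality <- data.frame(
    mag_id = taxa,
    sample_id = rep(na$environment$sample_id, length.out = n),
    completeness = round(stats::runif(n, 80, 100), 2),
    contamination = round(stats::runif(n, 0, 5), 2),
    stringsAsFactors = FALSE)

  rng <- cfg$contigs_per_genome
  contigs <- do.call(rbind, lapply(seq_len(n), function(i) {
    nc <- sample(seq(rng[1], rng[2]), 1)
    len <- round(stats::runif(nc, 2e4, 2e5))
    f <- stats::rlnorm(nc, 0, 0.3)
    f <- f / (sum(f * len) / sum(len))  # length-weighted mean factor = 1
    data.frame(mag_id = taxa[i],
               contig_id = sprintf("%s_c%03d", taxa[i], seq_len(nc)),
               length = len, factor = f, stringsAsFactors = FALSE)
  }))

  structure(list(tree = tree, gene_matrix = genes,
                 niche_traits = na$niche_traits,
                 environment = na$environment,
                 abundance = na$abundance,
                 contig_table = contigs,
                 quality_table = quality,
                 ani_matrix = ani,
                 niche_genes = na$niche_genes,
                 bm_component = na$bm_component,
                 config = cfg),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", x$config$n_taxa, "taxa,", x$config$n_genes,
      "genes,", x$config$n_samples, "samples (beta =", x$config$beta,
      ", seed =", x$config$seed, ")\n")
  invisible(x)
}

#' Per-sample contig count table of a synthetic world
#'
#' Decomposes each taxon's abundance into per-contig estimated counts for
#' one sample: contig coverage = taxon mean coverage times the contig's
#' stored factor (length-weighted mean factor is 1, so the length-weighted
#' mean of contig coverages reproduces the taxon's abundance exactly), and
#' estimated count = coverage * length / 200.
#'
#' @param world a `synthetic_world`.
#' @param sample_id one sample id.
#' @return data.frame(contig_id, mag_id, length, est_count).
#' @export
world_contig_counts <- function(world, sample_id) {
  stopifnot(inherits(world, "synthetic_world"))
  env <- world$environment
  mp <- env$mapped_read_pairs[match(sample_id, env$sample_id)]
  if (is.na(mp)) stop("unknown sample: ", sample_id)
  ct <- world$contig_table
  mean_cov <- world$abundance[ct$mag_id, sample_id] * (mp / 1e6)
  cov <- mean_cov * ct$factor
  data.frame(contig_id = ct$contig_id, mag_id = ct$mag_id,
             length = ct$length, est_count = cov * ct$length / 200,
             stringsAsFactors = FALSE)
}
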