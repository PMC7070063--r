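test_that("synthetic_config validates its invariants", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(n_taxa = 1))
  expect_error(synthetic_config(beta = 1.2))
  expect_error(synthetic_config(detection_limit = -1))
  expect_error(synthetic_config(n_niche_genes = 600, n_genes = 500))
  expect_error(synthetic_config(birth_rate = 0))
})

test_that("simulate_tree: forced topology, determinism, ultrametricity", {
  cfg2 <- synthetic_config(n_taxa = 2, n_genes = 10, n_niche_genes = 2,
                           n_samples = 5, seed = 1)
  tr2 <- simulate_tree(cfg2)
  expect_equal(length(tr2$tip.label), 2)
  expect_equal(tr2$Nnode, 1)
  cfg <- synthetic_config(n_taxa = 64, seed = 1)
  nwk1 <- ape::write.tree(simulate_tree(cfg))
  nwk2 <- ape::write.tree(simulate_tree(cfg))
  expect_identical(nwk1, nwk2)
  # independent depth traversal: all root-to-tip distances equal
  tr <- simulate_tree(cfg)
  depths <- ape::node.depth.edgelength(tr)[seq_len(64)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_true(all(tr$edge.length > 0))
})

test_that("gene content: absorbing state and zero-distance sisters", {
  cfg <- synthetic_config(n_taxa = 20, n_genes = 50, n_niche_genes = 5,
                          n_samples = 5, gene_gain_rate = 1,
                          gene_loss_rate = 0, multi_copy_frac = 0, seed = 2)
  tr <- simulate_tree(cfg)
  gm <- simulate_gene_content(tr, cfg)
  # loss rate 0: stationary state is all-present and absorbing
  expect_true(all(gm == 1))
  # sister tips at (effectively) zero distance carry identical rows
  cfg2 <- synthetic_config(n_taxa = 10, n_genes = 100, n_niche_genes = 5,
                           n_samples = 5, seed = 3)
  tr2 <- simulate_tree(cfg2)
  tip <- which(tr2$edge[, 2] <= 10)
  # graft a zero-length cherry: set two sister tip branches to ~0
  sis <- which(duplicated(tr2$edge[tip, 1]) |
                 duplicated(tr2$edge[tip, 1], fromLast = TRUE))
  pair <- tip[tr2$edge[tip, 1] == tr2$edge[tip[sis[1]], 1]][1:2]
  tr2$edge.length[pair] <- 1e-12
  gm2 <- simulate_gene_content(tr2, cfg2)
  tips <- tr2$edge[pair, 2]
  expect_identical(gm2[tips[1], ], gm2[tips[2], ])
})

test_that("niche traits interpolate between genes and Brownian motion", {
  base <- list(n_taxa = 50, n_genes = 120, n_niche_genes = 15, n_samples = 20)
  # beta = 1, no noise: traits are an exact linear function of niche genes
  cfg1 <- do.call(synthetic_config, c(base, beta = 1, noise_sd = 0, seed = 4))
  tr <- simulate_tree(cfg1)
  gm <- simulate_gene_content(tr, cfg1)
  na1 <- simulate_niche_and_abundance(tr, gm, cfg1)
  G <- cbind(1, gm[, na1$niche_genes])
  for (d in seq_len(ncol(na1$niche_traits))) {
    resid <- stats::lm.fit(G, na1$niche_traits[, d])$residuals
    expect_lt(max(abs(resid)), 1e-9)
  }
  # noiseless Gaussian response peaks in the nearest sample
  cfg0 <- do.call(synthetic_config, c(base, beta = 1, noise_sd = 0,
                                      detection_limit = 0, seed = 4))
  na0 <- simulate_niche_and_abundance(tr, gm, cfg0)
  E <- na0$latent_grid
  for (t in c(1, 25, 50)) {
    d2 <- colSums((t(E) - na0$niche_traits[t, ])^2)
    expect_equal(which.max(na0$abundance[t, ]), which.min(d2),
                 ignore_attr = TRUE)
  }
  # beta = 0: trait is (a standardized copy of) its Brownian component
  cfg00 <- do.call(synthetic_config, c(base, beta = 0, seed = 5))
  na00 <- simulate_niche_and_abundance(tr, gm, cfg00)
  for (d in seq_len(ncol(na00$niche_traits)))
    expect_gte(cor(na00$niche_traits[, d], na00$bm_component[, d],
                   method = "spearman"), 0.99)
})

test_that("worlds are bit-identical given the same config", {
  cfg <- synthetic_config(n_taxa = 25, n_genes = 40, n_niche_genes = 6,
                          n_samples = 10, seed = 9)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1$gene_matrix, w2$gene_matrix)
  expect_identical(w1$abundance, w2$abundance)
  expect_identical(w1$ani_matrix, w2$ani_matrix)
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))
  expect_identical(w1$contig_table, w2$contig_table)
})

test_that("world invariants hold", {
  w <- small_world(seed = 10)
  expect_true(all(w$abundance >= 0))
  expect_true(all(w$gene_matrix >= 0))
  expect_equal(w$ani_matrix, t(w$ani_matrix))
  expect_equal(unname(diag(w$ani_matrix)), rep(1, nrow(w$ani_matrix)))
  expect_setequal(w$tree$tip.label, rownames(w$gene_matrix))
  # contig decomposition conserves the generating abundance
  ct <- world_contig_counts(w, "S001")
  mp <- w$environment$mapped_read_pairs[w$environment$sample_id == "S001"]
  for (taxon in rownames(w$abundance)[1:5]) {
    rows <- ct$mag_id == taxon
    expect_equal(mag_abundance(contig_coverage(ct$est_count[rows],
                                               ct$length[rows]),
                               ct$length[rows], mp),
                 w$abundance[taxon, "S001"], tolerance = 1e-9)
  }
})

test_that("materialized inputs round-trip through the readers", {
  w <- small_world(seed = 12, n_taxa = 10, n_samples = 5, n_genes = 25)
  dir <- withr::local_tempdir()
  mf <- materialize_inputs(w, dir)
  expect_true(all(file.exists(file.path(dir, setdiff(mf$path, "contigs")))))
  # gene profiles rebuilt from the annotation TSV equal the gene matrix
  ann <- read_annotations_tsv(file.path(dir, "annotations.tsv"))
  profs <- profile_matrix(mag_profiles_from_annotations(ann))
  colnames(profs) <- sub("@NOG$", "", colnames(profs))
  carried <- colnames(w$gene_matrix)[colSums(w$gene_matrix) > 0]
  expect_equal(profs[rownames(w$gene_matrix), carried],
               w$gene_matrix[, carried])
  # ANI and tree round-trip
  expect_equal(read_ani_tsv(file.path(dir, "ani.tsv")), w$ani_matrix,
               tolerance = 1e-12)
  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, w$tree$tip.label)
  # a low-completeness taxon is dropped by the QC gate downstream
  w$quality_table$completeness[1] <- 60
  dir2 <- withr::local_tempdir()
  materialize_inputs(w, dir2)
  q <- read_quality_tsv(file.path(dir2, "quality.tsv"))
  expect_false(w$quality_table$mag_id[1] %in% qc_gate(q)$mag_id)
})

test_that("empty worlds are rejected before writing files", {
  w <- small_world(seed = 13, n_taxa = 10, n_samples = 5, n_genes = 25)
  w$gene_matrix <- w$gene_matrix[0, , drop = FALSE]
  expect_error(materialize_inputs(w, withr::local_tempdir()), "empty")
})

test_that("gene-based predictability is monotone in beta", {
  # statistical property: over replicate worlds, mean cross-validated rho
  # of a gene-based model is non-decreasing in beta (majority ordering)
  rho_for <- function(beta, seed) {
    w <- simulate_world(synthetic_config(
      n_taxa = 80, n_genes = 150, n_niche_genes = 20, n_samples = 40,
      beta = beta, noise_sd = 0.3, seed = seed))
    X <- prevalence_filter(w$gene_matrix)
    sp <- pcoa_cailliez(abundance_dissimilarity(w$abundance), k = 2)
    kfold_cv(X, sp$coordinates[, "PC1"],
             model_config("ridge", cv_folds = 5, seed = seed))$rho
  }
  seeds <- 101:110
  m0 <- mean(vapply(seeds, function(s) rho_for(0, s), numeric(1)))
  m5 <- mean(vapply(seeds, function(s) rho_for(0.5, s), numeric(1)))
  m1 <- mean(vapply(seeds, function(s) rho_for(1, s), numeric(1)))
  expect_true(m0 <= m5 + 0.05 && m5 <= m1 + 0.05)
  expect_gt(m1, m0)
})
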