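test_that("pairwise alignment statistics match definitions and a DP oracle", {
  expect_equal(align_pair("ACGTACGTAC", "ACGTACGTAC")$identity, 100)
  expect_equal(align_pair("ACGTACGTAC", "ACGTACGTAC")$coverage, 100)
  expect_equal(align_pair("ACGTACGTAC", "ACGTACGTAG")$identity, 90)
  expect_error(align_pair("", "ACGT"), "non-empty")
  set.seed(4)
  for (i in 1:25) {
    a <- random_dna_string(sample(5:30, 1))
    b <- random_dna_string(sample(5:30, 1))
    f <- align_pair(a, b)
    r <- align_pair(b, a)
    expect_equal(f$identity, r$identity)
    expect_equal(f$coverage, r$coverage)
    expect_equal(f$score, nw_score_oracle(a, b))
    # alignment strings must be a consistent encoding of the statistics
    cols <- nchar(f$alignment[["a"]])
    expect_equal(cols, nchar(f$alignment[["b"]]))
    xa <- strsplit(f$alignment[["a"]], "")[[1]]
    xb <- strsplit(f$alignment[["b"]], "")[[1]]
    expect_equal(sum(xa == xb & xa != "-"), round(f$identity * cols / 100))
  }
})

make_family_genes <- function(n_fam, copies, len, div, seed) {
  set.seed(seed)
  rows <- list()
  for (f in seq_len(n_fam)) {
    anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    for (k in seq_len(copies)) {
      x <- anc
      mut <- runif(len) < div
      x[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = sprintf("g%02d", k),
        gene_id = sprintf("f%02d_g%02d", f, k),
        sequence = paste(x, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("single-linkage clustering equals brute-force transitive closure", {
  genes <- make_family_genes(n_fam = 5, copies = 4, len = 120, div = 0.1,
                             seed = 7)
  catl <- cluster_genes(genes, prefilter = "none")
  oracle <- single_linkage_oracle(genes)
  genes_sorted <- genes[order(genes$genome_id, genes$gene_id), ]
  got <- catl$membership$cluster_id[match(genes_sorted$gene_id,
                                          catl$membership$gene_id)]
  expect_equal(mclust::adjustedRandIndex(got, oracle[order(genes$genome_id,
                                                           genes$gene_id)]), 1)
  # partition property
  expect_equal(nrow(catl$membership), nrow(genes))
  expect_equal(sum(table(catl$membership$cluster_id)), nrow(genes))
})

test_that("degenerate threshold settings give one cluster or all singletons", {
  g3 <- data.frame(genome_id = c("a", "b", "c"), gene_id = c("x", "y", "z"),
                   sequence = rep("ACGTACGTACGT", 3), stringsAsFactors = FALSE)
  expect_equal(cluster_genes(g3)$n_clusters, 1)
  genes <- make_family_genes(4, 3, 80, 0.05, seed = 2)
  catl <- cluster_genes(genes, min_identity = 100.1, prefilter = "none")
  expect_equal(catl$n_clusters, nrow(genes))
})

test_that("raising the identity threshold only refines clusters", {
  genes <- make_family_genes(4, 5, 100, 0.12, seed = 11)
  lo <- cluster_genes(genes, min_identity = 60, prefilter = "none")
  hi <- cluster_genes(genes, min_identity = 85, prefilter = "none")
  lo_of <- setNames(lo$membership$cluster_id, lo$membership$gene_id)
  hi_clusters <- split(hi$membership$gene_id, hi$membership$cluster_id)
  for (cl in hi_clusters)
    expect_length(unique(lo_of[cl]), 1)
})

test_that("k-mer prefilter reproduces the unfiltered clustering", {
  cfg <- sim_config(n_species = 2, genomes_per_species = 3,
                    n_core_families = 12, n_accessory_families = 15,
                    gene_length = 150, seed = 17)
  sim <- simulate_genomes(cfg)
  a <- cluster_genes(sim$genes, prefilter = "none")
  b <- cluster_genes(sim$genes, prefilter = "kmer")
  expect_identical(a$membership[, c("cluster_id", "gene_id")],
                   b$membership[, c("cluster_id", "gene_id")])
})

test_that("presence/absence matrix reflects cluster occupancy", {
  genes <- data.frame(
    genome_id = c("g1", "g2", "g3", "g4", "g1"),
    gene_id = c("a1", "a2", "b1", "b2", "c1"),
    sequence = c("ACGTACGTAA", "ACGTACGTAA", "TTTTGGGGCC", "TTTTGGGGCC",
                 "GAGAGAGACC"),
    stringsAsFactors = FALSE)
  catl <- cluster_genes(genes)
  pa <- build_presence_absence(catl, genomes = c("g1", "g2", "g3", "g4"))
  expect_equal(dim(pa), c(3L, 4L))
  shared <- pa[rowSums(pa) == 2, , drop = FALSE]
  expect_equal(unname(shared[1, ]), c(1L, 1L, 0L, 0L))
  expect_equal(unname(shared[2, ]), c(0L, 0L, 1L, 1L))
  expect_error(build_presence_absence(catl, genomes = c("g1", "g2")),
               "missing")
})

test_that("row sums equal the simulator's carrier-set sizes", {
  cfg <- sim_config(n_species = 2, genomes_per_species = 3,
                    n_core_families = 12, n_accessory_families = 20,
                    gene_length = 200, seed = 23)
  sim <- simulate_genomes(cfg)
  catl <- cluster_genes(sim$genes)
  expect_equal(score_clustering(catl, sim$truth), 1)
  pa <- build_presence_absence(catl)
  map <- match_clusters_to_families(catl, sim$truth)
  sizes_truth <- lengths(sim$truth$carriers)[map$family_id[match(rownames(pa),
                                                                 map$cluster_id)]]
  expect_equal(unname(rowSums(pa)), unname(sizes_truth))
})
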