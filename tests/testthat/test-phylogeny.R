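test_that("center-star alignment is exact for the star objective", {
  # identical members: no gap columns, input preserved
  aln <- center_star_align(c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC"))
  expect_equal(ncol(aln), 6)
  expect_false(any(aln == "-"))
  # simulator families are indel-free: width equals the gene length
  cfg <- sim_config(n_species = 2, genomes_per_species = 2,
                    n_core_families = 3, n_accessory_families = 0,
                    gene_length = 150, seed = 3)
  sim <- simulate_genomes(cfg)
  fam1 <- sim$genes[grepl("fam00001", sim$genes$gene_id), ]
  a1 <- center_star_align(setNames(fam1$sequence, fam1$genome_id))
  expect_equal(ncol(a1), 150)
  expect_false(any(a1 == "-"))
  # with indels, every member's projection onto the center achieves the
  # optimal pairwise score (the star objective's optimum)
  set.seed(9)
  for (rep in 1:10) {
    seqs <- setNames(vapply(1:3, function(i)
      random_dna_string(sample(6:12, 1)), ""), c("s1", "s2", "s3"))
    aln <- center_star_align(seqs)
    center <- attr(aln, "center")
    score_row <- function(x, y) {
      keep <- !(x == "-" & y == "-")
      x <- x[keep]; y <- y[keep]
      sum(ifelse(x == "-" | y == "-", -4, ifelse(x == y, 1, -1)))
    }
    for (m in setdiff(rownames(aln), center)) {
      expect_equal(score_row(aln[center, ], aln[m, ]),
                   nw_score_oracle(seqs[[center]], seqs[[m]], gap = -4))
    }
  }
})

test_that("Jukes-Cantor distances follow the closed form", {
  base <- strsplit(paste(rep("ACGT", 125), collapse = ""), "")[[1]]
  other <- base
  other[seq_len(50)] <- chartr("ACGT", "CAGT", other[seq_len(50)])
  changed <- sum(base != other)  # 25 columns actually differ per ACGT block
  aln <- rbind(r1 = base, r2 = other)
  d <- jc_distance_matrix(aln)
  p <- changed / 500
  expect_equal(d["r1", "r2"], -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_equal(d, t(d))
  # p = 0.1 reproduces the textbook value 0.1073
  x <- rep("A", 100); y <- x; y[1:10] <- "G"
  d2 <- jc_distance_matrix(rbind(a = x, b = y))
  expect_equal(round(d2["a", "b"], 4), 0.1073)
  # saturation is capped with a warning
  expect_warning(jc_distance_matrix(rbind(a = rep("A", 20), b = rep("C", 20))),
                 "saturated")
  # gap columns are excluded pairwise
  g <- rbind(a = c("A", "C", "G", "T"), b = c("A", "-", "G", "A"))
  expect_equal(jc_distance_matrix(g)["a", "b"],
               -0.75 * log(1 - (4 / 3) * (1 / 3)))
})

test_that("neighbor joining is consistent on additive matrices", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  D <- cophenetic(tr)
  nj <- build_nj(D)
  expect_equal(rf_distance(nj, tr), 0)
  expect_equal(cophenetic(nj)[rownames(D), colnames(D)], D, tolerance = 1e-9)
  # internal branch of ab|cd is 1
  internal <- nj$edge.length[nj$edge[, 2] > length(nj$tip.label)]
  expect_equal(sort(internal)[length(internal)], 1, tolerance = 1e-9)
  # random additive matrices up to 8 taxa
  set.seed(10)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    rt <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    D <- cophenetic(rt)
    got <- build_nj(D)
    expect_equal(rf_distance(got, rt), 0)
    expect_equal(cophenetic(got)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(build_nj(bad), "symmetric|3 taxa")
})

test_that("three-taxon trees use the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_nj(D)
  expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("bootstrap on a zero-divergence alignment gives full support", {
  aln <- matrix("A", 5, 40, dimnames = list(paste0("t", 1:5), NULL))
  D <- matrix(0, 5, 5, dimnames = list(rownames(aln), rownames(aln)))
  tr <- suppressWarnings(build_nj(D, bootstrap = 25, alignment = aln, seed = 2))
  expect_true(all(tr$node.label == 100))
})

test_that("UPGMA reconstructs ultrametric inputs exactly", {
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  u <- build_upgma(d2)
  expect_equal(sort(u$edge.length), c(2, 2))
  set.seed(12)
  for (i in 1:10) {
    rt <- ape::rcoal(sample(4:10, 1))
    D <- cophenetic(rt)
    got <- build_upgma(D)
    expect_equal(cophenetic(got)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    # heights monotone: every parent edge keeps tips equidistant from root
    depths <- ape::node.depth.edgelength(got)
    tips <- seq_along(got$tip.label)
    expect_lt(diff(range(depths[tips])), 1e-8)
  }
})

test_that("ANI matches the Jukes-Cantor identity at the planted divergence", {
  cfg <- sim_config(n_species = 1, genomes_per_species = 2,
                    n_core_families = 50, n_accessory_families = 0,
                    gene_length = 900, within_species_divergence = 0.05,
                    between_species_divergence = 0.05, seed = 6)
  sim <- simulate_genomes(cfg)
  catl <- cluster_genes(sim$genes)
  ani <- ani_matrix(catl)
  expect_equal(unname(diag(ani)), c(100, 100))
  expect_equal(ani, t(ani))
  d <- pairwise_divergence(sim$truth)[rownames(ani)[1], rownames(ani)[2]]
  p_exp <- jc_expected_identity(d)
  sites <- 50 * 900
  se <- sqrt(p_exp * (1 - p_exp) / sites)
  expect_lt(abs(ani[1, 2] / 100 - p_exp), 3 * se)
})

test_that("species clustering at 95% ANI recovers the simulated clades", {
  cfg <- sim_config(n_species = 2, genomes_per_species = 3,
                    n_core_families = 40, n_accessory_families = 0,
                    gene_length = 400, seed = 15)
  sim <- simulate_genomes(cfg)
  catl <- cluster_genes(sim$genes)
  ani <- ani_matrix(catl)
  grp <- cluster_species(ani, threshold = 95)
  truth_sp <- setNames(sim$truth$groups$species, sim$truth$groups$genome_id)
  expect_equal(mclust::adjustedRandIndex(grp, truth_sp[names(grp)]), 1)
  # within-species ANI sits in the calibrated 95-96% band
  same <- outer(truth_sp[rownames(ani)], truth_sp[colnames(ani)], "==")
  w <- ani[same & upper.tri(ani)]
  b <- ani[!same & upper.tri(ani)]
  expect_gt(min(w), max(b))
})

test_that("genomes sharing no single-copy cluster yield NA ANI with warning", {
  genes <- data.frame(genome_id = c("g1", "g2"), gene_id = c("x", "y"),
                      sequence = c(random_dna_string(80), random_dna_string(80)),
                      stringsAsFactors = FALSE)
  catl <- cluster_genes(genes)  # two singleton clusters
  expect_warning(ani <- ani_matrix(catl), "no single-copy")
  expect_true(is.na(ani["g1", "g2"]))
})
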