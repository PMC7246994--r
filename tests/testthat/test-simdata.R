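test_that("species tree has the configured clade layout and is seed-deterministic", {
  tr <- simulate_species_tree(4, 8, 0.085, 0.046, seed = 3)
  expect_length(tr$tip.label, 32)
  groups <- attr(tr, "groups")
  for (s in unique(groups$species))
    expect_true(ape::is.monophyletic(tr, groups$genome_id[groups$species == s]))
  tr2 <- simulate_species_tree(4, 8, 0.085, 0.046, seed = 3)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # zero within-species divergence collapses a single clade to a star
  star <- simulate_species_tree(1, 3, 0.2, 0.0, seed = 1)
  expect_length(star$tip.label, 3)
  expect_true(all(star$edge.length == 0))
  expect_error(simulate_species_tree(0, 3, 0.1, 0.1), "counts")
})

test_that("zero divergence and forced presence behave as designed", {
  cfg <- sim_config(n_species = 2, genomes_per_species = 2,
                    n_core_families = 5, n_accessory_families = 4,
                    accessory_presence_prob = 1, clade_restricted_frac = 0,
                    gene_length = 60, within_species_divergence = 0,
                    between_species_divergence = 0, seed = 5)
  sim <- simulate_genomes(cfg)
  # no mutation: all copies of a family are identical strings
  fam <- sim$truth$genes$family_id
  for (f in unique(fam))
    expect_length(unique(sim$genes$sequence[fam == f]), 1)
  # forced presence: every family in every genome
  expect_true(all(lengths(sim$truth$carriers) == 4))
})

test_that("carrier bookkeeping matches the emitted genes", {
  cfg <- sim_config(n_species = 3, genomes_per_species = 3,
                    n_core_families = 10, n_accessory_families = 30,
                    gene_length = 50, seed = 8)
  sim <- simulate_genomes(cfg)
  by_fam <- split(sim$truth$genes$genome_id, sim$truth$genes$family_id)
  for (f in names(sim$truth$carriers)) {
    expect_setequal(by_fam[[f]] %||% character(0), sim$truth$carriers[[f]])
  }
  core <- sim$truth$families$family_id[sim$truth$families$type == "core"]
  expect_true(all(lengths(sim$truth$carriers[core]) == 9))
})

test_that("pairwise identity matches the Jukes-Cantor expectation", {
  cfg <- sim_config(n_species = 2, genomes_per_species = 2,
                    n_core_families = 60, n_accessory_families = 0,
                    gene_length = 500, within_species_divergence = 0.03,
                    between_species_divergence = 0.1, seed = 13)
  sim <- simulate_genomes(cfg)
  div <- pairwise_divergence(sim$truth)
  genomes <- rownames(div)
  core <- sim$truth$families$family_id[sim$truth$families$type == "core"]
  seq_of <- function(g, f) sim$genes$sequence[sim$genes$gene_id == paste(f, g, sep = ".")]
  for (a in 1:3) for (b in (a + 1):4) {
    ga <- genomes[a]; gb <- genomes[b]
    matches <- 0; sites <- 0
    for (f in core) {
      xa <- strsplit(seq_of(ga, f), "")[[1]]
      xb <- strsplit(seq_of(gb, f), "")[[1]]
      matches <- matches + sum(xa == xb)
      sites <- sites + length(xa)
    }
    p_exp <- jc_expected_identity(div[ga, gb])
    se <- sqrt(p_exp * (1 - p_exp) / sites)
    expect_lt(abs(matches / sites - p_exp), 3 * se)
  }
})

test_that("generation is deterministic down to the FASTA bytes", {
  cfg <- sim_config(n_species = 2, genomes_per_species = 3,
                    n_core_families = 8, n_accessory_families = 10,
                    gene_length = 40, n_hgt_events = 2, seed = 21)
  s1 <- simulate_pangenome(cfg)
  s2 <- simulate_pangenome(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$truth$hgt_events, s2$truth$hgt_events)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_gene_fasta(s1$genes, f1, s1$truth)
  write_gene_fasta(s2$genes, f2, s2$truth)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_gene_fasta(f1)
  expect_equal(back$sequence, s1$genes$sequence)
  expect_equal(back$genome_id, s1$genes$genome_id)
})

test_that("planted transfers pull the recipient toward the donor clade", {
  cfg <- sim_config(n_species = 2, genomes_per_species = 4,
                    n_core_families = 10, n_accessory_families = 0,
                    gene_length = 400, within_species_divergence = 0.01,
                    between_species_divergence = 0.15, seed = 2)
  sim <- simulate_genomes(cfg)
  expect_identical(plant_hgt(sim$genes, sim$truth, 0)$genes, sim$genes)
  out <- plant_hgt(sim$genes, sim$truth, 1, seed = 9)
  ev <- out$truth$hgt_events
  expect_equal(nrow(ev), 1)
  groups <- out$truth$groups
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  rec_seq <- out$genes$sequence[out$genes$gene_id ==
                                  paste(ev$family_id, ev$recipient_genome, sep = ".")]
  donor_clade <- setdiff(groups$genome_id[groups$species == ev$donor_species],
                         ev$recipient_genome)
  own_clade <- setdiff(groups$genome_id[groups$species == ev$recipient_species],
                       ev$recipient_genome)
  id_to <- function(g) ident(rec_seq,
    out$genes$sequence[out$genes$gene_id == paste(ev$family_id, g, sep = ".")])
  expect_gt(min(vapply(donor_clade, id_to, 0)), max(vapply(own_clade, id_to, 0)))
  # determinism of the event list
  out2 <- plant_hgt(sim$genes, sim$truth, 1, seed = 9)
  expect_identical(out$truth$hgt_events, out2$truth$hgt_events)
  expect_error(plant_hgt(sim$genes, sim$truth, 99), "exceeds")
})
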