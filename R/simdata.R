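#' Configuration for the multi-species pan-genome simulator
#'
#' Bundles and validates every tunable of the generator. Defaults describe a
#' 4-species x 8-genome bacterial dataset: 600 core gene families shared by
#' all genomes plus 1200 accessory families with Bernoulli presence (half of
#' them restricted to a single species clade, which is what produces shell,
#' cloud and species-specific accessory classes). Divergence defaults are
#' calibrated on the Jukes-Cantor closed form so that within-species average
#' nucleotide identity lands near 95.5% (the conventional 95-96% span for
#' conspecific bacterial genomes) and between-species identity near 92%.
#'
#' @param n_species number of species clades (>= 1).
#' @param genomes_per_species genomes per clade (>= 1).
#' @param n_core_families gene families carried by every genome (>= 1).
#' @param n_accessory_families accessory families (>= 0).
#' @param accessory_presence_prob per-genome Bernoulli presence probability
#'   for accessory families, in `[0, 1]`.
#' @param clade_restricted_frac fraction of accessory families whose carriers
#'   are restricted to one (randomly chosen) species clade.
#' @param gene_length length of each gene in bp; scalar or a vector recycled
#'   across families (core families first, then accessory).
#' @param within_species_divergence expected pairwise substitutions/site
#'   between two genomes of the same species.
#' @param between_species_divergence expected pairwise substitutions/site
#'   between genomes of different species; must be >= the within value.
#' @param n_hgt_events number of horizontal transfer events to plant (>= 0).
#' @param seed integer seed; the full generator is deterministic given the
#'   configuration and seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_species = 4,
                       genomes_per_species = 8,
                       n_core_families = 600,
                       n_accessory_families = 1200,
                       accessory_presence_prob = 0.3,
                       clade_restricted_frac = 0.5,
                       gene_length = 900,
                       within_species_divergence = 0.046,
                       between_species_divergence = 0.085,
                       n_hgt_events = 0,
                       seed = 1) {
  if (n_species < 1 || genomes_per_species < 1 || n_core_families < 1)
    stop("n_species, genomes_per_species and n_core_families must be >= 1")
  if (n_accessory_families < 0 || n_hgt_events < 0)
    stop("n_accessory_families and n_hgt_events must be >= 0")
  if (accessory_presence_prob < 0 || accessory_presence_prob > 1)
    stop("accessory_presence_prob must be in [0, 1]")
  if (clade_restricted_frac < 0 || clade_restricted_frac > 1)
    stop("clade_restricted_frac must be in [0, 1]")
  if (any(gene_length < 1)) stop("gene_length must be positive")
  if (within_species_divergence < 0 || between_species_divergence < 0)
    stop("divergences must be >= 0")
  if (within_species_divergence > between_species_divergence)
    stop("within_species_divergence must be <= between_species_divergence")
  if (n_hgt_events > 0 && n_species < 2)
    stop("planting HGT requires at least two species")
  if (n_hgt_events > n_core_families)
    stop("n_hgt_events cannot exceed the number of core families")
  structure(list(
    n_species = as.integer(n_species),
    genomes_per_species = as.integer(genomes_per_species),
    n_core_families = as.integer(n_core_families),
    n_accessory_families = as.integer(n_accessory_families),
    accessory_presence_prob = accessory_presence_prob,
    clade_restricted_frac = clade_restricted_frac,
    gene_length = as.integer(gene_length),
    within_species_divergence = within_species_divergence,
    between_species_divergence = between_species_divergence,
    n_hgt_events = as.integer(n_hgt_events),
    seed = as.integer(seed)
  ), class = "sim_config")
}

genome_labels <- function(n_species, genomes_per_species) {
  sp <- sprintf("sp%02d", seq_len(n_species))
  data.frame(
    genome_id = as.vector(t(outer(sp, sprintf("g%02d", seq_len(genomes_per_species)),
                                  paste, sep = "_"))),
    species = rep(sp, each = genomes_per_species),
    stringsAsFactors = FALSE
  )
}

#' Simulate a species tree over genomes
#'
#' Builds a genome-labelled tree with `n_species` monophyletic clades. Each
#' genome tip hangs off its species ancestor at ~`within_div`/2 and each
#' species ancestor off the root at ~(`between_div` - `within_div`)/2, so
#' expected tip-to-tip path lengths are `within_div` within a clade and
#' `between_div` across clades. Branch lengths get a mild multiplicative
#' jitter (uniform on 0.8-1.2) so realized divergences vary around their
#' expectation; zero divergence collapses exactly to zero-length branches.
#'
#' @param n_species,genomes_per_species clade layout (counts >= 1).
#' @param between_div,within_div expected pairwise divergences
#'   (substitutions/site, `within_div <= between_div`).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return an `ape::phylo` tree whose tip labels are genome ids, with
#'   attributes `groups` (genome/species table), `tip_branch` and
#'   `species_branch` (named numeric vectors of realized branch lengths).
#' @export
simulate_species_tree <- function(n_species, genomes_per_species,
                                  between_div, within_div, seed = NULL) {
  if (n_species < 1 || genomes_per_species < 1)
    stop("counts must be >= 1")
  if (between_div < 0 || within_div < 0) stop("divergences must be >= 0")
  if (n_species * genomes_per_species < 2)
    stop("need at least two genomes in total")
  with_seed(seed, {
    lab <- genome_labels(n_species, genomes_per_species)
    tip_branch <- (within_div / 2) * runif(nrow(lab), 0.8, 1.2)
    names(tip_branch) <- lab$genome_id
    sp <- unique(lab$species)
    species_branch <- ((between_div - within_div) / 2) * runif(n_species, 0.8, 1.2)
    names(species_branch) <- sp
    clades <- vapply(sp, function(s) {
      tips <- lab$genome_id[lab$species == s]
      inner <- paste(sprintf("%s:%.10f", tips, tip_branch[tips]), collapse = ",")
      if (n_species == 1) {
        sprintf("(%s)", inner)
      } else if (length(tips) == 1) {
        # avoid a degree-2 node: fold the species branch into the tip
        sprintf("%s:%.10f", tips, tip_branch[tips] + species_branch[s])
      } else {
        sprintf("(%s):%.10f", inner, species_branch[s])
      }
    }, character(1))
    nwk <- if (n_species == 1) paste0(clades, ";") else
      sprintf("(%s);", paste(clades, collapse = ","))
    tree <- ape::read.tree(text = nwk)
    attr(tree, "groups") <- lab
    attr(tree, "tip_branch") <- tip_branch
    attr(tree, "species_branch") <- species_branch
    tree
  })
}

#' Simulate a multi-species pan-genome with recorded ground truth
#'
#' For every gene family an ancestral sequence is drawn uniformly over
#' A/C/G/T; each carrier genome's copy evolves from it along the species
#' tree under a Jukes-Cantor substitution process (no indels, so copies of
#' a family stay equal-length and positionally homologous). Core families
#' are carried by every genome; accessory carriers are i.i.d. Bernoulli
#' draws, optionally restricted to one species clade. Accessory families
#' that draw zero carriers contribute no genes but remain in the truth.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (a `genome_set` data frame: `genome_id`,
#'   `gene_id`, `sequence`) and `truth` (class `sim_truth`: config, species
#'   tree, genome groups, realized branch lengths, family table, carrier
#'   sets, gene-to-family map, and an empty HGT event table).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    tree <- simulate_species_tree(config$n_species, config$genomes_per_species,
                                  config$between_species_divergence,
                                  config$within_species_divergence)
    groups <- attr(tree, "groups")
    tip_branch <- attr(tree, "tip_branch")
    species_branch <- attr(tree, "species_branch")
    n_fam <- config$n_core_families + config$n_accessory_families
    fam_id <- sprintf("fam%05d", seq_len(n_fam))
    fam_type <- rep(c("core", "accessory"),
                    c(config$n_core_families, config$n_accessory_families))
    fam_len <- rep_len(config$gene_length, n_fam)

    # accessory presence design
    carriers <- vector("list", n_fam)
    names(carriers) <- fam_id
    home_clade <- rep(NA_character_, n_fam)
    for (f in seq_len(n_fam)) {
      if (fam_type[f] == "core") {
        carriers[[f]] <- groups$genome_id
      } else {
        restricted <- runif(1) < config$clade_restricted_frac
        pool <- if (restricted) {
          home <- sample(unique(groups$species), 1)
          home_clade[f] <- home
          groups$genome_id[groups$species == home]
        } else groups$genome_id
        keep <- runif(length(pool)) < config$accessory_presence_prob
        carriers[[f]] <- pool[keep]
      }
    }

    # evolve sequences: root -> species ancestor -> genome tip
    sp <- unique(groups$species)
    out_genome <- vector("list", n_fam)
    out_seq <- vector("list", n_fam)
    for (f in seq_len(n_fam)) {
      carr <- carriers[[f]]
      if (length(carr) == 0) next
      root <- random_dna_int(fam_len[f])
      anc <- lapply(setNames(sp, sp), function(s)
        jc_mutate(root, species_branch[s]))
      seqs <- vapply(carr, function(g) {
        s <- groups$species[match(g, groups$genome_id)]
        dna_int_to_string(jc_mutate(anc[[s]], tip_branch[g]))
      }, character(1))
      out_genome[[f]] <- carr
      out_seq[[f]] <- unname(seqs)
    }
    n_per_fam <- lengths(out_genome)
    genes <- data.frame(
      genome_id = unlist(out_genome, use.names = FALSE),
      gene_id = paste(rep(fam_id, n_per_fam), unlist(out_genome, use.names = FALSE),
                      sep = "."),
      sequence = unlist(out_seq, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    class(genes) <- c("genome_set", "data.frame")
    gene_map <- data.frame(
      gene_id = genes$gene_id,
      genome_id = genes$genome_id,
      family_id = rep(fam_id, n_per_fam),
      stringsAsFactors = FALSE
    )
    truth <- structure(list(
      config = config,
      species_tree = tree,
      groups = groups,
      tip_branch = tip_branch,
      species_branch = species_branch,
      families = data.frame(family_id = fam_id, type = fam_type,
                            length = fam_len, home_clade = home_clade,
                            n_carriers = n_per_fam,
                            stringsAsFactors = FALSE),
      carriers = carriers,
      genes = gene_map,
      hgt_events = data.frame(family_id = character(), donor_genome = character(),
                              recipient_genome = character(),
                              donor_species = character(),
                              recipient_species = character(),
                              stringsAsFactors = FALSE)
    ), class = "sim_truth")
    list(genes = genes, truth = truth)
  })
}

#' Realized pairwise divergence between genomes
#'
#' Tip-to-tip path lengths on the simulated species tree
#' (substitutions/site), the quantity the Jukes-Cantor identity formula is
#' evaluated at in calibration checks.
#'
#' @param truth a `sim_truth`.
#' @return symmetric numeric matrix over genome ids with zero diagonal.
#' @export
pairwise_divergence <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  d <- cophenetic(truth$species_tree)
  d[order(rownames(d)), order(colnames(d))]
}

#' Plant horizontal gene transfer events
#'
#' Replaces a recipient genome's copy of a core family with a fresh
#' Jukes-Cantor re-evolution of the donor genome's copy at within-species
#' divergence, so the transferred copy resembles the donor clade. Donor and
#' recipient are drawn from different species clades; families are sampled
#' without replacement.
#'
#' @param genes a `genome_set` from [simulate_genomes()].
#' @param truth the matching `sim_truth`.
#' @param n_events number of transfers (0 returns the input unchanged).
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return list(genes, truth) with mutated sequences and the events appended
#'   to `truth$hgt_events`.
#' @export
plant_hgt <- function(genes, truth, n_events, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_events == 0) return(list(genes = genes, truth = truth))
  core_fams <- truth$families$family_id[truth$families$type == "core"]
  if (n_events > length(core_fams))
    stop("n_events exceeds the number of core families")
  if (length(unique(truth$groups$species)) < 2)
    stop("HGT requires at least two species clades")
  with_seed(seed, {
    fams <- sample(core_fams, n_events)
    events <- vector("list", n_events)
    for (e in seq_len(n_events)) {
      sp <- unique(truth$groups$species)
      donor_sp <- sample(sp, 1)
      recip_sp <- sample(setdiff(sp, donor_sp), 1)
      donor <- sample(truth$groups$genome_id[truth$groups$species == donor_sp], 1)
      recip <- sample(truth$groups$genome_id[truth$groups$species == recip_sp], 1)
      donor_gene <- paste(fams[e], donor, sep = ".")
      recip_gene <- paste(fams[e], recip, sep = ".")
      donor_seq <- genes$sequence[match(donor_gene, genes$gene_id)]
      new_seq <- dna_int_to_string(
        jc_mutate(dna_string_to_int(donor_seq),
                  truth$config$within_species_divergence))
      genes$sequence[match(recip_gene, genes$gene_id)] <- new_seq
      events[[e]] <- data.frame(family_id = fams[e], donor_genome = donor,
                                recipient_genome = recip,
                                donor_species = donor_sp,
                                recipient_species = recip_sp,
                                stringsAsFactors = FALSE)
    }
    truth$hgt_events <- rbind(truth$hgt_events, do.call(rbind, events))
    list(genes = genes, truth = truth)
  })
}

#' Simulate a pan-genome and plant transfers in one call
#'
#' Convenience wrapper: [simulate_genomes()] followed by [plant_hgt()] with
#' `config$n_hgt_events` events, both driven by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list(genes, truth).
#' @export
simulate_pangenome <- function(config) {
  sim <- simulate_genomes(config)
  plant_hgt(sim$genes, sim$truth, config$n_hgt_events,
            seed = config$seed + 1L)
}

#' Simulate a gene alignment along an arbitrary tree
#'
#' Evolves one ancestral sequence down a `phylo` tree under Jukes-Cantor
#' (branch lengths in expected substitutions/site, no indels) and returns
#' the tip sequences as an alignment matrix. Complements
#' [simulate_genomes()], whose two-level species tree has no resolvable
#' within-clade topology: this generator is the tool for experiments that
#' need gene trees estimated against a structured true tree, e.g. the
#' long-vs-short representative-gene contrast.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param length alignment length in bp.
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return character matrix (tips x sites), rownames = tip labels.
#' @export
simulate_alignment <- function(tree, length, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length), length >= 1)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    n_nodes <- ntip + tree$Nnode
    seqs <- vector("list", n_nodes)
    root <- ntip + 1L
    seqs[[root]] <- random_dna_int(length)
    # preorder: parents before children
    ord <- rev(ape::postorder(tree))
    for (e in ord) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      seqs[[child]] <- jc_mutate(seqs[[par]], tree$edge.length[e])
    }
    out <- do.call(rbind, lapply(seq_len(ntip), function(i) DNA_BASES[seqs[[i]]]))
    rownames(out) <- tree$tip.label
    out
  })
}

#' Write simulated genes as FASTA
#'
#' Headers follow the `genome|family|gene` convention when truth is given,
#' and `genome||gene` otherwise.
#'
#' @param genes a `genome_set`.
#' @param path output FASTA file (one combined multi-FASTA).
#' @param truth optional `sim_truth` supplying family ids for the headers.
#' @export
write_gene_fasta <- function(genes, path, truth = NULL) {
  fam <- if (!is.null(truth))
    truth$genes$family_id[match(genes$gene_id, truth$genes$gene_id)]
  else rep("", nrow(genes))
  seqs <- Biostrings::DNAStringSet(genes$sequence)
  names(seqs) <- paste(genes$genome_id, fam, genes$gene_id, sep = "|")
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read genome-tagged gene sequences from FASTA
#'
#' Accepts the `genome|family|gene` header convention (family may be empty).
#'
#' @param path FASTA file.
#' @return a `genome_set` data frame (`genome_id`, `gene_id`, `sequence`).
#' @export
read_gene_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) < 3))
    stop("FASTA headers must follow genome|family|gene")
  genes <- data.frame(
    genome_id = vapply(parts, `[`, "", 1),
    gene_id = vapply(parts, `[`, "", 3),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
  class(genes) <- c("genome_set", "data.frame")
  genes
}

#' Write simulation truth tables
#'
#' Emits the carrier table (family, genome), the HGT event table and the
#' species tree (Newick) under `dir`.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if missing).
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  carr <- data.frame(
    family_id = rep(names(truth$carriers), lengths(truth$carriers)),
    genome_id = unlist(truth$carriers, use.names = FALSE)
  )
  write.table(carr, file.path(dir, "carriers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$hgt_events, file.path(dir, "hgt_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(truth$species_tree, file.path(dir, "species_tree.nwk"))
  invisible(dir)
}
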