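#' Consensus sequence of an alignment
#'
#' Per column, the unique plurality base. Columns with a tie for the
#' plurality, a gap in any row, or a non-ACGT character are marked
#' ambiguous and carry `NA` in the consensus; SNP calling skips them.
#'
#' @param aln character alignment matrix (>= 2 rows).
#' @return list with `consensus` (character vector, `NA` at ambiguous
#'   columns) and `ambiguous` (integer column indices).
#' @export
build_consensus <- function(aln) {
  if (!is.matrix(aln) || nrow(aln) < 2) stop("alignment needs >= 2 rows")
  codes <- matrix(match(aln, DNA_BASES), nrow = nrow(aln))
  counts <- vapply(1:4, function(b) colSums(codes == b, na.rm = TRUE),
                   numeric(ncol(aln)))
  counts <- matrix(counts, ncol = 4)
  top <- apply(counts, 1, max)
  n_top <- rowSums(counts == top)
  has_bad <- colSums(is.na(codes)) > 0       # gap or non-ACGT anywhere
  ambiguous <- which(has_bad | n_top > 1)
  consensus <- DNA_BASES[max.col(counts, ties.method = "first")]
  consensus[ambiguous] <- NA_character_
  list(consensus = consensus, ambiguous = ambiguous)
}

#' Call consensus SNPs on one alignment
#'
#' A SNP is an unambiguous alignment column where at least one sequence
#' deviates from the consensus base; one record is emitted per deviating
#' sequence, and the polymorphic-column count is the primary SNP total
#' (per-sequence deviation counts are reported alongside).
#'
#' @param aln character alignment matrix.
#' @param consensus result of [build_consensus()] on the same alignment
#'   (recomputed when omitted).
#' @return list with `records` (data frame: `column`, `consensus_base`,
#'   `seq_id`, `base`) and `summary` (list: `n_polymorphic`,
#'   `n_deviations`, `n_columns`, `n_ambiguous`, `density` =
#'   polymorphic columns per alignment column).
#' @export
call_snps <- function(aln, consensus = NULL) {
  if (is.null(consensus)) consensus <- build_consensus(aln)
  if (length(consensus$consensus) != ncol(aln))
    stop("consensus length does not match the alignment")
  cons <- consensus$consensus
  usable <- which(!is.na(cons))
  dev <- which(aln[, usable, drop = FALSE] !=
                 matrix(cons[usable], nrow(aln), length(usable), byrow = TRUE),
               arr.ind = TRUE)
  col_idx <- usable[dev[, 2]]
  records <- data.frame(
    column = col_idx,
    consensus_base = cons[col_idx],
    seq_id = rownames(aln)[dev[, 1]],
    base = aln[cbind(dev[, 1], col_idx)],
    stringsAsFactors = FALSE
  )
  records <- records[order(records$column, records$seq_id), ]
  rownames(records) <- NULL
  list(records = records,
       summary = list(n_polymorphic = length(unique(records$column)),
                      n_deviations = nrow(records),
                      n_columns = ncol(aln),
                      n_ambiguous = length(consensus$ambiguous),
                      density = length(unique(records$column)) / ncol(aln)))
}

#' Consensus SNP calling across a set of clusters
#'
#' Aligns each requested cluster (center-star, single-copy members,
#' clusters with < 2 members skipped), builds its consensus and calls
#' SNPs; totals are summed over clusters.
#'
#' @param catalog an `ortholog_catalog`.
#' @param clusters cluster ids to process (default: all with >= 2 members);
#'   typically the core clusters of a [partition_clusters()] result.
#' @param alignments optional precomputed [cluster_alignments()].
#' @return list with `per_cluster` (data frame: `cluster_id`,
#'   `n_polymorphic`, `n_deviations`, `n_columns`, `density`), `records`
#'   (all SNP records, tagged by cluster), `total_snps` (polymorphic
#'   columns summed), `total_deviations`.
#' @export
call_snps_clusters <- function(catalog, clusters = NULL, alignments = NULL) {
  stopifnot(inherits(catalog, "ortholog_catalog"))
  if (is.null(alignments)) alignments <- cluster_alignments(catalog, clusters)
  if (!is.null(clusters))
    alignments <- alignments[intersect(names(alignments), clusters)]
  per <- list(); recs <- list()
  for (id in names(alignments)) {
    aln <- alignments[[id]]
    sn <- call_snps(aln)
    per[[id]] <- data.frame(cluster_id = id,
                            n_polymorphic = sn$summary$n_polymorphic,
                            n_deviations = sn$summary$n_deviations,
                            n_columns = sn$summary$n_columns,
                            density = sn$summary$density,
                            stringsAsFactors = FALSE)
    if (nrow(sn$records))
      recs[[id]] <- cbind(cluster_id = id, sn$records)
  }
  per_cluster <- do.call(rbind, per)
  rownames(per_cluster) <- NULL
  list(per_cluster = per_cluster,
       records = if (length(recs)) do.call(rbind, recs) else NULL,
       total_snps = sum(per_cluster$n_polymorphic),
       total_deviations = sum(per_cluster$n_deviations))
}

#' Screen ortholog clusters for horizontal gene transfer
#'
#' Simplified best-match plus tree-incongruence screen (in the spirit of,
#' but much reduced from, full HGT pipelines such as MetaCHIP; stated as
#' such in all outputs). For each single-copy gene in each screened
#' cluster, the mean percent identity to same-species copies and the best
#' identity to each foreign species are computed on the cluster alignment.
#' A copy is a candidate when its best foreign identity exceeds the
#' within-species mean by more than `min_gap` percentage points (the
#' margin suppresses the mirror signal on the donor-side copy, whose best
#' foreign match is the transferred gene itself) AND the smallest clade
#' enclosing the copy in the cluster's gene tree is dominated by that
#' foreign species. Genomes whose species has no other genome in the
#' cluster are skipped with a warning.
#'
#' @param catalog an `ortholog_catalog`.
#' @param groups named character vector or data frame (`genome_id`,
#'   `species`) mapping every genome to its species.
#' @param clusters cluster ids to screen (default: all clusters carrying
#'   >= 4 single-copy genomes from >= 2 species).
#' @param gene_trees optional named list of precomputed gene trees; trees
#'   are built on demand (Jukes-Cantor + neighbor joining) otherwise.
#' @param alignments optional precomputed [cluster_alignments()].
#' @param min_gap identity margin in percentage points (default 2).
#' @return a `hgt_screen` data frame of candidates, sorted by identity
#'   gap: `cluster_id`, `genome_id`, `species`, `foreign_species`,
#'   `within_mean`, `best_foreign`, `gap`, `incongruent`. The full
#'   best-match screen (before the tree test) is in attribute `screened`.
#' @export
detect_hgt <- function(catalog, groups, clusters = NULL, gene_trees = NULL,
                       alignments = NULL, min_gap = 2) {
  stopifnot(inherits(catalog, "ortholog_catalog"))
  if (is.data.frame(groups))
    groups <- setNames(groups$species, groups$genome_id)
  mem <- catalog$membership
  if (!all(mem$genome_id %in% names(groups)))
    stop("every genome must be assigned a species group")
  if (is.null(alignments)) alignments <- cluster_alignments(catalog, clusters)
  if (!is.null(clusters))
    alignments <- alignments[intersect(names(alignments), clusters)]
  screened <- list()
  skipped_singleton <- 0L
  for (cl_id in names(alignments)) {
    aln <- alignments[[cl_id]]
    if (nrow(aln) < 4) next
    sp <- groups[rownames(aln)]
    if (length(unique(sp)) < 2) next
    pc <- alignment_pair_counts(aln)
    idn <- 100 * pc$matches / pc$columns_no_double_gap
    gmo <- rownames(aln)
    spo <- groups[gmo]
    tree <- NULL
    for (i in seq_along(gmo)) {
      same <- which(spo == spo[i])
      same <- setdiff(same, i)
      if (length(same) == 0) { skipped_singleton <- skipped_singleton + 1L; next }
      within_mean <- mean(idn[i, same])
      foreign <- setdiff(unique(spo), spo[i])
      if (length(foreign) == 0) next
      best_by_sp <- vapply(foreign, function(s)
        max(idn[i, which(spo == s)]), 0)
      bf <- max(best_by_sp)
      bf_sp <- foreign[which.max(best_by_sp)]
      gap <- bf - within_mean
      if (gap <= min_gap) next
      # tree-incongruence test, only for copies passing the identity screen
      if (is.null(tree)) {
        tree <- if (!is.null(gene_trees) && cl_id %in% names(gene_trees))
          gene_trees[[cl_id]]
        else build_nj(suppressWarnings(jc_distance_matrix(aln)))
      }
      sib <- clade_siblings(tree, gmo[i])
      incong <- length(sib) > 0 &&
        sum(groups[sib] == bf_sp) > length(sib) / 2
      screened[[length(screened) + 1L]] <- data.frame(
        cluster_id = cl_id, genome_id = gmo[i],
        species = unname(spo[i]), foreign_species = bf_sp,
        within_mean = within_mean, best_foreign = bf, gap = gap,
        incongruent = incong, stringsAsFactors = FALSE)
    }
  }
  if (skipped_singleton > 0)
    warning(sprintf("%d gene copies skipped: species with a single genome in the cluster",
                    skipped_singleton))
  all_rows <- if (length(screened)) do.call(rbind, screened) else
    data.frame(cluster_id = character(), genome_id = character(),
               species = character(), foreign_species = character(),
               within_mean = numeric(), best_foreign = numeric(),
               gap = numeric(), incongruent = logical(),
               stringsAsFactors = FALSE)
  out <- all_rows[all_rows$incongruent, , drop = FALSE]
  out <- out[order(-out$gap), ]
  rownames(out) <- NULL
  attr(out, "screened") <- all_rows
  class(out) <- c("hgt_screen", "data.frame")
  out
}

# tips sharing the smallest enclosing clade with `tip` (its parent node's
# other descendant leaves); on the root multifurcation this degenerates to
# "all other tips", which can never be dominated by one foreign species in
# a balanced design, i.e. the test is conservative there.
clade_siblings <- function(tree, tip) {
  ti <- match(tip, tree$tip.label)
  parent <- tree$edge[tree$edge[, 2] == ti, 1]
  if (length(parent) == 0) return(character(0))
  ntip <- length(tree$tip.label)
  tips <- integer(0)
  stack <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], ti)
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd <= ntip) tips <- c(tips, nd)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == nd, 2])
  }
  tree$tip.label[tips]
}

#' Tabulate HGT candidates by species pair
#'
#' @param candidates a `hgt_screen` result.
#' @return data frame of donor species (best foreign match), recipient
#'   species and event counts.
#' @export
hgt_pair_table <- function(candidates) {
  if (nrow(candidates) == 0)
    return(data.frame(donor_species = character(),
                      recipient_species = character(), n_events = integer()))
  tab <- as.data.frame(table(donor_species = candidates$foreign_species,
                             recipient_species = candidates$species),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n_events"
  tab[tab$n_events > 0, ]
}

#' Map recovered clusters to simulated gene families
#'
#' Majority vote of member genes' true family labels.
#'
#' @param catalog an `ortholog_catalog`.
#' @param truth a `sim_truth`.
#' @return data frame (`cluster_id`, `family_id`).
#' @export
match_clusters_to_families <- function(catalog, truth) {
  mem <- catalog$membership
  fam <- truth$genes$family_id[match(mem$gene_id, truth$genes$gene_id)]
  res <- tapply(fam, mem$cluster_id, function(f)
    names(sort(table(f), decreasing = TRUE))[1])
  data.frame(cluster_id = names(res), family_id = unname(res),
             stringsAsFactors = FALSE)
}

#' Score an HGT screen against planted events
#'
#' A candidate is a true positive when its cluster maps to a planted
#' family and its genome is that event's recipient.
#'
#' @param candidates a `hgt_screen` result.
#' @param catalog the `ortholog_catalog` the screen ran on.
#' @param truth a `sim_truth` with planted events.
#' @return list: `n_candidates`, `n_true`, `n_planted`, `recall`,
#'   `precision` (NA when there are no candidates).
#' @export
score_hgt <- function(candidates, catalog, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  map <- match_clusters_to_families(catalog, truth)
  planted <- truth$hgt_events
  key_truth <- paste(planted$family_id, planted$recipient_genome)
  fam_of <- map$family_id[match(candidates$cluster_id, map$cluster_id)]
  key_cand <- paste(fam_of, candidates$genome_id)
  tp <- key_cand %in% key_truth
  list(n_candidates = nrow(candidates),
       n_true = sum(tp),
       n_planted = nrow(planted),
       recall = if (nrow(planted)) sum(unique(key_truth) %in% key_cand) /
         length(unique(key_truth)) else NA_real_,
       precision = if (nrow(candidates)) mean(tp) else NA_real_)
}
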