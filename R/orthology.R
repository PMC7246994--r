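#' Global pairwise alignment statistics
#'
#' End-to-end Needleman-Wunsch alignment of two DNA sequences with linear
#' gap penalty. Identity is matches over aligned columns (a global pairwise
#' alignment has no double-gap columns); coverage is the number of columns
#' where both sequences contribute a base, relative to the shorter sequence.
#' Symmetric in its arguments.
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch,gap alignment scores (defaults +1/-1/-2).
#' @return list with `identity` (percent), `coverage` (percent), `score`,
#'   and `alignment` (two aligned strings).
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1)
    stop("a and b must be single strings")
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  al <- nw_align_cpp(a, b, match, mismatch, gap, -1L)
  list(
    identity = 100 * al$matches / al$columns,
    coverage = 100 * al$both_aligned / min(nchar(a), nchar(b)),
    score = al$score,
    alignment = c(a = al$aligned_a, b = al$aligned_b)
  )
}

#' Cluster genes into ortholog families by single linkage
#'
#' Builds the graph joining gene pairs whose global-alignment identity and
#' coverage meet the thresholds, and reports its connected components as
#' ortholog clusters (every gene is assigned; paralogs from one genome may
#' share a cluster). With many genes, candidate pairs are pre-screened by
#' shared positional k-mers before alignment, and pairs already connected
#' through earlier edges are skipped -- both shortcuts leave the components
#' of the threshold graph unchanged on positionally homologous (indel-free)
#' gene families. Cluster ids are assigned by each cluster's smallest
#' member key, so output order is deterministic.
#'
#' @param genes a `genome_set` data frame (`genome_id`, `gene_id`,
#'   `sequence`), e.g. from [simulate_genomes()] or [read_gene_fasta()].
#' @param min_identity,min_coverage edge thresholds in percent
#'   (defaults 70 / 75).
#' @param match,mismatch,gap alignment scores passed to the aligner.
#' @param prefilter `"auto"` (k-mer screen above 64 genes), `"none"`
#'   (align all pairs) or `"kmer"`.
#' @param kmer_k,kmer_stride,kmer_min_shared prefilter tuning: k-mer size,
#'   position sampling stride, and the minimum number of shared positional
#'   k-mers for a pair to be aligned.
#' @param band alignment band half-width (`NULL` = full dynamic programming
#'   without the prefilter, band 40 with it; banded alignment is exact for
#'   the near-diagonal high-identity pairs the screen admits).
#' @return an `ortholog_catalog`: list with `membership` (data frame
#'   `cluster_id`, `genome_id`, `gene_id`, `sequence`), `n_clusters`, and
#'   `params`.
#' @export
cluster_genes <- function(genes, min_identity = 70, min_coverage = 75,
                          match = 1, mismatch = -1, gap = -2,
                          prefilter = c("auto", "none", "kmer"),
                          kmer_k = 11, kmer_stride = 4, kmer_min_shared = 2,
                          band = NULL) {
  stopifnot(is.data.frame(genes), nrow(genes) > 0)
  if (anyDuplicated(paste(genes$genome_id, genes$gene_id)))
    stop("(genome_id, gene_id) pairs must be unique")
  prefilter <- match.arg(prefilter)
  # canonical gene order so component labelling is reproducible
  ord <- order(genes$genome_id, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  n <- nrow(genes)
  if (prefilter == "auto") prefilter <- if (n > 64) "kmer" else "none"

  pairs <- if (n < 2) {
    matrix(integer(0), ncol = 2)
  } else if (prefilter == "none") {
    t(combn(n, 2))
  } else {
    kmer_candidate_pairs_cpp(genes$sequence, as.integer(kmer_k),
                             as.integer(kmer_stride),
                             as.integer(kmer_min_shared))[, 1:2, drop = FALSE]
  }

  if (is.null(band)) band <- if (prefilter == "kmer") 40L else -1L
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    root <- cluster_components_cpp(genes$sequence,
                                   matrix(as.integer(pairs), ncol = 2),
                                   min_identity, min_coverage,
                                   match, mismatch, gap, as.integer(band))
  } else {
    root <- seq_len(n)
  }
  # order clusters by smallest member key (genes already sorted)
  first <- !duplicated(root)
  cluster_rank <- match(root, root[first])
  cluster_id <- sprintf("OG%05d", cluster_rank)
  membership <- data.frame(
    cluster_id = cluster_id,
    genome_id = genes$genome_id,
    gene_id = genes$gene_id,
    sequence = genes$sequence,
    stringsAsFactors = FALSE
  )
  membership <- membership[order(membership$cluster_id, membership$genome_id,
                                 membership$gene_id), ]
  rownames(membership) <- NULL
  structure(list(
    membership = membership,
    n_clusters = length(unique(cluster_id)),
    params = list(min_identity = min_identity, min_coverage = min_coverage,
                  match = match, mismatch = mismatch, gap = gap,
                  prefilter = prefilter)
  ), class = "ortholog_catalog")
}

#' @export
print.ortholog_catalog <- function(x, ...) {
  cat(sprintf("ortholog_catalog: %d genes in %d clusters across %d genomes\n",
              nrow(x$membership), x$n_clusters,
              length(unique(x$membership$genome_id))))
  invisible(x)
}

#' Binary presence/absence matrix of clusters across genomes
#'
#' @param catalog an `ortholog_catalog`.
#' @param genomes genome ids defining the columns; defaults to the genomes
#'   observed in the catalog. Genomes in the catalog but missing from this
#'   list are an error.
#' @return integer matrix (clusters x genomes) of 0/1 flags; a cell is 1
#'   when the genome contributes at least one gene to the cluster.
#' @export
build_presence_absence <- function(catalog, genomes = NULL) {
  stopifnot(inherits(catalog, "ortholog_catalog"))
  mem <- catalog$membership
  if (is.null(genomes)) genomes <- sort(unique(mem$genome_id))
  unknown <- setdiff(mem$genome_id, genomes)
  if (length(unknown))
    stop("genomes in catalog missing from genome list: ",
         paste(unknown, collapse = ", "))
  clusters <- sort(unique(mem$cluster_id))
  m <- matrix(0L, nrow = length(clusters), ncol = length(genomes),
              dimnames = list(clusters, genomes))
  m[cbind(match(mem$cluster_id, clusters), match(mem$genome_id, genomes))] <- 1L
  m
}

#' Restrict a presence/absence matrix to a genome subset
#'
#' Keeps the given columns and drops clusters absent from every retained
#' genome (a per-species pan-genome is the occupied submatrix).
#'
#' @param pa presence/absence matrix from [build_presence_absence()].
#' @param genomes column names to keep.
#' @return the occupied submatrix.
#' @export
subset_presence <- function(pa, genomes) {
  stopifnot(all(genomes %in% colnames(pa)))
  sub <- pa[, genomes, drop = FALSE]
  sub[rowSums(sub) > 0, , drop = FALSE]
}

#' Score recovered clusters against simulator truth
#'
#' Adjusted Rand index between the catalog's cluster labels and the
#' simulator's family labels over the same genes (1 = families recovered
#' exactly).
#'
#' @param catalog an `ortholog_catalog`.
#' @param truth a `sim_truth`.
#' @return adjusted Rand index (numeric scalar).
#' @export
score_clustering <- function(catalog, truth) {
  stopifnot(inherits(catalog, "ortholog_catalog"), inherits(truth, "sim_truth"))
  mem <- catalog$membership
  fam <- truth$genes$family_id[match(mem$gene_id, truth$genes$gene_id)]
  if (anyNA(fam)) stop("catalog contains genes unknown to the truth")
  mclust::adjustedRandIndex(mem$cluster_id, fam)
}

#' Write an ortholog catalog and presence matrix as TSV
#'
#' @param catalog an `ortholog_catalog`.
#' @param pa optional presence/absence matrix.
#' @param dir output directory.
#' @export
write_catalog <- function(catalog, dir, pa = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(catalog$membership[, c("cluster_id", "genome_id", "gene_id")],
              file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(pa)) {
    df <- data.frame(cluster_id = rownames(pa), pa, check.names = FALSE)
    write.table(df, file.path(dir, "presence_absence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
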