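# Pairwise match bookkeeping on an alignment matrix (rows = sequences,
# columns = sites, characters in A/C/G/T/-). Returns, for every pair of
# rows, the number of matching columns (both bases equal and not gaps),
# the number of comparable columns (both non-gap), and the number of
# columns excluding double gaps. Computed with one-hot cross products so
# per-cluster ANI and distance work stays vectorized.
alignment_pair_counts <- function(aln) {
  stopifnot(is.matrix(aln), nrow(aln) >= 2)
  codes <- matrix(match(aln, DNA_BASES), nrow = nrow(aln))
  nongap <- (!is.na(codes)) * 1
  M <- matrix(0, nrow(aln), nrow(aln))
  for (b in 1:4) {
    ind <- (!is.na(codes) & codes == b) * 1
    M <- M + tcrossprod(ind)
  }
  C <- tcrossprod(nongap)                     # both non-gap
  G <- tcrossprod(1 - nongap)                 # both gap
  dimnames(M) <- dimnames(C) <- dimnames(G) <-
    list(rownames(aln), rownames(aln))
  list(matches = M, comparable = C, columns_no_double_gap = ncol(aln) - G)
}

#' Center-star multiple alignment of a gene cluster
#'
#' The longest member (ties broken by smallest label) is the center; every
#' other member is globally aligned to it and the pairwise alignments are
#' merged on center coordinates, inserting the maximal gap run observed
#' before each center position. Exact for the star objective on indel-free
#' families (where all pairwise alignments are gapless) and a standard
#' deterministic heuristic otherwise.
#'
#' @param seqs named character vector of DNA sequences (names become row
#'   labels), or a data frame with `gene_id` and `sequence` columns.
#' @param match,mismatch,gap alignment scores; the default gap penalty is
#'   stiffer than the clustering default (-4 vs -2) because indels are far
#'   rarer than substitutions within a homologous family -- under -2 a
#'   compensating gap pair can spuriously beat the diagonal on long
#'   substitution-only sequences, under -4 it cannot in practice.
#' @param band half-width of the alignment band (`NULL`: full dynamic
#'   programming up to 200 bp, band 40 beyond -- exact for the
#'   high-identity within-cluster comparisons this is used on).
#' @return character matrix of single characters (rows = members, gaps as
#'   `-`), with attribute `center` naming the center sequence.
#' @export
center_star_align <- function(seqs, match = 1, mismatch = -1, gap = -4,
                              band = NULL) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$gene_id)
  stopifnot(is.character(seqs), length(seqs) >= 1, !is.null(names(seqs)))
  if (length(seqs) == 1) {
    m <- matrix(strsplit(seqs, "")[[1]], nrow = 1,
                dimnames = list(names(seqs), NULL))
    attr(m, "center") <- names(seqs)
    return(m)
  }
  lens <- nchar(seqs)
  if (is.null(band)) band <- if (max(lens) > 200) 40L else -1L
  center_i <- order(-lens, names(seqs))[1]
  center <- seqs[[center_i]]
  L <- nchar(center)
  others <- seq_along(seqs)[-center_i]

  aligned <- lapply(others, function(i)
    nw_align_cpp(center, seqs[[i]], match, mismatch, gap, as.integer(band)))
  # fast path: all pairwise alignments gapless (equal-length family)
  if (all(vapply(aligned, function(a) a$columns == L && a$both_aligned == L,
                 TRUE))) {
    rows <- c(list(strsplit(center, "")[[1]]),
              lapply(aligned, function(a) strsplit(a$aligned_b, "")[[1]]))
    m <- do.call(rbind, rows)
    rownames(m) <- c(names(seqs)[center_i], names(seqs)[others])
    m <- m[match(names(seqs), rownames(m)), , drop = FALSE]
    attr(m, "center") <- names(seqs)[center_i]
    return(m)
  }

  # general merge: ins[i] = gaps needed before center position i (i in 1..L+1)
  per_member <- lapply(aligned, function(a) {
    ca <- strsplit(a$aligned_a, "")[[1]]
    cm <- strsplit(a$aligned_b, "")[[1]]
    pos <- cumsum(ca != "-")                 # center coordinate per column
    slot <- ifelse(ca == "-", pos + 1L, pos) # gap columns precede next center pos
    list(cm = cm, ca = ca, slot = slot)
  })
  ins <- integer(L + 1)
  for (pm in per_member) {
    g <- tabulate(pm$slot[pm$ca == "-"], nbins = L + 1)
    ins <- pmax(ins, g)
  }
  width <- L + sum(ins)
  # column index of center position i in the merged alignment
  center_col <- cumsum(ins[seq_len(L)] + 1L)
  out <- matrix("-", nrow = length(seqs), ncol = width,
                dimnames = list(names(seqs), NULL))
  out[center_i, center_col] <- strsplit(center, "")[[1]]
  for (k in seq_along(others)) {
    pm <- per_member[[k]]
    row <- rep("-", width)
    # characters aligned to a center base go to that base's merged column;
    # insertion characters pack left-to-right in the gap block before their slot
    base_cols <- center_col[pm$slot[pm$ca != "-"]]
    row[base_cols] <- pm$cm[pm$ca != "-"]
    if (any(pm$ca == "-")) {
      gap_slots <- pm$slot[pm$ca == "-"]
      gap_chars <- pm$cm[pm$ca == "-"]
      for (s in unique(gap_slots)) {
        chars <- gap_chars[gap_slots == s]
        block_end <- if (s <= L) center_col[s] - 1L else width
        start <- block_end - ins[s] + 1L
        row[seq(start, length.out = length(chars))] <- chars
      }
    }
    out[others[k], ] <- row
  }
  attr(out, "center") <- names(seqs)[center_i]
  out
}

#' Center-star alignments for every cluster of a catalog
#'
#' Aligns the single-copy members (one gene per genome; genomes with
#' paralogs in a cluster are left out of that cluster's alignment) of each
#' requested cluster, labelling rows by genome. Clusters with fewer than 2
#' single-copy genomes are skipped. Computing these once and passing them
#' to [ani_matrix()], [gene_trees()], [call_snps_clusters()] and
#' [detect_hgt()] avoids re-aligning the same clusters at every stage.
#'
#' @param catalog an `ortholog_catalog`.
#' @param clusters cluster ids (default: all).
#' @return named list of alignment matrices (rows = genome ids).
#' @export
cluster_alignments <- function(catalog, clusters = NULL) {
  stopifnot(inherits(catalog, "ortholog_catalog"))
  mem <- catalog$membership
  if (!is.null(clusters)) mem <- mem[mem$cluster_id %in% clusters, ]
  out <- list()
  for (cl in split(mem, mem$cluster_id)) {
    cnt <- table(cl$genome_id)
    single <- names(cnt)[cnt == 1]
    if (length(single) < 2) next
    cl <- cl[cl$genome_id %in% single, ]
    out[[cl$cluster_id[1]]] <- center_star_align(setNames(cl$sequence,
                                                          cl$genome_id))
  }
  out
}

#' Average nucleotide identity over shared single-copy ortholog clusters
#'
#' ANI(a, b) is the mean pairwise percent identity across clusters where
#' both genomes contribute exactly one gene, with identities measured on
#' the cluster's center-star alignment (columns that are gaps in both
#' members are excluded, as in [align_pair()]). Genome pairs sharing no
#' single-copy cluster are reported as `NA` with a warning.
#'
#' @param catalog an `ortholog_catalog` (>= 2 genomes).
#' @param alignments optional precomputed [cluster_alignments()].
#' @return symmetric numeric matrix of percent identities with 100 on the
#'   diagonal; attribute `n_shared` holds the per-pair cluster counts.
#' @export
ani_matrix <- function(catalog, alignments = NULL) {
  stopifnot(inherits(catalog, "ortholog_catalog"))
  mem <- catalog$membership
  genomes <- sort(unique(mem$genome_id))
  ng <- length(genomes)
  if (ng < 2) stop("ANI needs at least two genomes")
  if (is.null(alignments)) alignments <- cluster_alignments(catalog)
  sum_id <- matrix(0, ng, ng, dimnames = list(genomes, genomes))
  n_shared <- matrix(0L, ng, ng, dimnames = list(genomes, genomes))
  for (aln in alignments) {
    pc <- alignment_pair_counts(aln)
    idn <- 100 * pc$matches / pc$columns_no_double_gap
    idx <- match(rownames(aln), genomes)
    sum_id[idx, idx] <- sum_id[idx, idx] + idn
    n_shared[idx, idx] <- n_shared[idx, idx] + 1L
  }
  ani <- sum_id / n_shared
  ani[n_shared == 0] <- NA_real_
  diag(ani) <- 100
  missing <- which(n_shared == 0 & upper.tri(n_shared), arr.ind = TRUE)
  if (nrow(missing))
    warning(sprintf("%d genome pair(s) share no single-copy cluster; ANI set to NA",
                    nrow(missing)))
  attr(ani, "n_shared") <- n_shared
  ani
}

#' ANI from a list of gene alignments
#'
#' Pooled percent identity per genome pair across alignments sharing the
#' same row labels: total matching sites over total comparable sites
#' (sites-weighted, unlike [ani_matrix()]'s per-cluster mean -- the two
#' coincide on equal-length clusters). Pairs never co-occurring are `NA`.
#'
#' @param alignments list of alignment matrices with genome rownames.
#' @return symmetric percent-identity matrix, 100 on the diagonal.
#' @export
ani_from_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1)
  genomes <- sort(unique(unlist(lapply(alignments, rownames))))
  M <- D <- matrix(0, length(genomes), length(genomes),
                   dimnames = list(genomes, genomes))
  for (aln in alignments) {
    pc <- alignment_pair_counts(aln)
    idx <- match(rownames(aln), genomes)
    M[idx, idx] <- M[idx, idx] + pc$matches
    D[idx, idx] <- D[idx, idx] + pc$columns_no_double_gap
  }
  ani <- 100 * M / D
  ani[D == 0] <- NA_real_
  diag(ani) <- 100
  ani
}

#' Jukes-Cantor distance matrix from an alignment
#'
#' Pairwise-deletion distances: for each pair, columns where either row has
#' a gap or ambiguity are excluded, p is the mismatch proportion over the
#' rest, and d = -(3/4) ln(1 - 4p/3). Saturated pairs (p >= 3/4) are capped
#' at `max_distance` with a warning and flagged in the `saturated`
#' attribute.
#'
#' @param aln character alignment matrix (>= 2 rows).
#' @param max_distance cap for saturated comparisons (default 5).
#' @return symmetric numeric distance matrix (substitutions/site).
#' @export
jc_distance_matrix <- function(aln, max_distance = 5) {
  pc <- alignment_pair_counts(aln)
  if (any(pc$comparable[upper.tri(pc$comparable)] == 0))
    stop("some sequence pair has zero comparable columns")
  p <- 1 - pc$matches / pc$comparable
  diag(p) <- 0
  sat <- p >= 0.75
  d <- jc_distance(as.vector(p), max_distance = max_distance)
  d <- matrix(d, nrow(p), dimnames = dimnames(p))
  diag(d) <- 0
  if (any(sat[upper.tri(sat)]))
    warning("saturated distances (p >= 3/4) capped at max_distance")
  attr(d, "saturated") <- sat
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(d < -1e-12)) stop("distance matrix must be non-negative")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  d
}

#' Neighbor-joining tree with optional bootstrap supports
#'
#' Saitou-Nei neighbor joining (via `ape::nj`; the three-taxon case is
#' solved directly with the three-point formulas). When `bootstrap > 0`
#' and an alignment is supplied, alignment columns are resampled with
#' replacement, a tree is rebuilt from each replicate's Jukes-Cantor
#' distances, and internal nodes are labelled with the percentage of
#' replicates containing their bipartition.
#'
#' @param d symmetric non-negative distance matrix (>= 3 taxa).
#' @param bootstrap number of replicates (default 0 = no supports).
#' @param alignment alignment matrix used for resampling (required when
#'   `bootstrap > 0`; its rownames must match the taxa).
#' @param seed integer seed for resampling, or `NULL`.
#' @return an `ape::phylo` tree; bootstrap percentages in `node.label`.
#' @export
build_nj <- function(d, bootstrap = 0, alignment = NULL, seed = NULL) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  tree <- if (n == 3) {
    lab <- rownames(d)
    x <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    y <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    z <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    ape::read.tree(text = sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                                  lab[1], x, lab[2], y, lab[3], z))
  } else {
    ape::nj(as.dist(d))
  }
  if (bootstrap > 0) {
    if (is.null(alignment)) stop("bootstrap requires an alignment")
    stopifnot(setequal(rownames(alignment), rownames(d)))
    aln <- alignment[rownames(d), , drop = FALSE]
    reps <- with_seed(seed, lapply(seq_len(bootstrap), function(b) {
      cols <- sample.int(ncol(aln), replace = TRUE)
      db <- suppressWarnings(jc_distance_matrix(aln[, cols, drop = FALSE]))
      build_nj(db)
    }))
    cnt <- ape::prop.clades(tree, reps, rooted = FALSE)
    cnt[is.na(cnt)] <- 0
    tree$node.label <- round(100 * cnt / bootstrap)
  }
  tree
}

#' UPGMA (average-linkage) tree
#'
#' Agglomerative average-linkage clustering of a distance matrix, returned
#' as an ultrametric `phylo` (branch lengths are merge-height differences /
#' 2, so tip-to-tip distances reproduce cluster heights). Ties are resolved
#' deterministically by lexicographic taxon order.
#'
#' @param d symmetric non-negative distance matrix (>= 2 taxa).
#' @return a rooted ultrametric `ape::phylo`.
#' @export
build_upgma <- function(d) {
  d <- check_distance_matrix(d)
  ord <- order(rownames(d))
  hc <- hclust(as.dist(d[ord, ord]), method = "average")
  ape::as.phylo(hc)
}

#' Species clusters from an ANI matrix
#'
#' Single-linkage grouping of genomes whose ANI meets the species
#' threshold (conventionally 95%); missing ANI entries are treated as
#' below threshold.
#'
#' @param ani ANI matrix from [ani_matrix()].
#' @param threshold species-level ANI cutoff in percent (default 95).
#' @return named integer vector of cluster memberships, one per genome.
#' @export
cluster_species <- function(ani, threshold = 95) {
  stopifnot(is.matrix(ani))
  d <- 100 - ani
  d[is.na(d)] <- 100
  ord <- order(rownames(d))
  hc <- hclust(as.dist(d[ord, ord]), method = "single")
  cutree(hc, h = 100 - threshold)
}

#' Per-cluster gene trees for a set of ortholog clusters
#'
#' Builds the center-star alignment and a Jukes-Cantor neighbor-joining
#' tree for each requested cluster, labelling tips by genome. Only
#' single-copy members are used; clusters with fewer than 3 single-copy
#' genomes are skipped.
#'
#' @param catalog an `ortholog_catalog`.
#' @param clusters cluster ids to process (default: all).
#' @param bootstrap,seed passed to [build_nj()].
#' @param alignments optional precomputed [cluster_alignments()].
#' @return named list of `phylo` trees; alignments in attribute
#'   `alignments`.
#' @export
gene_trees <- function(catalog, clusters = NULL, bootstrap = 0, seed = NULL,
                       alignments = NULL) {
  stopifnot(inherits(catalog, "ortholog_catalog"))
  if (is.null(alignments)) alignments <- cluster_alignments(catalog, clusters)
  if (!is.null(clusters))
    alignments <- alignments[intersect(names(alignments), clusters)]
  trees <- list()
  for (id in names(alignments)) {
    aln <- alignments[[id]]
    if (nrow(aln) < 3) next
    d <- suppressWarnings(jc_distance_matrix(aln))
    trees[[id]] <- build_nj(d, bootstrap = bootstrap, alignment = aln,
                            seed = seed)
  }
  attr(trees, "alignments") <- alignments[names(trees)]
  trees
}
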