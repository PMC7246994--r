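#' Nontrivial splits (bipartitions) of an unrooted tree
#'
#' Each internal edge of the unrooted tree induces a bipartition of the
#' leaves; trivial splits (one side a single leaf) are dropped. Splits are
#' stored as logical membership vectors over the lexicographically sorted
#' leaf set, normalized so the first leaf is always on the `FALSE` side,
#' plus a character key for set operations.
#'
#' @param tree an `ape::phylo`.
#' @return list with `membership` (logical matrix, splits x leaves),
#'   `keys` (character vector), `labels` (sorted leaf labels).
#' @export
split_set <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labels <- sort(tree$tip.label)
  n <- length(labels)
  t2 <- if (n > 2) ape::unroot(tree) else tree
  ntip <- length(t2$tip.label)
  nnode <- t2$Nnode
  # tip sets below each edge, by postorder accumulation
  desc <- matrix(FALSE, ntip + nnode, n)
  desc[cbind(seq_len(ntip), match(t2$tip.label, labels))] <- TRUE
  for (e in ape::postorder(t2)) {
    par <- t2$edge[e, 1]; child <- t2$edge[e, 2]
    desc[par, ] <- desc[par, ] | desc[child, ]
  }
  internal_children <- t2$edge[, 2][t2$edge[, 2] > ntip]
  memb <- desc[internal_children, , drop = FALSE]
  # normalize: first sorted leaf on the FALSE side
  flip <- memb[, 1]
  memb[flip, ] <- !memb[flip, , drop = FALSE]
  sizes <- rowSums(memb)
  memb <- memb[sizes >= 2 & sizes <= n - 2, , drop = FALSE]
  memb <- unique(memb)
  keys <- if (nrow(memb)) {
    apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  } else character(0)
  list(membership = memb, keys = keys, labels = labels)
}

check_same_leaves <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share an identical leaf set")
  invisible(TRUE)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the two trees' nontrivial
#' split sets.
#'
#' @param t1,t2 trees (`phylo`) on the same leaf set.
#' @return integer distance, at most 2(n - 3).
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  k1 <- split_set(t1)$keys
  k2 <- split_set(t2)$keys
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Matching-split distance
#'
#' Minimum-cost perfect matching between the two trees' nontrivial split
#' sets, where matching split A|B to C|D costs the smaller leaf
#' disagreement `min(|A∩D| + |B∩C|, |A∩C| + |B∩D|)` and a split left
#' unmatched (the smaller set is padded with null splits) costs the size
#' of its smaller side. Solved exactly with the Hungarian algorithm.
#'
#' @param t1,t2 trees (`phylo`) on the same leaf set.
#' @return the minimum total matching cost (integer-valued).
#' @export
matching_split_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  s1 <- split_set(t1)
  s2 <- split_set(t2)
  m1 <- s1$membership
  m2 <- s2$membership[, match(s1$labels, s2$labels), drop = FALSE]
  # re-normalize t2 splits to t1's column order (first label on FALSE side)
  flip <- m2[, 1]
  if (any(flip)) m2[flip, ] <- !m2[flip, , drop = FALSE]
  k1 <- nrow(m1); k2 <- nrow(m2)
  if (k1 == 0 && k2 == 0) return(0)
  n <- length(s1$labels)
  size <- max(k1, k2)
  cost <- matrix(0, size, size)
  if (k1 > 0 && k2 > 0) {
    # hamming distance between membership vectors = |A∩D| + |B∩C|
    ham <- outer(seq_len(k1), seq_len(k2),
                 Vectorize(function(i, j) sum(xor(m1[i, ], m2[j, ]))))
    cost[seq_len(k1), seq_len(k2)] <- pmin(ham, n - ham)
  }
  if (k2 < size)  # pad t2 side with null splits
    for (i in seq_len(k1))
      cost[i, (k2 + 1):size] <- min(sum(m1[i, ]), n - sum(m1[i, ]))
  if (k1 < size)
    for (j in seq_len(k2))
      cost[(k1 + 1):size, j] <- min(sum(m2[j, ]), n - sum(m2[j, ]))
  hungarian(cost)$cost
}

# per-quartet topology codes for a tree: 0 = unresolved (star), 1/2/3 =
# which pairing (ab|cd, ac|bd, ad|bc) forms the split, computed from
# topological (unit branch length) path distances via the four-point
# condition. `quartets` is the 4 x C(n,4) output of combn over sorted
# leaf indices.
quartet_codes <- function(tree, labels, quartets) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  D <- cophenetic(t2)[labels, labels]
  n <- length(labels)
  ix <- function(i, j) (j - 1L) * n + i
  a <- quartets[1, ]; b <- quartets[2, ]; c <- quartets[3, ]; d <- quartets[4, ]
  s1 <- D[ix(a, b)] + D[ix(c, d)]
  s2 <- D[ix(a, c)] + D[ix(b, d)]
  s3 <- D[ix(a, d)] + D[ix(b, c)]
  m <- pmin(s1, s2, s3)
  ties <- (s1 <= m) + (s2 <= m) + (s3 <= m)
  code <- ifelse(s1 <= m, 1L, ifelse(s2 <= m, 2L, 3L))
  code[ties > 1] <- 0L
  code
}

#' Quartet distance
#'
#' Number of 4-leaf subsets whose induced unrooted topology (one of the
#' three resolutions, or unresolved for multifurcations) differs between
#' the two trees, by explicit enumeration over all `choose(n, 4)`
#' quartets. An unresolved quartet differs from any resolved one and
#' matches an unresolved one.
#'
#' @param t1,t2 trees (`phylo`) on the same leaf set, n >= 4.
#' @return integer distance in `[0, choose(n, 4)]`.
#' @export
quartet_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  labels <- sort(t1$tip.label)
  n <- length(labels)
  if (n < 4) stop("quartet distance needs at least 4 leaves")
  quartets <- combn(n, 4)
  sum(quartet_codes(t1, labels, quartets) !=
      quartet_codes(t2, labels, quartets))
}

#' Rank gene trees against a reference and select representatives
#'
#' Scores every gene tree against the reference by matching-split and
#' quartet distance (Robinson-Foulds is reported alongside), ranks genes
#' under each metric (average ranks for ties), sums the two ranks, and
#' selects the `ceiling(top_frac * n)` best genes by combined rank,
#' including any ties at the selection boundary. Gene trees whose leaf set
#' differs from the reference are excluded with a warning.
#'
#' @param gene_trees named list of `phylo` trees.
#' @param reference the reference tree (e.g. the pan-genome ANI tree).
#' @param top_frac fraction of genes to select (default 0.05).
#' @param metric `"both"` (rank sum, default), `"ms"` or `"quartet"`.
#' @return a `tree_distance_report` data frame, one row per eligible gene:
#'   `gene`, `rf`, `ms`, `quartet`, `rank_ms`, `rank_quartet`,
#'   `combined_rank`, `selected`, ordered by combined rank.
#' @export
select_representatives <- function(gene_trees, reference, top_frac = 0.05,
                                   metric = c("both", "ms", "quartet")) {
  metric <- match.arg(metric)
  stopifnot(length(gene_trees) >= 1, !is.null(names(gene_trees)))
  ok <- vapply(gene_trees, function(t)
    setequal(t$tip.label, reference$tip.label), TRUE)
  if (any(!ok))
    warning(sprintf("excluding %d gene tree(s) with mismatched leaf sets: %s",
                    sum(!ok), paste(names(gene_trees)[!ok], collapse = ", ")))
  gene_trees <- gene_trees[ok]
  if (length(gene_trees) == 0) stop("no gene tree shares the reference leaf set")
  labels <- sort(reference$tip.label)
  quartets <- combn(length(labels), 4)
  ref_codes <- quartet_codes(reference, labels, quartets)
  rf <- vapply(gene_trees, rf_distance, 0, t2 = reference)
  ms <- vapply(gene_trees, matching_split_distance, 0, t2 = reference)
  qd <- vapply(gene_trees, function(t)
    sum(quartet_codes(t, labels, quartets) != ref_codes), 0)
  rank_ms <- rank(ms, ties.method = "average")
  rank_q <- rank(qd, ties.method = "average")
  combined <- switch(metric,
                     both = rank_ms + rank_q,
                     ms = 2 * rank_ms,
                     quartet = 2 * rank_q)
  k <- ceiling(top_frac * length(gene_trees))
  threshold <- sort(combined)[k]
  out <- data.frame(gene = names(gene_trees), rf = rf, ms = ms, quartet = qd,
                    rank_ms = rank_ms, rank_quartet = rank_q,
                    combined_rank = combined,
                    selected = combined <= threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$combined_rank, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("tree_distance_report", "data.frame")
  out
}
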