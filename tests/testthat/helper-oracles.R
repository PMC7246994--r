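# Independent oracles used across the suite. Each deliberately avoids the
# package's own code path for the quantity it checks.

# Plain-R dynamic program for the optimal global alignment score.
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- (0:n) * gap
  S[1, ] <- (0:m) * gap
  for (i in seq_len(n))
    for (j in seq_len(m))
      S[i + 1, j + 1] <- max(S[i, j] + if (x[i] == y[j]) match else mismatch,
                             S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
  S[n + 1, m + 1]
}

# Brute-force single linkage: full pairwise threshold graph, transitive
# closure by repeated boolean matrix products.
single_linkage_oracle <- function(genes, min_identity = 70, min_coverage = 75) {
  n <- nrow(genes)
  A <- diag(TRUE, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      al <- align_pair(genes$sequence[i], genes$sequence[j])
      A[i, j] <- A[j, i] <- al$identity >= min_identity &&
        al$coverage >= min_coverage
    }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      next_id <- next_id + 1L
      comp[A[i, ]] <- next_id
    }
  }
  comp
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# Factorial brute force over all split matchings, using the metric's cost
# definition directly on leaf-name sets.
matching_split_oracle <- function(t1, t2) {
  leaf_sides <- function(tree) {
    labels <- sort(tree$tip.label)
    t2u <- if (length(labels) > 2) ape::unroot(tree) else tree
    ntip <- length(t2u$tip.label)
    internal <- unique(t2u$edge[, 2][t2u$edge[, 2] > ntip])
    sides <- lapply(internal, function(nd) {
      tips <- ape::extract.clade(t2u, nd)$tip.label
      sort(tips)
    })
    sides <- Filter(function(s)
      length(s) >= 2 && length(s) <= length(labels) - 2, sides)
    unique(lapply(sides, function(s)
      if (labels[1] %in% s) sort(setdiff(labels, s)) else s))
  }
  labels <- sort(t1$tip.label)
  n <- length(labels)
  s1 <- leaf_sides(t1); s2 <- leaf_sides(t2)
  k <- max(length(s1), length(s2))
  if (k == 0) return(0)
  cost <- matrix(0, k, k)
  for (i in seq_len(k))
    for (j in seq_len(k)) {
      if (i <= length(s1) && j <= length(s2)) {
        A <- s1[[i]]; B <- setdiff(labels, A)
        C <- s2[[j]]; D <- setdiff(labels, C)
        cost[i, j] <- min(length(intersect(A, D)) + length(intersect(B, C)),
                          length(intersect(A, C)) + length(intersect(B, D)))
      } else if (i <= length(s1)) {
        A <- s1[[i]]
        cost[i, j] <- min(length(A), n - length(A))
      } else if (j <= length(s2)) {
        C <- s2[[j]]
        cost[i, j] <- min(length(C), n - length(C))
      }
    }
  perms <- all_permutations(k)
  min(apply(perms, 1, function(p) sum(cost[cbind(seq_len(k), p)])))
}

# Quartet distance by pruning each 4-subset and comparing the induced
# trees with an external topology test.
quartet_oracle <- function(t1, t2) {
  labels <- sort(t1$tip.label)
  subsets <- combn(labels, 4)
  differs <- apply(subsets, 2, function(q) {
    p1 <- ape::unroot(ape::keep.tip(t1, q))
    p2 <- ape::unroot(ape::keep.tip(t2, q))
    phangorn::RF.dist(p1, p2) > 0
  })
  sum(differs)
}

# Hypergeometric upper tail by exhaustive enumeration of all draws.
hyper_tail_oracle <- function(k, K, N, n) {
  members <- c(rep(TRUE, K), rep(FALSE, N - K))
  draws <- combn(N, n)
  mean(colSums(matrix(members[draws], nrow = n)) >= k)
}

# Independent Monte-Carlo model of one alignment column under the
# simulator's substitution process: root -> per-species ancestor -> tips,
# each branch a Jukes-Cantor transition. Returns the probability that the
# column is counted as a SNP (unique-plurality consensus, >= 1 deviation).
column_snp_prob_oracle <- function(truth, n_cols = 2e5, seed = 1) {
  stay <- function(b) 0.25 + 0.75 * exp(-4 * b / 3)
  groups <- truth$groups
  set.seed(seed)
  root <- rep(1L, n_cols)
  tips <- matrix(0L, nrow(groups), n_cols)
  anc <- list()
  for (s in unique(groups$species)) {
    q <- stay(truth$species_branch[s])
    mut <- runif(n_cols) >= q
    a <- root
    a[mut] <- ((root[mut] - 1L + sample.int(3L, sum(mut), TRUE)) %% 4L) + 1L
    anc[[s]] <- a
  }
  for (i in seq_len(nrow(groups))) {
    g <- groups$genome_id[i]
    q <- stay(truth$tip_branch[g])
    a <- anc[[groups$species[i]]]
    mut <- runif(n_cols) >= q
    a2 <- a
    a2[mut] <- ((a[mut] - 1L + sample.int(3L, sum(mut), TRUE)) %% 4L) + 1L
    tips[i, ] <- a2
  }
  cnt <- vapply(1:4, function(b) colSums(tips == b), numeric(n_cols))
  top <- pmax(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4])
  n_top <- (cnt[, 1] == top) + (cnt[, 2] == top) + (cnt[, 3] == top) +
    (cnt[, 4] == top)
  mean(top < nrow(groups) & n_top == 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna_string <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
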