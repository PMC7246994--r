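#' Read a gene/cluster category table
#'
#' TSV with columns `cluster_id`, `category` and optionally `level`
#' (hierarchy tag, e.g. a Brite level or "pathway"). A cluster may carry
#' several categories; unannotated clusters simply do not appear.
#'
#' @param path TSV file.
#' @return data frame with `cluster_id`, `category`, `level`.
#' @export
read_category_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cluster_id", "category") %in% names(df)))
    stop("category table needs cluster_id and category columns")
  if (is.null(df$level)) df$level <- "default"
  if (any(!nzchar(df$category))) stop("category labels must be non-empty")
  df[, c("cluster_id", "category", "level")]
}

#' Fold extension of category counts from core to pan
#'
#' For each category (within each hierarchy level), counts the annotated
#' clusters in the whole pan-genome, in the softcore tier (softcore +
#' core) and in the core, then reports the pan/softcore and pan/core
#' ratios -- the "n-fold extension" of a functional category when moving
#' from the conserved genome to the full gene repertoire. Display columns
#' round to 1 decimal; full precision is kept in the `*_full` columns. A
#' totals row per level sums the counts. Subset counts of zero yield `NA`
#' extensions.
#'
#' @param categories category table (see [read_category_table()]).
#' @param partition a [partition_clusters()] result covering the clusters.
#' @return data frame: `level`, `category`, `pan`, `softcore`, `core`,
#'   `softcore_to_pan`, `core_to_pan` (1-decimal display),
#'   `softcore_to_pan_full`, `core_to_pan_full`.
#' @export
tabulate_fold_extension <- function(categories, partition) {
  stopifnot(inherits(partition, "pangenome_partition"))
  if (is.null(categories$level)) categories$level <- "default"
  if (!all(categories$cluster_id %in% partition$cluster_id))
    stop("categories reference clusters missing from the partition")
  lab <- partition$label[match(categories$cluster_id, partition$cluster_id)]
  categories$in_core <- lab == "core"
  categories$in_softcore <- lab %in% c("core", "softcore")
  rows <- list()
  for (lv in unique(categories$level)) {
    sub <- categories[categories$level == lv, ]
    for (cat in unique(sub$category)) {
      cc <- sub[sub$category == cat, ]
      cc <- cc[!duplicated(cc$cluster_id), ]      # one count per cluster
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, category = cat, pan = nrow(cc),
        softcore = sum(cc$in_softcore), core = sum(cc$in_core),
        stringsAsFactors = FALSE)
    }
    lvl_rows <- do.call(rbind, rows[vapply(rows, function(r) r$level == lv, TRUE)])
    rows[[length(rows) + 1L]] <- data.frame(
      level = lv, category = "Total", pan = sum(lvl_rows$pan),
      softcore = sum(lvl_rows$softcore), core = sum(lvl_rows$core),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$softcore_to_pan_full <- ifelse(out$softcore > 0, out$pan / out$softcore, NA)
  out$core_to_pan_full <- ifelse(out$core > 0, out$pan / out$core, NA)
  out$softcore_to_pan <- round(out$softcore_to_pan_full, 1)
  out$core_to_pan <- round(out$core_to_pan_full, 1)
  rownames(out) <- NULL
  out[, c("level", "category", "pan", "softcore", "core",
          "softcore_to_pan", "core_to_pan",
          "softcore_to_pan_full", "core_to_pan_full")]
}

#' Species-specific accessory gene sets
#'
#' For each species, the non-core clusters present in at least one of its
#' genomes and absent from every genome of all other species.
#'
#' @param pa presence/absence matrix.
#' @param partition the matching [partition_clusters()] result.
#' @param groups named character vector or data frame mapping every genome
#'   (column of `pa`) to its species.
#' @return named list of cluster-id character vectors, one per species.
#' @export
species_specific_accessory <- function(pa, partition, groups) {
  stopifnot(inherits(partition, "pangenome_partition"))
  if (is.data.frame(groups))
    groups <- setNames(groups$species, groups$genome_id)
  if (!all(colnames(pa) %in% names(groups)))
    stop("groups must cover all genomes")
  sp <- groups[colnames(pa)]
  non_core <- partition$cluster_id[partition$label != "core"]
  out <- list()
  for (s in unique(sp)) {
    own <- pa[, sp == s, drop = FALSE]
    other <- pa[, sp != s, drop = FALSE]
    hit <- rownames(pa)[rowSums(own) > 0 &
                          (ncol(other) == 0 | rowSums(other) == 0)]
    out[[s]] <- intersect(hit, non_core)
  }
  out
}

#' Category enrichment of a gene set (hypergeometric + BH)
#'
#' Upper-tail hypergeometric test per category: the probability of drawing
#' at least the observed number of category members when sampling
#' `|gene_set|` clusters from the background without replacement. The rich
#' factor is the fraction of a category's background clusters found in the
#' set. q-values are Benjamini-Hochberg over all tested categories. The
#' test statistic and the all-annotated-background convention are stated
#' assumptions of this implementation.
#'
#' @param gene_set cluster ids of the test set (must be a subset of
#'   `background`).
#' @param background cluster ids of the background universe.
#' @param categories category table (rows referencing other clusters are
#'   ignored).
#' @return data frame sorted by q then p: `category`, `set_count`,
#'   `set_size`, `background_count`, `background_size`, `rich_factor`,
#'   `p`, `q`.
#' @export
enrich <- function(gene_set, background, categories) {
  gene_set <- unique(gene_set)
  background <- unique(background)
  if (length(gene_set) == 0 || length(background) == 0)
    stop("gene set and background must be non-empty")
  if (!all(gene_set %in% background))
    stop("gene_set must be a subset of background")
  categories <- categories[categories$cluster_id %in% background, ]
  categories <- categories[!duplicated(paste(categories$category,
                                             categories$cluster_id)), ]
  if (nrow(categories) == 0)
    return(data.frame(category = character(), set_count = integer(),
                      set_size = integer(), background_count = integer(),
                      background_size = integer(), rich_factor = numeric(),
                      p = numeric(), q = numeric()))
  N <- length(background)
  n <- length(gene_set)
  cats <- unique(categories$category)
  K <- vapply(cats, function(cat)
    sum(categories$category == cat), 0L)
  k <- vapply(cats, function(cat)
    sum(categories$cluster_id[categories$category == cat] %in% gene_set), 0L)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(category = cats, set_count = k, set_size = n,
                    background_count = K, background_size = N,
                    rich_factor = k / K, p = p,
                    q = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$category), ]
  rownames(out) <- NULL
  out
}
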