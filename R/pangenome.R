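#' Partition clusters into core, softcore, shell and cloud
#'
#' Standard occupancy tiers: core = present in every genome; softcore =
#' present in at least `ceiling(softcore_frac * n)` genomes (the "95-100%"
#' tier) without being core; cloud = present in at most `cloud_max`
#' genomes; shell = the remainder ("more than two but less than 95%").
#' Label precedence is core > softcore > cloud > shell, which only matters
#' for degenerate tiny genome sets. Note that for n <= 20 genomes
#' `ceiling(0.95 n) = n`, so the softcore tier collapses onto the core and
#' core + shell + cloud = pan.
#'
#' @param pa presence/absence matrix from [build_presence_absence()].
#' @param softcore_frac softcore occupancy fraction, in (0, 1] (default 0.95).
#' @param cloud_max maximum occupancy of a cloud cluster (default 2).
#' @return a `pangenome_partition` data frame (`cluster_id`, `presence`,
#'   `label`) with attributes `n_genomes`, `softcore_frac`, `cloud_max`.
#' @export
partition_clusters <- function(pa, softcore_frac = 0.95, cloud_max = 2) {
  stopifnot(is.matrix(pa), nrow(pa) > 0)
  if (softcore_frac <= 0 || softcore_frac > 1)
    stop("softcore_frac must be in (0, 1]")
  n <- ncol(pa)
  presence <- rowSums(pa > 0)
  soft_min <- ceiling(softcore_frac * n)
  label <- ifelse(presence == n, "core",
           ifelse(presence >= soft_min, "softcore",
           ifelse(presence <= cloud_max, "cloud", "shell")))
  out <- data.frame(cluster_id = rownames(pa), presence = as.integer(presence),
                    label = label, stringsAsFactors = FALSE)
  attr(out, "n_genomes") <- n
  attr(out, "softcore_frac") <- softcore_frac
  attr(out, "cloud_max") <- cloud_max
  class(out) <- c("pangenome_partition", "data.frame")
  out
}

#' Pan- and core-genome accumulation curves
#'
#' Adds genomes one at a time in `n_perm` random orders; after each
#' addition, pan(N) is the number of clusters present in at least one of
#' the first N genomes and core(N) the number present in all of them.
#' new(N) = pan(N) - pan(N-1) is the gene discovery increment (new(1) =
#' pan(1)).
#'
#' @param pa presence/absence matrix.
#' @param n_perm number of random genome orderings (default 10).
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return an `accumulation_curves` data frame (`perm`, `N`, `pan`, `core`,
#'   `new`) with attribute `medians` (per-N medians across permutations).
#' @export
accumulation_curves <- function(pa, n_perm = 10, seed = NULL) {
  stopifnot(is.matrix(pa), n_perm >= 1)
  n <- ncol(pa)
  with_seed(seed, {
    res <- vector("list", n_perm)
    for (p in seq_len(n_perm)) {
      ord <- sample.int(n)
      P <- pa[, ord, drop = FALSE] > 0
      first_present <- max.col(P, ties.method = "first")
      pan <- cumsum(tabulate(first_present, nbins = n))
      Z <- !P
      has_zero <- rowSums(Z) > 0
      first_absent <- rep(n + 1L, nrow(P))
      if (any(has_zero))
        first_absent[has_zero] <- max.col(Z[has_zero, , drop = FALSE],
                                          ties.method = "first")
      core <- nrow(P) - cumsum(tabulate(first_absent, nbins = n))
      res[[p]] <- data.frame(perm = p, N = seq_len(n), pan = pan, core = core,
                             new = diff(c(0L, pan)))
    }
    out <- do.call(rbind, res)
    med <- data.frame(
      N = seq_len(n),
      pan = vapply(seq_len(n), function(k) median(out$pan[out$N == k]), 0),
      core = vapply(seq_len(n), function(k) median(out$core[out$N == k]), 0),
      new = vapply(seq_len(n), function(k) median(out$new[out$N == k]), 0)
    )
    attr(out, "medians") <- med
    attr(out, "n_genomes") <- n
    class(out) <- c("accumulation_curves", "data.frame")
    out
  })
}

#' Fit Heaps' law to the gene-discovery curve
#'
#' Regresses the log median number of new genes per added genome on log N
#' for N = 2..n (least squares). Under the Heaps'-law decay reading
#' n_new = k * N^-alpha, the fitted slope is -alpha and exp(intercept) is
#' k; alpha < 1 marks an open pan-genome. Zero medians are replaced by a
#' 0.5 pseudocount before logging so all points stay usable.
#'
#' @param curves an [accumulation_curves()] result (>= 3 genomes).
#' @return a `heaps_fit` list: `k`, `alpha`, `open_flag`, `n_points`,
#'   `r_squared`.
#' @export
fit_heaps <- function(curves) {
  stopifnot(inherits(curves, "accumulation_curves"))
  n <- attr(curves, "n_genomes")
  if (n < 3) stop("Heaps' fit needs at least 3 genomes")
  med <- attr(curves, "medians")
  pts <- med[med$N >= 2, ]
  y <- ifelse(pts$new <= 0, 0.5, pts$new)
  if (nrow(pts) < 2) stop("fewer than 2 usable points for the fit")
  fit <- lm(log(y) ~ log(pts$N))
  alpha <- -unname(coef(fit)[2])
  k <- exp(unname(coef(fit)[1]))
  ly <- log(y)
  r2 <- if (all(abs(ly - mean(ly)) < 1e-300)) 1 else
    1 - sum(residuals(fit)^2) / sum((ly - mean(ly))^2)
  structure(list(k = k, alpha = alpha, open_flag = alpha < 1,
                 n_points = nrow(pts), r_squared = r2),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("Heaps' law fit: k = %.2f, alpha = %.4f (%s pan-genome)\n",
              x$k, x$alpha, if (x$open_flag) "open" else "closed"))
  invisible(x)
}

#' Pan-genome summary report
#'
#' One row of partition bookkeeping in the shape of a per-dataset summary
#' table: genome count, mean gene count per genome (+- SD), mean genome
#' size in Mb computed from summed gene lengths when sequences are
#' available, and the cluster counts N_core, N_softcore (threshold tier,
#' includes core), N_shell, N_cloud, N_pan. By construction
#' N_softcore + N_shell + N_cloud = N_pan.
#'
#' @param pa presence/absence matrix.
#' @param partition the [partition_clusters()] result for the same matrix.
#' @param genes optional `genome_set` for gene-count and size statistics.
#' @return a one-row `data.frame`.
#' @export
pangenome_report <- function(pa, partition, genes = NULL) {
  stopifnot(inherits(partition, "pangenome_partition"))
  if (!identical(sort(partition$cluster_id), sort(rownames(pa))))
    stop("partition does not match the presence/absence matrix")
  tab <- table(factor(partition$label,
                      levels = c("core", "softcore", "shell", "cloud")))
  n_core <- unname(tab["core"])
  out <- data.frame(
    N_genome = ncol(pa),
    mean_genes = NA_real_, sd_genes = NA_real_,
    mean_size_mb = NA_real_, sd_size_mb = NA_real_,
    N_core = n_core,
    N_softcore = n_core + unname(tab["softcore"]),
    N_shell = unname(tab["shell"]),
    N_cloud = unname(tab["cloud"]),
    N_pan = nrow(pa)
  )
  if (!is.null(genes)) {
    keep <- genes$genome_id %in% colnames(pa)
    cnt <- table(factor(genes$genome_id[keep], levels = colnames(pa)))
    out$mean_genes <- mean(cnt)
    out$sd_genes <- sd(cnt)
    sz <- tapply(nchar(genes$sequence[keep]),
                 factor(genes$genome_id[keep], levels = colnames(pa)), sum)
    out$mean_size_mb <- mean(sz) / 1e6
    out$sd_size_mb <- sd(sz) / 1e6
  }
  out
}

#' Reconstruct a presence matrix with prescribed partition counts
#'
#' Builds the simplest presence/absence matrix over `n_genomes` whose
#' partition has exactly the given core / shell / cloud counts (shell
#' clusters get occupancy `cloud_max + 1`, cloud clusters occupancy 1).
#' Useful for checking the partition-accounting identity against published
#' per-species tables, which print core, shell, cloud and pan counts.
#'
#' @param n_genomes number of genomes (> cloud_max + 1).
#' @param n_core,n_shell,n_cloud cluster counts per tier.
#' @param cloud_max cloud occupancy threshold (default 2).
#' @return integer presence/absence matrix.
#' @export
presence_from_counts <- function(n_genomes, n_core, n_shell, n_cloud,
                                 cloud_max = 2) {
  stopifnot(n_genomes > cloud_max + 1)
  occ <- rep(c(n_genomes, cloud_max + 1L, 1L), c(n_core, n_shell, n_cloud))
  m <- matrix(0L, nrow = length(occ), ncol = n_genomes,
              dimnames = list(sprintf("OG%05d", seq_along(occ)),
                              sprintf("g%02d", seq_len(n_genomes))))
  for (r in seq_along(occ)) m[r, seq_len(occ[r])] <- 1L
  m
}
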