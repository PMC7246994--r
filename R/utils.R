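#' Expected Jukes-Cantor per-site identity
#'
#' Closed-form probability that two homologous sites match after evolving
#' apart by `d` expected substitutions/site under Jukes-Cantor:
#' \eqn{1/4 + (3/4) e^{-4d/3}}.
#'
#' @param d numeric vector of divergences (substitutions/site, >= 0).
#' @return numeric vector of expected identities in (0.25, 1].
#' @export
jc_expected_identity <- function(d) {
  stopifnot(is.numeric(d), all(d >= 0))
  0.25 + 0.75 * exp(-4 * d / 3)
}

#' Jukes-Cantor distance from an observed mismatch proportion
#'
#' @param p observed proportion of mismatching sites.
#' @param max_distance value substituted for saturated comparisons
#'   (p >= 3/4, where the JC transform diverges).
#' @return numeric vector of distances; saturated entries carry the cap and
#'   an attribute is not set here (callers flag saturation).
#' @export
jc_distance <- function(p, max_distance = 5) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  d <- ifelse(p >= 0.75, max_distance, -0.75 * log(pmax(1 - 4 * p / 3, 1e-300)))
  pmin(d, max_distance)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# sequences handled internally as integer vectors in 1:4
dna_int_to_string <- function(x) paste(DNA_BASES[x], collapse = "")

dna_string_to_int <- function(s) {
  m <- match(strsplit(toupper(s), "")[[1]], DNA_BASES)
  if (anyNA(m)) stop("non-ACGT character in sequence")
  m
}

# Evolve an integer-coded sequence for `d` expected substitutions/site under
# Jukes-Cantor: each site changes with probability (3/4)(1 - e^{-4d/3}),
# uniformly to one of the three other bases.
jc_mutate <- function(x, d) {
  if (d <= 0) return(x)
  p_change <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(runif(length(x)) < p_change)
  if (length(hit)) {
    # sample uniformly among the 3 other bases
    shift <- sample.int(3L, length(hit), replace = TRUE)
    x[hit] <- ((x[hit] - 1L + shift) %% 4L) + 1L
  }
  x
}

random_dna_int <- function(length) sample.int(4L, length, replace = TRUE)

# Hungarian algorithm (Kuhn-Munkres with potentials), O(n^3), for square
# cost matrices. Returns list(cost, assignment) where assignment[i] is the
# column matched to row i. Hand-rolled because no assignment-problem solver
# is available among the package's dependencies; exact for the small split
# matchings used here (matrix side <= number of tree splits).
hungarian <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  n <- nrow(cost)
  if (n == 0) return(list(cost = 0, assignment = integer(0)))
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  total <- 0
  for (j in seq_len(n)) {
    if (p[j + 1] > 0) {
      assignment[p[j + 1]] <- j
      total <- total + cost[p[j + 1], j]
    }
  }
  list(cost = total, assignment = assignment)
}
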