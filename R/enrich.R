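#' Build a signed inverse-adjusted-p rank statistic
#'
#' Each gene's ranking statistic is the direction of its fold change
#' multiplied by the reciprocal of its adjusted p-value:
#' `sign(log2FC) * (1 / adjP)`. Strongly significant up-regulated genes
#' get large positive values, strongly significant down-regulated genes
#' large negative values; a gene with adjP = 1 sits at +/-1 and a gene
#' with log2FC = 0 at exactly 0. Adjusted p-values of 0 are floored at
#' 1e-300 to keep the statistic finite.
#'
#' @param de_table data.frame with columns `gene_id`, `log2FC`, `adjP`
#' @return a `RankedGeneList` data.frame (`gene_id`, `stat`) sorted by
#'   descending statistic, ties broken by gene id.
#' @export
build_rank_statistic <- function(de_table) {
  req <- c("gene_id", "log2FC", "adjP")
  if (!all(req %in% names(de_table)))
    stop("`de_table` needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(de_table$gene_id))
    stop("duplicate gene ids in DE table")
  adjP <- de_table$adjP
  if (any(adjP < 0 | adjP > 1, na.rm = TRUE) || anyNA(adjP))
    stop("adjP values must lie in [0, 1]")
  adjP <- pmax(adjP, 1e-300)
  stat <- sign(de_table$log2FC) * (1 / adjP)
  ord <- order(-stat, de_table$gene_id, method = "radix")
  out <- data.frame(
    gene_id = de_table$gene_id[ord],
    stat = stat[ord],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("RankedGeneList", "data.frame")
  out
}

#' Classic (unweighted) running-sum enrichment score
#'
#' Walking the ranked list top to bottom, the running sum increases by
#' `1 / n_hits` at each gene in the set and decreases by
#' `1 / (N - n_hits)` at each gene outside it. The enrichment score is
#' the running-sum value of maximal absolute deviation from zero
#' (signed), the unweighted Kolmogorov-Smirnov-style statistic. Set
#' members absent from the ranked list are dropped before scoring.
#'
#' @param ranked a `RankedGeneList` (or character vector of ordered ids)
#' @param set character vector of member gene ids
#' @return list with `es`, `running` (the running-sum profile),
#'   `hit_positions`, `n_hits`.
#' @export
enrichment_score_classic <- function(ranked, set) {
  ids <- if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
  if (anyDuplicated(ids)) stop("ranked list contains duplicate gene ids")
  n <- length(ids)
  hit <- ids %in% unique(set)
  n_hits <- sum(hit)
  if (n_hits == 0L) stop("gene set has no member in the ranked list")
  if (n_hits == n) stop("gene set covers the entire ranked list")
  # exact integer arithmetic on the common denominator n_hits*(n-n_hits)
  # so ties in |running sum| break identically everywhere (first index)
  n_miss <- n - n_hits
  scaled <- cumsum(ifelse(hit, as.numeric(n_miss), -as.numeric(n_hits)))
  running <- scaled / (n_hits * n_miss)
  es <- running[which.max(abs(scaled))]
  list(es = es, running = running,
       hit_positions = which(hit), n_hits = n_hits)
}

#' Gene-set permutation p-value for the classic enrichment score
#'
#' Draws `n_perm` random gene sets of the same size from the ranked list
#' and compares their |ES| with the observed one:
#' `p = (1 + #{|ES_perm| >= |ES_obs|}) / (1 + n_perm)`. Gene-set (not
#' phenotype) permutation: it needs only the ranked list, not the
#' sample-level expression, and is the appropriate desk-scale null.
#'
#' @param ranked a `RankedGeneList` or ordered id vector
#' @param set member gene ids
#' @param n_perm number of permutations (>= 1)
#' @param seed integer seed for reproducibility
#' @return list with `p`, `es_obs`, `n_perm`.
#' @export
permutation_pvalue <- function(ranked, set, n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  ids <- if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
  obs <- enrichment_score_classic(ids, set)
  k <- obs$n_hits
  n <- length(ids)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  exceed <- 0L
  incr_hit <- 1 / k
  incr_miss <- -1 / (n - k)
  for (i in seq_len(n_perm)) {
    pos <- sample.int(n, k)
    incr <- rep(incr_miss, n)
    incr[pos] <- incr_hit
    run <- cumsum(incr)
    if (max(abs(run)) >= abs(obs$es) - 1e-12) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (1 + n_perm), es_obs = obs$es, n_perm = n_perm)
}

# set the RNG to `seed`, return a restorer for the caller's RNG state
.Random.seed_guard <- function(seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }
}

#' Hypergeometric over-representation score
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between a hit list and a gene set inside a finite universe,
#' reported alongside `-log10(p)` as the enrichment score.
#'
#' @param hit_list character vector of hit gene ids (subset of universe)
#' @param gene_set character vector of set member ids (subset of universe)
#' @param universe character vector of all testable gene ids
#' @return list with `p`, `score` (`-log10(p)`), `overlap`, `n_hits`,
#'   `n_set`, `n_universe`.
#' @export
ora_hypergeometric <- function(hit_list, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hit_list <- unique(hit_list)
  gene_set <- unique(gene_set)
  if (!all(hit_list %in% universe)) stop("hit list not contained in universe")
  if (!all(gene_set %in% universe)) stop("gene set not contained in universe")
  k <- length(intersect(hit_list, gene_set))
  p <- stats::phyper(k - 1, length(gene_set),
                     length(universe) - length(gene_set),
                     length(hit_list), lower.tail = FALSE)
  list(p = p, score = -log10(p), overlap = k,
       n_hits = length(hit_list), n_set = length(gene_set),
       n_universe = length(universe))
}
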