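#' Score bulk samples against a gene signature
#'
#' The signature score of a sample is the mean, over signature genes
#' present in the matrix, of that gene's median-centered stabilized
#' expression: per gene, the cohort median (across samples) is subtracted
#' before averaging. Median centering puts genes of different baseline
#' abundance on a common additive scale, so the score measures coordinate
#' up- or down-regulation of the set relative to the cohort.
#'
#' @param normalized a `NormalizedMatrix` from [vst_log()], or a plain
#'   gene x sample numeric matrix already on a log-like scale
#' @param signature character vector of gene ids; members missing from the
#'   matrix are dropped with a warning, never imputed
#' @return a `SignatureScoreTable` data.frame: `unit_id`, `score`,
#'   `stratum` (NA until [stratify_median()]), `group` (NA). Attribute
#'   `genes_used` / `genes_missing` record the signature coverage.
#' @export
score_bulk <- function(normalized, signature) {
  values <- if (inherits(normalized, "NormalizedMatrix")) normalized$values
            else as.matrix(normalized)
  signature <- unique(signature)
  present <- intersect(signature, rownames(values))
  missing <- setdiff(signature, rownames(values))
  if (length(present) == 0L)
    stop("no signature gene present in the expression matrix")
  if (length(missing))
    warning(length(missing), " signature gene(s) absent from matrix, dropped: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  sub <- values[present, , drop = FALSE]
  centered <- sub - apply(sub, 1, stats::median)
  tab <- data.frame(
    unit_id = colnames(values),
    score = colMeans(centered),
    stratum = NA_character_,
    group = NA_character_,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(tab, "genes_used") <- present
  attr(tab, "genes_missing") <- missing
  class(tab) <- c("SignatureScoreTable", "data.frame")
  tab
}

#' Score single cells against a gene signature
#'
#' Per-cell mean expression of the signature genes. Unlike the bulk score,
#' no median centering is applied by default — the per-cell score is a
#' plain "average expression of the signature genes"; set `center = TRUE`
#' to median-center each gene across cells first.
#'
#' @param expr cell x gene numeric expression matrix (cells in rows)
#' @param signature character vector of gene ids
#' @param groups optional per-cell group labels (e.g. treatment-naive /
#'   residual / progressive disease)
#' @param center median-center genes across cells before averaging
#' @return a `SignatureScoreTable` with one row per cell.
#' @export
score_cells <- function(expr, signature, groups = NULL, center = FALSE) {
  expr <- as.matrix(expr)
  if (!is.null(groups) && length(groups) != nrow(expr))
    stop("one group label per cell required")
  signature <- unique(signature)
  present <- intersect(signature, colnames(expr))
  missing <- setdiff(signature, colnames(expr))
  if (length(present) == 0L)
    stop("no signature gene present in the expression matrix")
  if (length(missing))
    warning(length(missing), " signature gene(s) absent from matrix, dropped")
  sub <- expr[, present, drop = FALSE]
  if (center) sub <- sweep(sub, 2, apply(sub, 2, stats::median))
  tab <- data.frame(
    unit_id = if (!is.null(rownames(expr))) rownames(expr)
              else sprintf("cell%d", seq_len(nrow(expr))),
    score = rowMeans(sub),
    stratum = NA_character_,
    group = if (is.null(groups)) NA_character_ else as.character(groups),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(tab, "genes_used") <- present
  attr(tab, "genes_missing") <- missing
  class(tab) <- c("SignatureScoreTable", "data.frame")
  tab
}

#' Split a score table at the cohort median
#'
#' Units scoring strictly above the cohort median are labelled `"high"`,
#' all others `"low"`. The tie rule (score exactly at the median goes
#' low) is deterministic and conservative for a "high stratum fares
#' worse" hypothesis.
#'
#' @param table a `SignatureScoreTable`
#' @return the table with `stratum` filled in.
#' @export
stratify_median <- function(table) {
  if (!inherits(table, "SignatureScoreTable"))
    stop("expected a SignatureScoreTable")
  if (nrow(table) < 2L) stop("need at least 2 units to stratify")
  med <- stats::median(table$score)
  table$stratum <- ifelse(table$score > med, "high", "low")
  table
}

#' Welch two-sample comparison of signature scores
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom on
#' the scores of two groups. When both groups are exactly constant and
#' equal, returns t = 0, p = 1 (degenerate fast path).
#'
#' @param table a `SignatureScoreTable` with `group` labels
#' @param group_a,group_b the two group labels to compare
#' @return list with `mean_diff` (A minus B), `t`, `df`, `p` (two-sided).
#' @export
differential_mean_test <- function(table, group_a, group_b) {
  a <- table$score[table$group == group_a & !is.na(table$group)]
  b <- table$score[table$group == group_b & !is.na(table$group)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 units")
  va <- stats::var(a); vb <- stats::var(b)
  diff <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (diff == 0)
      return(list(mean_diff = 0, t = 0, df = NA_real_, p = 1))
    return(list(mean_diff = diff, t = sign(diff) * Inf, df = NA_real_, p = 0))
  }
  se2 <- va / length(a) + vb / length(b)
  t_stat <- diff / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(mean_diff = diff, t = t_stat, df = df, p = p)
}
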