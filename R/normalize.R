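#' Median-of-ratios size factors
#'
#' The standard count-normalization estimator: each sample's factor is the
#' median, over genes expressed in every sample, of that sample's count
#' divided by the gene's geometric mean across samples. Factors are then
#' rescaled so their geometric mean is 1 (canonical scaling), which fixes
#' the arbitrary overall scale.
#'
#' @param counts gene x sample numeric matrix of non-negative counts
#' @return named numeric vector of positive per-sample size factors with
#'   geometric mean 1.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  expressed <- rowSums(counts > 0) == ncol(counts)
  if (!any(expressed))
    stop("no gene has nonzero counts in all samples; size factors unestimable")
  sub <- counts[expressed, , drop = FALSE]
  log_geo <- rowMeans(log(sub))
  factors <- apply(sub, 2, function(col) exp(stats::median(log(col) - log_geo)))
  factors <- factors / exp(mean(log(factors)))
  stats::setNames(factors, colnames(counts))
}

#' Log variance-stabilizing transform
#'
#' A log-based stand-in for the parametric variance-stabilizing transform:
#' `log2(count / size_factor + 1)`. Downstream signature scoring
#' median-centers each gene, which absorbs gene-wise offsets, so the
#' choice of stabilizer mainly affects tail behavior, not the score
#' ordering.
#'
#' @param counts gene x sample matrix of non-negative counts
#' @param size_factors per-sample positive factors; defaults to
#'   [size_factors_median_of_ratios()] of `counts`
#' @return a `NormalizedMatrix`: list with `values` (gene x sample real
#'   matrix), `size_factors`, and `transform = "vst_log"`.
#' @export
vst_log <- function(counts, size_factors = size_factors_median_of_ratios(counts)) {
  counts <- as.matrix(counts)
  if (any(size_factors <= 0)) stop("size factors must be positive")
  if (length(size_factors) != ncol(counts))
    stop("one size factor per sample required")
  values <- log2(sweep(counts, 2, size_factors, "/") + 1)
  structure(
    list(values = values, size_factors = size_factors, transform = "vst_log"),
    class = "NormalizedMatrix"
  )
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix (%s): %d genes x %d samples\n",
              x$transform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (length_kb * total_mapped / 1e6)`, where `total_mapped`
#' is the per-sample total of reads mapped to annotated genes.
#'
#' @param counts gene x sample matrix
#' @param gene_lengths_bp per-gene transcript lengths in base pairs (> 0)
#' @param totals per-sample mapped-read totals (> 0); defaults to column
#'   sums of `counts`
#' @return gene x sample matrix of RPKM values.
#' @export
rpkm <- function(counts, gene_lengths_bp, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(gene_lengths_bp) != nrow(counts))
    stop("one length per gene required")
  if (any(gene_lengths_bp <= 0)) stop("gene lengths must be positive")
  if (any(totals <= 0)) stop("per-sample totals must be positive")
  counts / (outer(gene_lengths_bp / 1e3, totals / 1e6))
}
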