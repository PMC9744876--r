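#' Dual-species count container
#'
#' Bundles a gene-by-sample integer count matrix from a combined
#' human+mouse annotation with per-gene species labels and per-sample
#' class labels. This is the object the cross-mapping filter consumes:
#' xenograft libraries contain reads of both species, while species-pure
#' control libraries (tumor cells grown in vitro, sham-injected mouse
#' brain) anchor the contamination model.
#'
#' @param counts gene x sample matrix of non-negative counts, with row and
#'   column names. A base matrix or any Matrix-package sparse matrix.
#' @param gene_info data.frame with columns `gene_id`, `species`
#'   (`"human"` or `"mouse"`) and `length_bp` (positive integer; used by
#'   RPKM). Rows must cover every row of `counts`.
#' @param sample_info data.frame with columns `sample_id` and `class`
#'   (one of `"xenograft"`, `"human_only"`, `"mouse_only"`).
#'
#' @return An object of class `DualSpeciesCounts`: a list with elements
#'   `counts`, `gene_info` (aligned to rows), `sample_info` (aligned to
#'   columns).
#' @export
DualSpeciesCounts <- function(counts, gene_info, sample_info) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry gene row names and sample column names")
  if (any(counts < 0)) stop("`counts` must be non-negative")
  req_g <- c("gene_id", "species", "length_bp")
  if (!all(req_g %in% names(gene_info)))
    stop("`gene_info` needs columns: ", paste(req_g, collapse = ", "))
  if (!all(c("sample_id", "class") %in% names(sample_info)))
    stop("`sample_info` needs columns: sample_id, class")
  if (!all(rownames(counts) %in% gene_info$gene_id))
    stop("every count row must appear in `gene_info$gene_id`")
  if (!all(colnames(counts) %in% sample_info$sample_id))
    stop("every count column must appear in `sample_info$sample_id`")
  gene_info <- gene_info[match(rownames(counts), gene_info$gene_id), ,
                         drop = FALSE]
  sample_info <- sample_info[match(colnames(counts), sample_info$sample_id), ,
                             drop = FALSE]
  rownames(gene_info) <- NULL
  rownames(sample_info) <- NULL
  bad_sp <- setdiff(unique(gene_info$species), c("human", "mouse"))
  if (length(bad_sp))
    stop("unknown species label(s): ", paste(bad_sp, collapse = ", "))
  bad_cl <- setdiff(unique(sample_info$class),
                    c("xenograft", "human_only", "mouse_only"))
  if (length(bad_cl))
    stop("unknown sample class(es): ", paste(bad_cl, collapse = ", "))
  if (any(gene_info$length_bp <= 0)) stop("gene lengths must be positive")
  structure(
    list(counts = counts, gene_info = gene_info, sample_info = sample_info),
    class = "DualSpeciesCounts"
  )
}

#' @export
print.DualSpeciesCounts <- function(x, ...) {
  cat(sprintf(
    "DualSpeciesCounts: %d genes (%d human, %d mouse) x %d samples\n",
    nrow(x$counts),
    sum(x$gene_info$species == "human"),
    sum(x$gene_info$species == "mouse"),
    ncol(x$counts)
  ))
  cl <- table(x$sample_info$class)
  cat("  samples:", paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.DualSpeciesCounts <- function(x) dim(x$counts)

# sample ids of a given class
samples_of_class <- function(data, class) {
  data$sample_info$sample_id[data$sample_info$class == class]
}

# per-sample total reads mapped to genes annotated to `species`
species_totals <- function(data, species, samples = colnames(data$counts)) {
  idx <- data$gene_info$species == species
  colSums(data$counts[idx, samples, drop = FALSE])
}
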