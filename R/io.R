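#' Read a count matrix from TSV or MatrixMarket files
#'
#' TSV layout: header row of sample ids, first column of gene ids.
#' MatrixMarket layout: an `.mtx` file with sidecar one-column text files
#' of gene ids (rows) and sample ids (columns).
#'
#' @param path path to the `.tsv` or `.mtx` file
#' @param genes_path,samples_path sidecar index files (MTX only)
#' @return gene x sample numeric matrix with dimnames.
#' @export
read_counts <- function(path, genes_path = NULL, samples_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(genes_path) || is.null(samples_path))
      stop("MTX input needs `genes_path` and `samples_path` sidecars")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(samples_path)
    m
  } else {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
    as.matrix(df)
  }
}

#' Write a count matrix as TSV (default) or MatrixMarket
#'
#' @param mat gene x sample matrix with dimnames
#' @param path output path; a `.mtx` suffix selects MatrixMarket with
#'   `<path>.genes.txt` / `<path>.samples.txt` sidecars
#' @return the path, invisibly.
#' @export
write_counts <- function(mat, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(mat), paste0(path, ".genes.txt"))
    writeLines(colnames(mat), paste0(path, ".samples.txt"))
  } else {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Assemble a DualSpeciesCounts object from files
#'
#' @param counts_path count matrix (TSV or MTX)
#' @param genes_path gene annotation TSV (`gene_id, species, length_bp`),
#'   or the MTX row-index sidecar when `samples_path` names the column
#'   sidecar and `annotation_path` the annotation
#' @param samples_path sample sheet TSV (`sample_id, class`)
#' @param annotation_path gene annotation TSV when the matrix is MTX
#' @return a [DualSpeciesCounts()].
#' @export
read_dual_species <- function(counts_path, genes_path, samples_path,
                              annotation_path = NULL) {
  if (grepl("\\.mtx$", counts_path)) {
    mat <- read_counts(counts_path, genes_path,
                       samples_path = paste0(counts_path, ".samples.txt"))
    gene_info <- utils::read.delim(annotation_path)
  } else {
    mat <- read_counts(counts_path)
    gene_info <- utils::read.delim(genes_path)
  }
  sample_info <- utils::read.delim(samples_path)
  DualSpeciesCounts(mat, gene_info, sample_info)
}

#' Read a plain-text signature gene list (one id per line)
#'
#' @param path file path; blank lines and `#` comments are skipped
#' @return character vector of gene ids.
#' @export
read_signature <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member ids.
#'
#' @param path GMT file path
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 3L) stop("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1L)
  sets
}

#' Read burden trajectories from a long-format TSV
#'
#' Columns: `animal_id, compartment, day, burden`; one series per
#' (animal, compartment).
#'
#' @param path TSV path
#' @param treatment_start day treatment began (shared across animals)
#' @param detection_threshold optional burden threshold for incidence
#' @return list of [BurdenSeries()].
#' @export
read_burden_tsv <- function(path, treatment_start,
                            detection_threshold = NA_real_) {
  df <- utils::read.delim(path)
  req <- c("animal_id", "compartment", "day", "burden")
  if (!all(req %in% names(df)))
    stop("burden table needs columns: ", paste(req, collapse = ", "))
  keys <- unique(df[, c("animal_id", "compartment")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$animal_id == keys$animal_id[i] &
              df$compartment == keys$compartment[i], ]
    sub <- sub[order(sub$day), ]
    BurdenSeries(keys$animal_id[i], sub$day, sub$burden,
                 treatment_start, keys$compartment[i],
                 detection_threshold)
  })
}

#' Write burden trajectories as a long-format TSV
#' @param series list of [BurdenSeries()]
#' @param path output TSV path
#' @return the path, invisibly.
#' @export
write_burden_tsv <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(animal_id = s$animal_id, compartment = s$compartment,
               day = s$time, burden = s$burden,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
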