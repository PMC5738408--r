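#' Write a numeric matrix as TSV with a leading id column
#'
#' @param x matrix with dimnames.
#' @param path output file.
#' @param id_name name of the leading identifier column.
#' @export
write_matrix_tsv <- function(x, path, id_name = "gene_id") {
  df <- data.frame(rownames(x), signif(as.matrix(x), 10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_name, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a gene x sample matrix from TSV
#'
#' Expects a header row of sample ids and a leading gene id column.
#'
#' @param path TSV file.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path GMT file.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene-id vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n) {
    paste(c(n, n, sets[[n]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a BED file of genomic regions
#'
#' 0-based half-open intervals; only the first four columns are used.
#'
#' @param path BED file.
#' @return data.frame: chrom, start, end, name.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  else df$name <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  df[, c("chrom", "start", "end", "name")]
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path text file.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  trimws(x[nzchar(trimws(x))])
}

#' Write a simulated cohort to a directory
#'
#' Counts, metadata, ground truth and gene coordinates as TSV.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  tdf <- data.frame(gene_id = names(truth$lfc), lfc = truth$lfc,
                    de_gene = truth$de_gene, eqtl_gene = truth$eqtl_gene,
                    icc_donor = truth$icc_donor, row.names = NULL)
  utils::write.table(tdf, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(truth$mixing_cell_types,
                   file.path(dir, "truth_mixing.tsv"), id_name = "sample_id")
  utils::write.table(cohort$gene_coords, file.path(dir, "gene_coords.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a gene x sample count matrix from MatrixMarket triplet files
#'
#' @param mtx_path MatrixMarket file.
#' @param rownames_path text file of gene ids, one per line.
#' @param colnames_path text file of sample ids, one per line.
#' @return dense integer matrix with dimnames.
#' @export
read_counts_mtx <- function(mtx_path, rownames_path, colnames_path) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required to read MatrixMarket files")
  }
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- read_gene_list(rownames_path)
  colnames(m) <- read_gene_list(colnames_path)
  m
}

#' Write a count matrix as MatrixMarket triplets plus name files
#'
#' @param x matrix with dimnames.
#' @param dir output directory; writes counts.mtx, genes.txt, samples.txt.
#' @export
write_counts_mtx <- function(x, dir) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required to write MatrixMarket files")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(x), file.path(dir, "genes.txt"))
  writeLines(colnames(x), file.path(dir, "samples.txt"))
  invisible(dir)
}
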