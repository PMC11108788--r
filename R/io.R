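#' Write a count matrix as MatrixMarket MTX with barcodes/features TSV
#'
#' @param sce a SingleCellExperiment with a `counts` assay
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_mtx_dir <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  utils::write.table(as.data.frame(SummarizedExperiment::rowData(sce)),
                     file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::colData(sce)),
                     file.path(dir, "cell_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_mtx_dir()]
#'
#' @param dir directory holding matrix.mtx, barcodes.tsv, features.tsv and
#'   cell_metadata.tsv
#' @return a SingleCellExperiment
#' @export
read_mtx_dir <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- utils::read.delim(file.path(dir, "features.tsv"),
                                stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cell_metadata.tsv"),
                             stringsAsFactors = FALSE)
  dimnames(m) <- list(features$gene, barcodes)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(cells, row.names = barcodes),
    rowData = S4Vectors::DataFrame(features, row.names = features$gene))
}

#' Write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' @param gene_sets named list of character vectors
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  sets
}

#' Write a data.frame as a diffable TSV
#'
#' Stable column order and fixed 9-significant-digit float formatting so
#' repeated runs produce byte-identical files.
#' @param df data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tsv_stable <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 9, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
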