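#' Quality-control parameter set
#'
#' Defaults per modality follow the atlas thresholds: cells keep 500-5,000
#' detected genes, 700-50,000 counts and at most 10% mitochondrial reads;
#' nuclei keep 400-5,000 genes, 500-40,000 counts and at most 5%
#' mitochondrial reads. Doublets are dropped above a Scrublet score of 0.4
#' in both modalities. Gene/count bounds are inclusive; the mitochondrial
#' and doublet rules are strict ("more than").
#'
#' The nuclei upper count bound is configurable; 40,000 is the default.
#'
#' @param modality "cell" or "nucleus"
#' @param min_genes,max_genes inclusive bounds on detected genes
#' @param min_counts,max_counts inclusive bounds on total counts
#' @param max_mito_fraction strict upper bound on mitochondrial fraction
#' @param max_doublet_score strict upper bound on doublet score
#' @return object of class `qc_params`
#' @export
qc_params <- function(modality = c("cell", "nucleus"),
                      min_genes = NULL, max_genes = NULL,
                      min_counts = NULL, max_counts = NULL,
                      max_mito_fraction = NULL,
                      max_doublet_score = 0.4) {
  modality <- match.arg(modality)
  def <- if (modality == "cell") {
    list(min_genes = 500L, max_genes = 5000L,
         min_counts = 700L, max_counts = 50000L, max_mito_fraction = 0.10)
  } else {
    list(min_genes = 400L, max_genes = 5000L,
         min_counts = 500L, max_counts = 40000L, max_mito_fraction = 0.05)
  }
  p <- list(modality = modality,
            min_genes = if (is.null(min_genes)) def$min_genes else min_genes,
            max_genes = if (is.null(max_genes)) def$max_genes else max_genes,
            min_counts = if (is.null(min_counts)) def$min_counts else min_counts,
            max_counts = if (is.null(max_counts)) def$max_counts else max_counts,
            max_mito_fraction = if (is.null(max_mito_fraction)) def$max_mito_fraction else max_mito_fraction,
            max_doublet_score = max_doublet_score)
  if (p$min_genes > p$max_genes || p$min_counts > p$max_counts) {
    stop("min must not exceed max for gene and count ranges")
  }
  structure(p, class = "qc_params")
}

#' Per-cell quality-control metrics
#'
#' @param sce SingleCellExperiment with a `counts` assay
#' @param mito_genes character vector of mitochondrial gene names; genes
#'   absent from the matrix trigger a warning
#' @return data.frame with barcode, n_genes (genes with count > 0),
#'   n_counts, mito_fraction (0/0 defined as 0), and doublet_score if
#'   present in `colData`
#' @export
compute_qc_metrics <- function(sce, mito_genes = grep("^MT-", rownames(sce), value = TRUE)) {
  if (ncol(sce) == 0 || nrow(sce) == 0) stop("empty count matrix")
  m <- SummarizedExperiment::assay(sce, "counts")
  missing <- setdiff(mito_genes, rownames(m))
  if (length(missing)) {
    warning("mito genes not in matrix: ", paste(missing, collapse = ", "))
    mito_genes <- setdiff(mito_genes, missing)
  }
  n_counts <- Matrix::colSums(m)
  n_genes <- Matrix::colSums(m > 0)
  mito <- if (length(mito_genes)) {
    Matrix::colSums(m[mito_genes, , drop = FALSE])
  } else rep(0, ncol(m))
  mito_fraction <- ifelse(n_counts > 0, mito / n_counts, 0)
  out <- data.frame(barcode = colnames(m),
                    n_genes = as.integer(n_genes),
                    n_counts = as.numeric(n_counts),
                    mito_fraction = mito_fraction,
                    stringsAsFactors = FALSE)
  cd <- SummarizedExperiment::colData(sce)
  if ("doublet_score" %in% names(cd)) out$doublet_score <- cd$doublet_score
  rownames(out) <- out$barcode
  out
}

#' Filter cells by the quality-control rules
#'
#' Rules are applied sequentially for attribution: doublet score, then gene
#' range, then count range, then mitochondrial fraction; a cell failing
#' several rules is attributed to the first. Gene/count bounds are
#' inclusive; doublet and mitochondrial thresholds are strict.
#'
#' @param sce SingleCellExperiment
#' @param metrics table from [compute_qc_metrics()], aligned to `sce` cells
#' @param params a [qc_params()] object; its modality must match the cells'
#'   modality when the `colData` carries one
#' @return list with `sce` (filtered) and `report` (class `qc_report`:
#'   n_input, n_kept, per-rule removals, kept barcodes)
#' @export
filter_cells <- function(sce, metrics, params) {
  stopifnot(inherits(params, "qc_params"))
  if (!identical(metrics$barcode, colnames(sce))) {
    stop("metrics are not aligned to the matrix cells")
  }
  cd <- SummarizedExperiment::colData(sce)
  if ("modality" %in% names(cd)) {
    mods <- unique(cd$modality)
    if (length(mods) == 1 && mods != params$modality) {
      stop("params modality '", params$modality,
           "' does not match matrix modality '", mods, "'")
    }
  }
  ds <- if ("doublet_score" %in% names(metrics)) metrics$doublet_score else rep(0, nrow(metrics))
  fail_doublet <- ds > params$max_doublet_score
  fail_genes <- metrics$n_genes < params$min_genes | metrics$n_genes > params$max_genes
  fail_counts <- metrics$n_counts < params$min_counts | metrics$n_counts > params$max_counts
  fail_mito <- metrics$mito_fraction > params$max_mito_fraction

  first_fail <- rep(NA_character_, nrow(metrics))
  first_fail[fail_mito] <- "mito"
  first_fail[fail_counts] <- "counts"
  first_fail[fail_genes] <- "genes"
  first_fail[fail_doublet] <- "doublet"
  keep <- is.na(first_fail)

  report <- structure(list(
    n_input = ncol(sce),
    n_kept = sum(keep),
    removed = c(doublet = sum(first_fail == "doublet", na.rm = TRUE),
                genes = sum(first_fail == "genes", na.rm = TRUE),
                counts = sum(first_fail == "counts", na.rm = TRUE),
                mito = sum(first_fail == "mito", na.rm = TRUE)),
    kept_barcodes = colnames(sce)[keep],
    params = unclass(params)), class = "qc_report")
  list(sce = sce[, keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_input, "cells in,", x$n_kept, "kept\n")
  for (r in names(x$removed)) cat("  removed by", r, ":", x$removed[[r]], "\n")
  invisible(x)
}
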