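#' Per-cluster expression proportions
#'
#' Fraction of a cluster's cells with a nonzero raw count for each gene —
#' the quantity the ligand-receptor relevance filter thresholds.
#'
#' @param sce SingleCellExperiment with a `counts` assay
#' @param clusters per-cell cluster labels (default: `colData` `cluster`)
#' @return clusters x genes numeric matrix of proportions
#' @export
expression_proportion <- function(sce, clusters = NULL) {
  if (is.null(clusters)) {
    clusters <- SummarizedExperiment::colData(sce)$cluster
  }
  stopifnot(length(clusters) == ncol(sce))
  if (anyNA(clusters)) stop("every cell must be labeled")
  m <- SummarizedExperiment::assay(sce, "counts")
  cl <- factor(clusters)
  if (any(table(cl) == 0)) stop("empty cluster")
  nz <- m > 0
  out <- t(sapply(levels(cl), function(l) {
    idx <- which(cl == l)
    Matrix::rowSums(nz[, idx, drop = FALSE]) / length(idx)
  }))
  rownames(out) <- levels(cl)
  out
}

#' Ligand-receptor relevance filter
#'
#' An interaction between an emitter and a receiver cluster is retained
#' only when the ligand is expressed in more than `threshold` (default 5%)
#' of the emitter's cells AND every receptor subunit is expressed in more
#' than `threshold` of the receiver's cells (min-over-subunits rule;
#' strict inequality). Genes missing from the proportion table count as
#' proportion 0.
#'
#' @param pairs data.frame with interaction_id, ligand, receptor_subunits
#'   (semicolon-separated for multi-subunit receptors)
#' @param proportions clusters x genes matrix from [expression_proportion()]
#' @param emitters,receivers cluster labels to evaluate (default all)
#' @param threshold expression-proportion cutoff (default 0.05)
#' @return data.frame: emitter, receiver, interaction_id, ligand,
#'   receptor_subunits, ligand_prop, receptor_prop (min over subunits),
#'   retained
#' @export
filter_interactions <- function(pairs, proportions,
                                emitters = rownames(proportions),
                                receivers = rownames(proportions),
                                threshold = 0.05) {
  pairs <- validate_lr_pairs(pairs)
  prop_of <- function(cluster, gene) {
    ifelse(gene %in% colnames(proportions), proportions[cluster, gene], 0)
  }
  grid <- expand.grid(emitter = emitters, receiver = receivers,
                      pair = seq_len(nrow(pairs)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lig <- pairs$ligand[grid$pair]
  rec <- strsplit(pairs$receptor_subunits[grid$pair], ";", fixed = TRUE)
  lig_prop <- mapply(prop_of, grid$emitter, lig)
  rec_prop <- mapply(function(cl, subunits) {
    min(vapply(subunits, function(g) prop_of(cl, g), 0))
  }, grid$receiver, rec)
  data.frame(emitter = grid$emitter, receiver = grid$receiver,
             interaction_id = pairs$interaction_id[grid$pair],
             ligand = lig,
             receptor_subunits = pairs$receptor_subunits[grid$pair],
             ligand_prop = unname(lig_prop),
             receptor_prop = unname(rec_prop),
             retained = unname(lig_prop > threshold & rec_prop > threshold),
             stringsAsFactors = FALSE)
}
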