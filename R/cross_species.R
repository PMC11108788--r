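#' Map a gene set through a homolog table
#'
#' Genes without a homolog row are dropped (and reported); one-to-many
#' rows expand to every homolog, then the result is deduplicated.
#'
#' @param genes character gene set
#' @param homologs data.frame with columns human_gene, mouse_gene
#' @param direction "human_to_mouse" or "mouse_to_human"
#' @return list with `mapped` (character set) and `dropped` (unmapped input
#'   genes)
#' @export
map_homologs <- function(genes, homologs,
                         direction = c("human_to_mouse", "mouse_to_human")) {
  direction <- match.arg(direction)
  stopifnot(all(c("human_gene", "mouse_gene") %in% names(homologs)))
  if (any(!nzchar(homologs$human_gene)) || any(!nzchar(homologs$mouse_gene))) {
    stop("homolog table has empty fields")
  }
  from <- if (direction == "human_to_mouse") homologs$human_gene else homologs$mouse_gene
  to <- if (direction == "human_to_mouse") homologs$mouse_gene else homologs$human_gene
  hit <- from %in% genes
  mapped <- unique(to[hit])
  dropped <- setdiff(genes, from)
  list(mapped = mapped, dropped = dropped)
}

#' Jaccard index of two gene sets
#'
#' |A intersect B| / |A union B|. Two empty sets give 0 with the
#' `both_empty` attribute set, keeping summary tables total.
#'
#' @param a,b character sets
#' @return numeric in [0, 1]
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    return(structure(0, both_empty = TRUE))
  }
  length(intersect(a, b)) / u
}

#' Over-representation analysis (one-sided hypergeometric)
#'
#' For each pathway, the upper-tail hypergeometric probability of an
#' overlap at least as large as observed between the hit list and the
#' pathway within the universe; Benjamini-Hochberg adjustment across the
#' supplied pathways.
#'
#' @param hits character gene list (e.g. aging DEGs of one cell type and
#'   direction); genes outside the universe are dropped with a warning
#' @param pathways named list of pathway gene sets (clipped to the universe)
#' @param universe character background set (e.g. genes expressed in the
#'   cell type)
#' @return data.frame: pathway, overlap, set_size, n_hits, universe_size,
#'   p_value, p_adjusted
#' @export
ora_hypergeometric <- function(hits, pathways, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!is.list(pathways)) pathways <- list(pathway = pathways)
  out_hits <- setdiff(hits, universe)
  if (length(out_hits)) {
    warning(length(out_hits), " hit gene(s) outside the universe dropped")
  }
  hits <- intersect(unique(hits), universe)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(pathways[[nm]]), universe)
    ov <- length(intersect(hits, pw))
    p <- stats::phyper(ov - 1, length(pw), length(universe) - length(pw),
                       length(hits), lower.tail = FALSE)
    data.frame(pathway = nm, overlap = ov, set_size = length(pw),
               n_hits = length(hits), universe_size = length(universe),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Cross-species pathway co-enrichment score
#'
#' For each (pathway, direction), the number of cell types in which the
#' pathway is significantly enriched (adjusted p < alpha) in BOTH species
#' with the same direction. By the plotting convention, up-regulated
#' counts are signed positive and down-regulated counts negative.
#'
#' @param human,mouse data.frames of enrichment records with columns
#'   pathway, cell_type, direction, p_adjusted
#' @param alpha significance cutoff on adjusted p (default 0.05)
#' @return data.frame: pathway, direction, n_celltypes, signed_count
#' @export
coenrichment_score <- function(human, mouse, alpha = 0.05) {
  req <- c("pathway", "cell_type", "direction", "p_adjusted")
  stopifnot(all(req %in% names(human)), all(req %in% names(mouse)))
  sig <- function(df) {
    df <- df[!is.na(df$p_adjusted) & df$p_adjusted < alpha, req]
    unique(paste(df$pathway, df$direction, df$cell_type, sep = "\r"))
  }
  both <- intersect(sig(human), sig(mouse))
  keys <- unique(rbind(human[, c("pathway", "direction")],
                       mouse[, c("pathway", "direction")]))
  parts <- strsplit(both, "\r", fixed = TRUE)
  pd <- vapply(parts, function(p) paste(p[1], p[2], sep = "\r"), "")
  counts <- table(pd)
  key_id <- paste(keys$pathway, keys$direction, sep = "\r")
  n <- as.integer(ifelse(key_id %in% names(counts), counts[key_id], 0))
  data.frame(pathway = keys$pathway, direction = keys$direction,
             n_celltypes = n,
             signed_count = ifelse(keys$direction == "down", -n, n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cell-type Jaccard consistency of aging DEG sets between species
#'
#' DEG sets are compared per (cell type, direction) after mapping the
#' human sets onto mouse homologs (direction configurable).
#'
#' @param human_degs,mouse_degs data.frames with columns cell_type,
#'   direction, gene
#' @param homologs homolog table (see [map_homologs()])
#' @param direction mapping direction applied to the human sets
#' @return data.frame: cell_type, direction, jaccard, n_human, n_mouse
#' @export
cross_species_jaccard <- function(human_degs, mouse_degs, homologs,
                                  direction = "human_to_mouse") {
  keys <- unique(rbind(human_degs[, c("cell_type", "direction")],
                       mouse_degs[, c("cell_type", "direction")]))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    ct <- keys$cell_type[i]; dr <- keys$direction[i]
    h <- human_degs$gene[human_degs$cell_type == ct & human_degs$direction == dr]
    m <- mouse_degs$gene[mouse_degs$cell_type == ct & mouse_degs$direction == dr]
    hm <- map_homologs(h, homologs, direction)$mapped
    data.frame(cell_type = ct, direction = dr,
               jaccard = as.numeric(jaccard(hm, m)),
               n_human = length(hm), n_mouse = length(unique(m)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
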