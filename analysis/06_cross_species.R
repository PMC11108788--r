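#!/usr/bin/env Rscript
# Stage 6 — cross-species consistency of aging signatures.
#
# Human aging DEG sets are mapped onto mouse homologs and compared with a
# synthetic mouse DEG set of known overlap (70% of mapped human calls
# retained plus noise genes). Consistency is scored three ways: the
# per-direction Jaccard index, hypergeometric over-representation of each
# pathway within each species (BH-adjusted), and the co-enrichment count
# of cell types where a pathway is enriched in BOTH species in the same
# direction.

suppressMessages(library(myoaging))
degs <- read.delim("results/aging_degs.tsv")
homologs <- read.delim("results/homologs.tsv")
gene_sets <- read_gmt("results/gene_sets.gmt")

sig <- degs[degs$significant, ]
human <- data.frame(cell_type = "all",
                    direction = ifelse(sig$logfc_age >= 0, "up", "down"),
                    gene = sig$gene)
mouse <- withr::with_seed(derive_seed(1, "cross_species"), {
  per_dir <- lapply(c("up", "down"), function(dr) {
    h <- human$gene[human$direction == dr]
    h <- h[runif(length(h)) < 0.7]
    mg <- map_homologs(h, homologs)$mapped
    if (!length(mg)) return(NULL)
    data.frame(cell_type = "all", direction = dr, gene = mg)
  })
  noise <- paste0("m", sample(degs$gene, 5))
  rbind(do.call(rbind, per_dir),
        data.frame(cell_type = "all", direction = "up", gene = noise))
})

jac <- cross_species_jaccard(human, mouse, homologs)
write_tsv_stable(jac, "results/cross_species_jaccard.tsv")
print(jac, digits = 3, row.names = FALSE)

universe_h <- degs$gene[degs$prop_expressed > 0.05]
universe_m <- map_homologs(universe_h, homologs)$mapped
pathways_m <- lapply(gene_sets, function(g) map_homologs(g, homologs)$mapped)
enr <- function(sets, pws, uni) {
  do.call(rbind, lapply(c("up", "down"), function(dr) {
    r <- ora_hypergeometric(intersect(sets$gene[sets$direction == dr], uni),
                            pws, uni)
    r$cell_type <- "all"; r$direction <- dr
    r
  }))
}
enr_h <- enr(human, gene_sets, universe_h)
enr_m <- enr(mouse, pathways_m, universe_m)
write_tsv_stable(enr_h, "results/enrichment_human.tsv")
write_tsv_stable(enr_m, "results/enrichment_mouse.tsv")
co <- coenrichment_score(enr_h, enr_m)
write_tsv_stable(co, "results/coenrichment.tsv")
message("pathways co-enriched in >= 1 cell type: ",
        sum(co$n_celltypes > 0), " of ", nrow(co), " (pathway, direction)")
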