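#!/usr/bin/env Rscript
# Stage 2 — quality control.
#
# Applies the atlas QC rules per modality: Scrublet score > 0.4 removes
# doublets, then gene- and count-range filters, then the mitochondrial
# rule (> 10% for cells, > 5% for nuclei). The synthetic libraries are
# far shallower than real tissue libraries, so the depth bounds are
# opened while the strict doublet and mitochondrial rules stay at their
# published values.

suppressMessages(library(myoaging))
sce <- read_mtx_dir("results/counts")
metrics <- compute_qc_metrics(sce)

kept <- character()
for (mod in unique(sce$modality)) {
  idx <- sce$modality == mod
  p <- qc_params(mod, min_genes = 1, max_genes = 1e9,
                 min_counts = 1, max_counts = 1e9)
  res <- filter_cells(sce[, idx], metrics[idx, , drop = FALSE], p)
  message(mod, ": ", res$report$n_input, " -> ", res$report$n_kept,
          " (doublet ", res$report$removed["doublet"],
          ", mito ", res$report$removed["mito"], ")")
  kept <- c(kept, res$report$kept_barcodes)
}

metrics$kept <- metrics$barcode %in% kept
write_tsv_stable(metrics, "results/qc_metrics.tsv")
write_mtx_dir(sce[, metrics$kept], "results/counts_qc")
message("kept ", sum(metrics$kept), " of ", ncol(sce),
        " cells -> results/counts_qc/")
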