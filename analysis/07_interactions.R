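#!/usr/bin/env Rscript
# Stage 7 — ligand-receptor relevance filtering.
#
# For every (emitter cluster, receiver cluster, interaction) triple, the
# interaction is kept only if the ligand is expressed (raw count > 0) in
# more than 5% of the emitter's cells and every receptor subunit in more
# than 5% of the receiver's cells.

suppressMessages(library(myoaging))
sce <- read_mtx_dir("results/counts_qc")
pairs <- read.delim("results/lr_pairs.tsv")

props <- expression_proportion(sce)
calls <- filter_interactions(pairs, props)
write_tsv_stable(calls, "results/interaction_calls.tsv")

message(sum(calls$retained), " of ", nrow(calls),
        " (emitter, receiver, pair) triples pass the 5% filter")
kept <- calls[calls$retained, ]
if (nrow(kept)) {
  print(head(kept[order(-kept$ligand_prop),
                  c("emitter", "receiver", "interaction_id",
                    "ligand_prop", "receptor_prop")], 10),
        digits = 2, row.names = FALSE)
}
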