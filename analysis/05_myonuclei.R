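#!/usr/bin/env Rscript
# Stage 5 — myonucleus typing and aging comparison.
#
# Nuclei are typed from library-size-scaled, log-transformed MYH7/MYH2/
# MYH1 expression with the strict 0.5 threshold (all three at or below
# 0.5 -> unclassified). Donor-level class proportions exclude donors with
# > 75% unclassified nuclei; young vs aged proportions are compared per
# class with the exact Mann-Whitney test.

suppressMessages(library(myoaging))
sce <- read_mtx_dir("results/counts_qc")
norm <- normalize_log(SummarizedExperiment::assay(sce, "counts"))
expr <- t(as.matrix(norm[c("MYH7", "MYH2", "MYH1"), , drop = FALSE]))

calls <- classify_myonuclei(expr, threshold = 0.5)
props <- donor_proportions(calls, sce$donor, sce$age_group)
write_tsv_stable(calls, "results/myonuclei_calls.tsv")
write_tsv_stable(props, "results/myonuclei_proportions.tsv")

message("class counts:")
print(table(calls$class))
message(sum(props$excluded), " donor(s) excluded (>75% unclassified)")

use <- props[!props$excluded, ]
tests <- do.call(rbind, lapply(
  c("MYH7+", "MYH2+", "MYH2+MYH1+"), function(cl) {
    r <- compare_age_groups(use[[cl]][use$age_group == "young"],
                            use[[cl]][use$age_group == "aged"],
                            test = "mannwhitney")
    data.frame(class = cl, statistic = r$statistic, p_value = r$p_value)
  }))
write_tsv_stable(tests, "results/myonuclei_age_tests.tsv")
print(tests, digits = 3, row.names = FALSE)
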