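#!/usr/bin/env Rscript
# Rebuild the subtype-stratified mutation frequency tables of the 87-case
# cohort and its 19-case laser-microdissected subcohort from the packaged
# per-gene marginal counts, and count novel recurrent genes outside the
# four established drivers.

suppressPackageStartupMessages(library(clonarch))

pc <- printed_cohort_counts()
fix <- reconstruct_cohort_cases(pc$counts, pc$sizes)

tab1 <- build_frequency_table(fix$cases, fix$mutations)
tab2 <- build_frequency_table(fix$cases, fix$mutations, lmd_only = TRUE)
dir.create("results", showWarnings = FALSE)
readr::write_tsv(tab1, "results/freq_table_cohort.tsv")
readr::write_tsv(tab2, "results/freq_table_lmd.tsv")
readr::write_tsv(dplyr::left_join(fix$mutations, fix$cases, by = "case_id"),
                 "results/mutation_matrix_long.tsv")

cat("Frequency table, full cohort (n =", sum(pc$sizes$n_cases), "):\n")
print(as.data.frame(tab1[1:6, c("gene", "n_all", "pct_all")]))
cat("Frequency table, microdissected subcohort (n =", sum(pc$sizes$n_lmd),
    "):\n")
print(as.data.frame(tab2[1:6, c("gene", "n_all", "pct_all")]))

rec <- recurrent_genes(fix$mutations)
cat(sprintf("Novel recurrent genes (>= 2 cases, excluding TET2/DNMT3A/RHOA/IDH2): %d of 71 panel genes (%s%%)\n",
            rec$n_genes, format_percent(percent(rec$n_genes, 71))))
cat(paste(rec$genes, collapse = ", "), "\n")
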