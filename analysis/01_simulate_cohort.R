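#!/usr/bin/env Rscript
# Simulate a 19-case cohort under the multistep, multilineal clonal model:
# an ancestral TET2/DNMT3A-mutated clone feeding a PD1+ T-lineage tumor
# subclone (G17V-RHOA/IDH2-style) and a CD20+ B-lineage subclone
# (NOTCH1-style). Writes pileup, amplicon, IgH colony and truth tables.

suppressPackageStartupMessages(library(clonarch))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- simulation_config(seed = 1L)
sim <- simulate_cohort(cfg)

write_pileup_tsv(sim$pileup, file.path(out, "pileup.tsv"))
write_amplicon_tsv(sim$amplicons, file.path(out, "amplicons.tsv"))
write_colony_tsv(sim$colonies, file.path(out, "colonies.tsv"))
readr::write_tsv(sim$truth, file.path(out, "truth.tsv"))

cat("Simulated", cfg$n_cases, "cases:",
    nrow(sim$pileup), "pileup sites,",
    nrow(sim$amplicons), "amplicon measurements,",
    nrow(sim$colonies), "IgH colonies.\n")
cat("Mutations per case and their true lineage:\n")
print(as.data.frame(sim$truth))
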