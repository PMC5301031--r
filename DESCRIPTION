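Package: clonarch
Title: Clonal Architecture of Nodal T-Cell Lymphomas from
    Compartment-Resolved Variant Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for inferring the clonal architecture of
    nodal T-cell lymphomas (angioimmunoblastic T-cell lymphoma and
    related TFH-phenotype lymphomas) from targeted sequencing of bulk
    tumor and laser-microdissected PD1+ (tumor-enriched) and CD20+
    (B-cell) compartments. Implements the variant screening cascade
    (allele frequency, read support, strand support, synonymous and
    known-SNP removal, germline allele-frequency window), classification
    of validated mutations as multilineal, T-cell-specific or
    B-cell-specific from compartment allele frequencies, IgH VDJ
    clonality and somatic-hypermutation calling from subcloned colony
    sequences, and subtype-stratified mutation frequency tables. A
    synthetic-cohort simulator generates pileup, amplicon and IgH colony
    data under the multistep, multilineal clonal model (ancestral
    epigenetic-regulator clone feeding both T- and B-lineage subclones)
    so the full workflow is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
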