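# TSV readers/writers for the workflow's interchange formats. Column
# subsets and types are pinned so round-trips are lossless.

PILEUP_COLS <- c("sample", "contig", "pos", "ref", "alt", "alt_fwd",
                 "alt_rev", "depth_fwd", "depth_rev", "effect", "known_snp")
AMPLICON_COLS <- c("sample", "mutation_id", "compartment", "alt_count",
                   "depth")
COLONY_COLS <- c("sample", "colony_id", "v_gene", "d_gene", "j_gene",
                 "junction_aa", "v_sequence")

#' Write / read pileup site tables
#'
#' @param sites Pileup tibble (extra columns are dropped on write).
#' @param path File path.
#' @return `read_pileup_tsv()` returns a typed tibble.
#' @export
write_pileup_tsv <- function(sites, path) {
  readr::write_tsv(sites[, intersect(c(PILEUP_COLS, "compartment",
                                       "mutation_id"), names(sites))], path)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE) |>
    dplyr::mutate(known_snp = as.logical(.data$known_snp))
}

#' Write / read amplicon measurement tables
#' @param amplicons Amplicon tibble.
#' @param path File path.
#' @export
write_amplicon_tsv <- function(amplicons, path) {
  readr::write_tsv(amplicons[, intersect(AMPLICON_COLS, names(amplicons))],
                   path)
  invisible(path)
}

#' @rdname write_amplicon_tsv
#' @export
read_amplicon_tsv <- function(path) {
  readr::read_tsv(path, col_types = "cccii", progress = FALSE)
}

#' Write / read IgH colony tables
#' @param colonies Colony tibble.
#' @param path File path.
#' @export
write_colony_tsv <- function(colonies, path) {
  readr::write_tsv(colonies[, intersect(COLONY_COLS, names(colonies))], path)
  invisible(path)
}

#' @rdname write_colony_tsv
#' @export
read_colony_tsv <- function(path) {
  readr::read_tsv(path, col_types = "ccccccc", progress = FALSE)
}
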