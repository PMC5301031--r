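# IgH VDJ clonality and somatic-hypermutation analysis of subcloned
# colony sequences. Colonies sharing identical V/D/J usage and junction
# amino-acid sequence form a clone; an expanded clone (>= 2 colonies among
# at least 12 picked) on a polyclonal background means oligoclonality.
# A rearranged V segment with < 98% identity to its closest germline
# reference is somatically hypermutated ("mutated").

#' Germline identity of a rearranged V segment
#'
#' Globally aligns the query against every germline reference (match +1,
#' mismatch -1, linear gap -2 by default) and reports the best-scoring
#' reference together with the percent identity, computed as
#' 100 x matches / aligned columns (gap columns included in the
#' denominator), rounded to one decimal.
#'
#' @param v_sequence Query nucleotide sequence (A/C/G/T string).
#' @param germline_refs Germline references: a named character vector or a
#'   [Biostrings::DNAStringSet]. Defaults to the packaged synthetic set.
#' @param match,mismatch,gap Alignment scores (gap is the per-column linear
#'   gap penalty, given as a negative score).
#' @return List with `best_ref` (reference name) and `identity` (percent).
#' @export
germline_identity <- function(v_sequence, germline_refs = germline_v_set(),
                              match = 1, mismatch = -1, gap = -2) {
  if (is.character(germline_refs)) {
    germline_refs <- Biostrings::DNAStringSet(germline_refs)
  }
  if (length(germline_refs) < 1) {
    stop("empty germline reference set", call. = FALSE)
  }
  if (!nzchar(v_sequence)) stop("empty query sequence", call. = FALSE)
  if (is.null(names(germline_refs))) {
    names(germline_refs) <- sprintf("ref%d", seq_along(germline_refs))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  q <- Biostrings::DNAString(v_sequence)
  scores <- vapply(seq_along(germline_refs), function(i) {
    Biostrings::pairwiseAlignment(q, germline_refs[[i]], type = "global",
                                  substitutionMatrix = mat,
                                  gapOpening = 0, gapExtension = -gap,
                                  scoreOnly = TRUE)
  }, numeric(1))
  best <- which.max(scores)
  aln <- Biostrings::pairwiseAlignment(q, germline_refs[[best]],
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = -gap)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(p == s & p != "-")
  identity <- round(100 * matches / length(p), 1)
  list(best_ref = names(germline_refs)[best], identity = identity)
}

#' Somatic hypermutation status from germline identity
#'
#' A V segment with germline identity strictly below 98% is regarded as
#' mutated (somatically hypermutated); 98% or above as unmutated.
#'
#' @param identity Percent identity in `[0, 100]` (vectorized).
#' @return Character vector, `"mutated"` or `"unmutated"`.
#' @export
call_mutation_status <- function(identity) {
  if (any(!is.finite(identity) | identity < 0 | identity > 100)) {
    stop("identity must lie in [0, 100]", call. = FALSE)
  }
  ifelse(identity < 98, "mutated", "unmutated")
}

vdj_key <- function(colonies) {
  paste(colonies$v_gene,
        ifelse(is.na(colonies$d_gene), "<noD>", colonies$d_gene),
        colonies$j_gene, colonies$junction_aa, sep = "/")
}

#' Group colonies into clones by identical VDJ usage and junction
#'
#' Colonies are grouped by the exact combination of V, D (a missing D
#' segment is its own value) and J gene plus the junction amino-acid
#' sequence; groups reaching `min_clone_size` are expanded clones.
#'
#' @param colonies Tibble of colony records for one sample (columns
#'   `colony_id`, `v_gene`, `d_gene`, `j_gene`, `junction_aa`, and
#'   `v_sequence` for downstream identity calls).
#' @param min_clone_size Minimum colonies for an expanded clone (>= 2; two
#'   identical colonies of twelve already count as a clone).
#' @return Tibble of expanded clones ordered by size (desc) then key:
#'   `v_gene`, `d_gene`, `j_gene`, `junction_aa`, `size`, `members`
#'   (list of colony ids), `v_sequence` (representative).
#' @export
group_clones <- function(colonies, min_clone_size = 2) {
  if (min_clone_size < 2) {
    stop("`min_clone_size` must be at least 2", call. = FALSE)
  }
  colonies <- tibble::as_tibble(colonies)
  if (nrow(colonies) == 0) {
    return(tibble::tibble(v_gene = character(0), d_gene = character(0),
                          j_gene = character(0), junction_aa = character(0),
                          size = integer(0), members = list(),
                          v_sequence = character(0)))
  }
  if ("sample" %in% names(colonies) &&
      dplyr::n_distinct(colonies$sample) > 1) {
    stop("group_clones() expects colonies from a single sample",
         call. = FALSE)
  }
  colonies$.key <- vdj_key(colonies)
  grp <- colonies |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      v_gene = .data$v_gene[1], d_gene = .data$d_gene[1],
      j_gene = .data$j_gene[1], junction_aa = .data$junction_aa[1],
      size = dplyr::n(),
      members = list(.data$colony_id),
      v_sequence = .data$v_sequence[1],
      .groups = "drop"
    ) |>
    dplyr::filter(.data$size >= min_clone_size) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$.key)
  grp$.key <- NULL
  grp
}

#' Call B-cell clonality from colony sequences
#'
#' Monoclonality is established by direct Sanger sequencing of the IgH PCR
#' product (subcloning not applicable); otherwise the sample is oligoclonal
#' when at least one expanded clone is found among the subcloned colonies
#' and polyclonal when all colonies are unique. Each expanded clone is
#' scored for germline identity and hypermutation status when references
#' are supplied.
#'
#' @param colonies Colony tibble for one sample (may be empty when
#'   `direct_sequence_monoclonal` is `TRUE`).
#' @param direct_sequence_monoclonal Did direct sequencing already
#'   demonstrate monoclonality?
#' @param min_clone_size Minimum colonies for an expanded clone.
#' @param germline_refs Optional germline V references for identity and
#'   hypermutation scoring of each clone.
#' @return List of class `"igh_clonality"`: `sample`, `call` (`monoclonal`,
#'   `oligoclonal` or `polyclonal`), `n_colonies`, `clones` (tibble, with
#'   `identity` and `mutation_status` when references were given).
#' @export
call_clonality <- function(colonies, direct_sequence_monoclonal = FALSE,
                           min_clone_size = 2,
                           germline_refs = NULL) {
  colonies <- tibble::as_tibble(colonies)
  sample_id <- if (nrow(colonies) > 0 && "sample" %in% names(colonies)) {
    colonies$sample[1]
  } else {
    NA_character_
  }
  if (direct_sequence_monoclonal) {
    res <- list(sample = sample_id, call = "monoclonal",
                n_colonies = nrow(colonies),
                clones = group_clones(colonies[0, ], min_clone_size))
    class(res) <- "igh_clonality"
    return(res)
  }
  if (nrow(colonies) == 0) {
    stop("no colonies and no direct-sequencing monoclonality: nothing to call",
         call. = FALSE)
  }
  clones <- group_clones(colonies, min_clone_size)
  if (!is.null(germline_refs) && nrow(clones) > 0) {
    ids <- lapply(clones$v_sequence, germline_identity,
                  germline_refs = germline_refs)
    clones$best_ref <- vapply(ids, `[[`, character(1), "best_ref")
    clones$identity <- vapply(ids, `[[`, numeric(1), "identity")
    clones$mutation_status <- call_mutation_status(clones$identity)
  }
  res <- list(
    sample = sample_id,
    call = if (nrow(clones) > 0) "oligoclonal" else "polyclonal",
    n_colonies = nrow(colonies),
    clones = clones
  )
  class(res) <- "igh_clonality"
  res
}

#' @export
print.igh_clonality <- function(x, ...) {
  cat("<igh_clonality>", x$sample, "-", x$call, "(", x$n_colonies,
      "colonies,", nrow(x$clones), "expanded clones )\n")
  if (nrow(x$clones)) print(x$clones)
  invisible(x)
}
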