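# Cohort-level aggregation: subtype-stratified gene mutation frequency
# tables and recurrently mutated genes.

#' Cohort subtype labels
#' @return Character vector of the three nodal T-cell lymphoma subtype
#'   labels used throughout.
#' @export
cohort_subtypes <- function() c("AITL", "nodal_PTCL_TFH", "PTCL_NOS_TFH")

#' Percentage rounded half-up to one decimal
#'
#' `100 * count / total`, rounded half-up to one decimal place (6.25
#' becomes 6.3, where banker's rounding would give 6.2), matching how the
#' published frequency tables round.
#'
#' @param count,total Nonnegative integers with `count <= total`,
#'   `total >= 1` (vectorized; `total` recycled).
#' @return Numeric vector of percentages.
#' @export
percent <- function(count, total) {
  if (any(total < 1)) stop("total must be >= 1", call. = FALSE)
  if (any(count < 0 | count > total)) {
    stop("count must lie in [0, total]", call. = FALSE)
  }
  p <- 100 * count / total
  floor(10 * p + 0.5 + 1e-9) / 10
}

#' Render a percentage without a trailing ".0"
#' @param x Numeric percentages.
#' @return Character vector ("75", "6.3", ...).
#' @export
format_percent <- function(x) {
  sub("\\.0$", "", sprintf("%.1f", x))
}

#' Subtype-stratified gene mutation frequency table
#'
#' For each gene, counts the cases (per subtype and overall) whose mutated
#' gene set contains it, with percentages over the subtype denominators.
#' With `lmd_only = TRUE` the table is restricted to the
#' laser-microdissected subcohort.
#'
#' @param cases Tibble with one row per case: `case_id`, `subtype` (one of
#'   [cohort_subtypes()]), `microdissected` (logical).
#' @param mutations Tibble with one row per mutated case-gene pair:
#'   `case_id`, `gene`.
#' @param genes Genes to tabulate; defaults to all mutated genes ordered by
#'   overall count (descending, ties alphabetical).
#' @param lmd_only Restrict to microdissected cases?
#' @return Tibble with one row per gene: `n_<subtype>` / `pct_<subtype>`
#'   per subtype plus `n_all` / `pct_all`.
#' @export
build_frequency_table <- function(cases, mutations, genes = NULL,
                                  lmd_only = FALSE) {
  cases <- tibble::as_tibble(cases)
  mutations <- tibble::as_tibble(mutations)
  bad <- setdiff(unique(cases$subtype), cohort_subtypes())
  if (length(bad)) {
    stop("unknown subtype label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (lmd_only) cases <- cases[cases$microdissected, ]
  if (nrow(cases) == 0) stop("no cases selected", call. = FALSE)
  mutations <- dplyr::semi_join(
    dplyr::distinct(mutations, .data$case_id, .data$gene),
    cases, by = "case_id"
  )
  if (is.null(genes)) {
    tally <- mutations |>
      dplyr::count(.data$gene, sort = FALSE) |>
      dplyr::arrange(dplyr::desc(.data$n), .data$gene)
    genes <- tally$gene
  }
  if (!length(genes)) stop("no genes to tabulate", call. = FALSE)

  denom <- table(factor(cases$subtype, levels = cohort_subtypes()))
  mut <- dplyr::left_join(mutations, cases[, c("case_id", "subtype")],
                          by = "case_id")
  out <- tibble::tibble(gene = genes)
  for (st in cohort_subtypes()) {
    n <- vapply(genes, function(g) {
      sum(mut$gene == g & mut$subtype == st)
    }, integer(1))
    out[[paste0("n_", st)]] <- unname(n)
    out[[paste0("pct_", st)]] <-
      if (denom[[st]] > 0) percent(unname(n), denom[[st]]) else NA_real_
  }
  n_all <- vapply(genes, function(g) sum(mut$gene == g), integer(1))
  out$n_all <- unname(n_all)
  out$pct_all <- percent(unname(n_all), sum(denom))
  out
}

#' Recurrently mutated genes outside the established drivers
#'
#' Genes mutated in at least `min_cases` cases, excluding the four
#' established drivers (TET2, DNMT3A, RHOA, IDH2) by default, together
#' with the number of distinct cases carrying at least one such gene.
#'
#' @param mutations Tibble of mutated case-gene pairs (`case_id`, `gene`).
#' @param exclude Genes excluded from the novel-recurrent count.
#' @param min_cases Minimum cases for a gene to count as recurrent.
#' @return List with `genes` (character), `n_genes`, `n_cases`.
#' @export
recurrent_genes <- function(mutations,
                            exclude = c("TET2", "DNMT3A", "RHOA", "IDH2"),
                            min_cases = 2) {
  mutations <- dplyr::distinct(tibble::as_tibble(mutations),
                               .data$case_id, .data$gene)
  mutations <- mutations[!mutations$gene %in% exclude, ]
  tally <- dplyr::count(mutations, .data$gene)
  rec <- sort(tally$gene[tally$n >= min_cases])
  carriers <- unique(mutations$case_id[mutations$gene %in% rec])
  list(genes = rec, n_genes = length(rec), n_cases = length(carriers))
}

#' Printed cohort counts packaged with clonarch
#'
#' Loads the per-gene, per-subtype mutated-case counts of the 87-case
#' nodal T-cell lymphoma cohort (and its 19-case laser-microdissected
#' subcohort) that ship with the package as plain TSV.
#'
#' @return List with `sizes` (subtype, `n_cases`, `n_lmd`) and `counts`
#'   (gene, subtype, `n_mutated`, `n_mutated_lmd`).
#' @export
printed_cohort_counts <- function() {
  path <- function(f) system.file("extdata", f, package = "clonarch",
                                  mustWork = TRUE)
  sizes <- readr::read_tsv(path("nodal_tcl_cohort_sizes.tsv"),
                           col_types = "cii", progress = FALSE)
  counts <- readr::read_tsv(path("nodal_tcl_gene_counts.tsv"),
                            col_types = "ccii", progress = FALSE)
  list(sizes = sizes, counts = counts)
}

#' Reconstruct a per-case mutation matrix from marginal counts
#'
#' Builds a deterministic synthetic case-level mutation matrix whose
#' per-gene, per-subtype counts (overall and within the microdissected
#' subcohort) equal the supplied marginals: within each subtype the first
#' `n_lmd` cases are microdissected, and each gene's mutations go to the
#' first `n_mutated_lmd` microdissected cases then the first remaining
#' non-microdissected cases. The marginals are reproduced exactly; the
#' co-occurrence structure across genes is an artifact of the
#' reconstruction, not data.
#'
#' @param counts,sizes As returned by [printed_cohort_counts()].
#' @return List with `cases` (`case_id`, `subtype`, `microdissected`) and
#'   `mutations` (`case_id`, `gene`).
#' @export
reconstruct_cohort_cases <- function(counts = printed_cohort_counts()$counts,
                                     sizes = printed_cohort_counts()$sizes) {
  cases <- purrr::pmap_dfr(sizes, function(subtype, n_cases, n_lmd) {
    tibble::tibble(
      case_id = sprintf("%s%02d", gsub("_", "", subtype), seq_len(n_cases)),
      subtype = subtype,
      microdissected = seq_len(n_cases) <= n_lmd
    )
  })
  muts <- purrr::pmap_dfr(counts, function(gene, subtype, n_mutated,
                                           n_mutated_lmd) {
    sub_cases <- cases[cases$subtype == subtype, ]
    n_lmd <- sum(sub_cases$microdissected)
    if (n_mutated_lmd > n_lmd ||
        n_mutated - n_mutated_lmd > nrow(sub_cases) - n_lmd) {
      stop("marginal counts for ", gene, "/", subtype,
           " are incompatible with the cohort sizes", call. = FALSE)
    }
    picked <- c(
      sub_cases$case_id[sub_cases$microdissected][seq_len(n_mutated_lmd)],
      sub_cases$case_id[!sub_cases$microdissected][
        seq_len(n_mutated - n_mutated_lmd)]
    )
    tibble::tibble(case_id = picked, gene = gene)
  })
  list(cases = cases, mutations = muts)
}
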