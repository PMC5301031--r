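# IgH VDJ colony simulator: expanded B clones share an identical
# V/D/J + junction and a V segment mutated away from a packaged germline
# reference to a target identity; polyclonal background colonies carry
# unique junctions and near-germline V segments.

#' Packaged synthetic germline IGHV reference set
#'
#' Five synthetic 300-nt V-segment sequences shipped with the package
#' (generated once under a fixed seed). They stand in for a germline IGHV
#' reference so clonality and hypermutation analyses run without any
#' download; they are not IMGT alleles.
#'
#' @return A [Biostrings::DNAStringSet] of germline V segments.
#' @export
germline_v_set <- function() {
  Biostrings::readDNAStringSet(
    system.file("extdata", "ighv_synthetic_germline.fasta",
                package = "clonarch", mustWork = TRUE)
  )
}

IGH_D_GENES <- c("D2-2", "D3-3", "D3-10", "D4-17", "D6-19")
IGH_J_GENES <- c("J1", "J2", "J3", "J4", "J5", "J6")
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_junction <- function() {
  len <- sample(10:22, 1)
  paste0("CAR", paste(sample(AA_ALPHABET, len, replace = TRUE),
                      collapse = ""), "W")
}

# substitute positions to a *different* base so realized identity matches
# the target (substitution back to the original base would inflate it)
mutate_to_identity <- function(germline_seq, identity) {
  s <- strsplit(as.character(germline_seq), "")[[1]]
  n_mut <- round((1 - identity / 100) * length(s))
  if (n_mut > 0) {
    pos <- sample(length(s), n_mut)
    s[pos] <- vapply(s[pos],
                     function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
  }
  paste(s, collapse = "")
}

#' Simulate subcloned IgH VDJ colony sequences
#'
#' Emulates picking colonies after subcloning a BIOMED-2-style IgH PCR
#' product: each expanded B clone contributes `round(fraction * n_colonies)`
#' colonies sharing identical V/D/J usage, junction amino-acid sequence and
#' V-segment sequence (a copy of a germline reference mutated to
#' `target_identity` percent identity); the remaining colonies are
#' polyclonal background, each with a distinct junction and a near-germline
#' V segment.
#'
#' @param n_colonies Total colonies picked (the study picked at least 12).
#' @param clone_fractions Numeric vector of expanded-clone colony
#'   fractions; must sum to at most 1. Empty means fully polyclonal.
#' @param target_identity Germline identity (percent, in `(0, 100]`) of
#'   each expanded clone's V segment; 100 means unmutated.
#' @param seed Optional integer seed for reproducible colony sets.
#' @param germline Germline V reference ([Biostrings::DNAStringSet]);
#'   defaults to the packaged synthetic set.
#' @param sample_id Sample label.
#' @return Tibble with columns `sample`, `colony_id`, `v_gene`, `d_gene`,
#'   `j_gene`, `junction_aa`, `v_sequence` and truth column `clone_id`
#'   (`NA` for background colonies).
#' @export
simulate_igh_colonies <- function(n_colonies, clone_fractions = numeric(0),
                                  target_identity = 72, seed = NULL,
                                  germline = germline_v_set(),
                                  sample_id = "S1") {
  if (!is.numeric(n_colonies) || length(n_colonies) != 1 || n_colonies < 1) {
    stop("`n_colonies` must be a single integer >= 1", call. = FALSE)
  }
  if (length(clone_fractions) &&
      (any(clone_fractions < 0) || sum(clone_fractions) > 1 + 1e-9)) {
    stop("`clone_fractions` must be nonnegative and sum to at most 1",
         call. = FALSE)
  }
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 100) {
    stop("`target_identity` must lie in (0, 100]", call. = FALSE)
  }
  if (length(germline) < 1) stop("empty germline reference set", call. = FALSE)

  run <- function() {
    sizes <- round(clone_fractions * n_colonies)
    if (sum(sizes) > n_colonies) {
      stop("clone fractions imply more colonies than picked", call. = FALSE)
    }
    used_junctions <- character(0)
    fresh_junction <- function() {
      repeat {
        j <- random_junction()
        if (!j %in% used_junctions) {
          used_junctions <<- c(used_junctions, j)
          return(j)
        }
      }
    }

    rows <- list()
    for (k in seq_along(sizes)) {
      if (sizes[k] == 0) next
      ref_i <- sample(length(germline), 1)
      row <- tibble::tibble(
        sample = sample_id,
        v_gene = names(germline)[ref_i],
        d_gene = sample(IGH_D_GENES, 1),
        j_gene = sample(IGH_J_GENES, 1),
        junction_aa = fresh_junction(),
        v_sequence = mutate_to_identity(germline[[ref_i]], target_identity),
        clone_id = sprintf("clone%d", k)
      )
      rows[[length(rows) + 1]] <- row[rep(1, sizes[k]), ]
    }
    n_bg <- n_colonies - sum(sizes)
    if (n_bg > 0) {
      bg <- lapply(seq_len(n_bg), function(i) {
        ref_i <- sample(length(germline), 1)
        tibble::tibble(
          sample = sample_id,
          v_gene = names(germline)[ref_i],
          d_gene = sample(IGH_D_GENES, 1),
          j_gene = sample(IGH_J_GENES, 1),
          junction_aa = fresh_junction(),
          v_sequence = mutate_to_identity(germline[[ref_i]],
                                          100 - sample(0:2, 1)),
          clone_id = NA_character_
        )
      })
      rows <- c(rows, bg)
    }
    out <- dplyr::bind_rows(rows)
    out <- out[sample(nrow(out)), ]  # shuffle picking order
    out$colony_id <- sprintf("%s_c%02d", sample_id, seq_len(nrow(out)))
    out[, c("sample", "colony_id", "v_gene", "d_gene", "j_gene",
            "junction_aa", "v_sequence", "clone_id")]
  }

  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
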