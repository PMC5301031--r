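# End-to-end orchestration (simulate -> screen -> assign -> igh ->
# summarize) plus the repeatable calibration experiments used by the
# analysis scripts and the test suite.

#' Run the full workflow on a simulated cohort
#'
#' Executes the five stages in order and writes every stage's outputs to
#' `out_dir`: simulated inputs (pileup, amplicon, colony, truth TSV and the
#' germline V FASTA), screened candidates, lineage calls with per-sample
#' gene summaries, IgH clonality calls, and the cohort frequency table. A
#' manifest (JSON) lists every file with its MD5 digest together with the
#' configuration, so identical configurations are verifiably identical runs.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if missing).
#' @param germline_fasta Path to a germline V FASTA; defaults to the
#'   packaged synthetic reference. A missing file aborts before any stage
#'   runs.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         germline_fasta = NULL) {
  validate_sim_config(config)
  if (is.null(germline_fasta)) {
    germline_fasta <- system.file("extdata", "ighv_synthetic_germline.fasta",
                                  package = "clonarch", mustWork = TRUE)
  }
  if (!file.exists(germline_fasta)) {
    stop("germline FASTA not found: ", germline_fasta, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  files <- character(0)
  emit <- function(stage, f) files[[f]] <<- stage

  # -- stage 1: simulate ----------------------------------------------------
  sim <- simulate_cohort(config)
  germ <- Biostrings::readDNAStringSet(germline_fasta)
  write_pileup_tsv(sim$pileup, path("pileup.tsv")); emit("simulate", "pileup.tsv")
  write_amplicon_tsv(sim$amplicons, path("amplicons.tsv"))
  emit("simulate", "amplicons.tsv")
  write_colony_tsv(sim$colonies, path("colonies.tsv"))
  emit("simulate", "colonies.tsv")
  readr::write_tsv(sim$truth, path("truth.tsv")); emit("simulate", "truth.tsv")
  Biostrings::writeXStringSet(germ, path("germline_v.fasta"), width = 60)
  emit("simulate", "germline_v.fasta")

  # -- stage 2: screen (discovery runs on whole-tumor DNA) ------------------
  pileup <- sim$pileup[sim$pileup$compartment == "whole_tumor", ]
  screened <- screen_variants(pileup)
  readr::write_tsv(screened, path("screened.tsv")); emit("screen", "screened.tsv")
  readr::write_tsv(screened[screened$status == "retained", ],
                   path("candidates.tsv"))
  emit("screen", "candidates.tsv")

  # -- stage 3: assign lineage from amplicon validation ---------------------
  calls <- classify_lineages(sim$amplicons)
  readr::write_tsv(calls, path("lineage_calls.tsv"))
  emit("assign", "lineage_calls.tsv")
  gene_map <- sim$truth[, c("mutation_id", "gene")]
  gene_summary <- calls |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(~ aggregate_sample(.x, gene_map)) |>
    dplyr::ungroup()
  readr::write_tsv(gene_summary, path("gene_summary.tsv"))
  emit("assign", "gene_summary.tsv")

  # -- stage 4: IgH clonality ----------------------------------------------
  clonality <- sim$colonies |>
    dplyr::group_split(.data$sample) |>
    purrr::map_dfr(function(col) {
      res <- call_clonality(col, germline_refs = germ)
      top <- if (nrow(res$clones)) res$clones[1, ] else NULL
      tibble::tibble(
        sample = res$sample, call = res$call, n_colonies = res$n_colonies,
        n_clones = nrow(res$clones),
        top_clone_size = if (is.null(top)) NA_integer_ else top$size,
        top_clone_identity = if (is.null(top)) NA_real_ else top$identity,
        top_clone_status = if (is.null(top)) NA_character_ else
          top$mutation_status
      )
    })
  readr::write_tsv(clonality, path("clonality.tsv")); emit("igh", "clonality.tsv")

  # -- stage 5: cohort summary ----------------------------------------------
  cases <- tibble::tibble(case_id = sim$cases$case_id, subtype = "AITL",
                          microdissected = TRUE)
  detected <- gene_summary[gene_summary$multilineal | gene_summary$t_specific |
                             gene_summary$b_specific, ]
  freq <- build_frequency_table(
    cases, tibble::tibble(case_id = detected$sample, gene = detected$gene)
  )
  readr::write_tsv(freq, path("freq_table.tsv"))
  emit("summarize", "freq_table.tsv")

  manifest <- list(
    config = config[setdiff(names(config), "compartment_purities")],
    compartment_purities = config$compartment_purities,
    files = tibble::tibble(
      stage = unname(unlist(files)),
      file = names(files),
      md5 = unname(tools::md5sum(file.path(out_dir, names(files))))
    )
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Lineage-recovery calibration experiment
#'
#' Simulates cases under the default architecture until `n_mutations`
#' mutation instances exist, classifies each from its amplicon
#' measurements, and compares the calls with the generative truth. Used to
#' verify that, at validation depth and error rates typical of amplicon
#' deep sequencing, classification recovers the true lineage essentially
#' always.
#'
#' @param n_mutations Number of mutation instances to score.
#' @param amplicon_depth Mean amplicon depth.
#' @param error_rate Per-base substitution error.
#' @param seed Integer seed.
#' @return List: `calls` (with `truth_lineage`), `accuracy`, and
#'   `rhoa_calls` (table of calls for the G17V-RHOA-style mutation).
#' @export
recovery_experiment <- function(n_mutations = 1000, amplicon_depth = 1000,
                                error_rate = 0.001, seed = 1L) {
  config <- simulation_config(amplicon_depth_mean = amplicon_depth,
                              error_rate = error_rate, seed = seed,
                              n_cases = 1L)
  tree <- build_default_architecture(config)
  per_case <- nrow(tree$mutations)
  n_cases <- ceiling(n_mutations / per_case)
  amp <- purrr::map_dfr(seq_len(n_cases), function(i) {
    simulate_amplicons(tree, config, sprintf("REC%04d", i),
                       seed = seed + 17L * i)
  })
  calls <- classify_lineages(amp)
  calls <- dplyr::left_join(
    calls, tree$mutations[, c("id", "gene", "truth_lineage")],
    by = c(mutation_id = "id")
  )
  calls <- calls[seq_len(n_mutations), ]
  list(
    calls = calls,
    accuracy = mean(calls$call == calls$truth_lineage),
    rhoa_calls = table(calls$call[calls$mutation_id == "RHOA_G17V"])
  )
}

#' Negative-control screening experiment
#'
#' Simulates error-only pileup sites (true VAF 0) at a given depth and
#' error rate and reports how often they survive the screening cascade.
#'
#' @param n_sites Number of error-only sites.
#' @param error_rate Per-base substitution error.
#' @param depth_mean Mean total depth.
#' @param seed Integer seed.
#' @return List: `pass_rate` (fraction retained) and `screened` tibble.
#' @export
negative_control_experiment <- function(n_sites = 1000, error_rate = 0.001,
                                        depth_mean = 100, seed = 1L) {
  withr::with_seed(seed, {
    vp <- error_adjusted_vaf(0, error_rate)
    depth <- rdepth(n_sites, depth_mean)
    depth_fwd <- stats::rbinom(n_sites, depth, 0.5)
    depth_rev <- depth - depth_fwd
    sites <- tibble::tibble(
      alt_fwd = stats::rbinom(n_sites, depth_fwd, vp),
      alt_rev = stats::rbinom(n_sites, depth_rev, vp),
      depth_fwd = depth_fwd, depth_rev = depth_rev,
      effect = "nonsynonymous", known_snp = FALSE
    )
    screened <- screen_variants(sites)
    list(pass_rate = mean(screened$status == "retained"), screened = screened)
  })
}

#' IgH simulate-and-call round-trip experiment
#'
#' Repeatedly simulates a colony set containing one expanded clone and
#' calls clonality plus clone hypermutation status, reporting how often the
#' full round trip recovers an oligoclonal sample with a mutated clone.
#'
#' @param n_seeds Number of independent colony sets.
#' @param n_colonies Colonies per set.
#' @param clone_fraction Expanded-clone colony fraction.
#' @param target_identity Target germline identity (percent) of the clone.
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @return List: `oligoclonal_rate`, `oligoclonal_mutated_rate`,
#'   `identities` (realized clone identities).
#' @export
igh_roundtrip_experiment <- function(n_seeds = 200, n_colonies = 12,
                                     clone_fraction = 2 / 12,
                                     target_identity = 72, seed = 1L) {
  germ <- germline_v_set()
  oligo <- logical(n_seeds)
  mutated <- logical(n_seeds)
  identities <- rep(NA_real_, n_seeds)
  for (i in seq_len(n_seeds)) {
    col <- simulate_igh_colonies(n_colonies, clone_fraction, target_identity,
                                 seed = seed + i, germline = germ,
                                 sample_id = sprintf("RT%03d", i))
    res <- call_clonality(col, germline_refs = germ)
    oligo[i] <- res$call == "oligoclonal"
    if (nrow(res$clones)) {
      identities[i] <- res$clones$identity[1]
      mutated[i] <- res$clones$mutation_status[1] == "mutated"
    }
  }
  list(
    oligoclonal_rate = mean(oligo),
    oligoclonal_mutated_rate = mean(oligo & mutated),
    identities = identities
  )
}
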