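# Read-count simulators for the discovery (pileup) and validation
# (amplicon) stages. Count model: total depth ~ Poisson(mean); each read is
# assigned to a strand by a fair coin; each read is an alt read with
# probability v' = v(1-e) + (1-v) e/3, folding the per-base substitution
# error toward the specific alt base into the allele frequency. The
# per-read strand model guarantees alt_fwd <= depth_fwd by construction
# while keeping the marginal alt count Binomial(depth, v').

error_adjusted_vaf <- function(v, error_rate) {
  v * (1 - error_rate) + (1 - v) * error_rate / 3
}

rdepth <- function(n, mean) {
  d <- stats::rpois(n, mean)
  d + (d == 0L)  # depth >= 1 so a VAF is always defined
}

#' Simulate targeted-sequencing pileup sites for one case
#'
#' For every mutation in the clone tree and every compartment, draws a
#' stranded read-count pileup around the mutation's expected VAF. Also
#' emits error-only sites (expected VAF 0, negative controls for the
#' screening cascade) and heterozygous germline known-SNP decoy sites
#' (expected VAF 0.5, flagged `known_snp`).
#'
#' @param tree A [clone_tree()].
#' @param config A [simulation_config()]; `depth_mean` and `error_rate`
#'   drive the count model.
#' @param case_id Sample label prefix.
#' @param seed Integer seed (defaults to `config$seed`); the same seed
#'   reproduces the identical site list.
#' @return Tibble with one row per site x compartment: `sample` (case and
#'   compartment), `case_id`, `compartment`, `contig`, `pos`, `ref`, `alt`,
#'   `alt_fwd`, `alt_rev`, `depth_fwd`, `depth_rev`, `effect`, `known_snp`,
#'   plus the simulator truth columns `mutation_id` and `true_vaf`.
#' @export
simulate_pileup <- function(tree, config, case_id = "case01",
                            seed = config$seed) {
  stopifnot(inherits(tree, "clone_tree"))
  validate_sim_config(config)
  withr::with_seed(seed, {
    mut <- tree$mutations
    grid <- tidyr::expand_grid(mutation_id = mut$id,
                               compartment = compartments())
    grid <- dplyr::left_join(grid, mut, by = c(mutation_id = "id"))
    grid$true_vaf <- mapply(function(m, comp) expected_vaf(tree, m, comp),
                            grid$mutation_id, grid$compartment)
    sites <- tibble::tibble(
      case_id = case_id,
      compartment = grid$compartment,
      mutation_id = grid$mutation_id,
      contig = grid$contig, pos = grid$pos,
      ref = grid$ref, alt = grid$alt,
      effect = grid$effect,
      known_snp = FALSE,
      true_vaf = grid$true_vaf
    )

    bases <- c("A", "C", "G", "T")
    if (config$n_error_sites > 0) {
      idx <- seq_len(config$n_error_sites)
      err <- tidyr::expand_grid(i = idx, compartment = compartments())
      sites <- dplyr::bind_rows(sites, tibble::tibble(
        case_id = case_id,
        compartment = err$compartment,
        mutation_id = sprintf("errctrl_%02d", err$i),
        contig = "chrE", pos = 1000L * err$i,
        ref = bases[(err$i - 1L) %% 4L + 1L],
        alt = bases[err$i %% 4L + 1L],
        effect = "nonsynonymous", known_snp = FALSE, true_vaf = 0
      ))
    }
    if (config$n_snp_sites > 0) {
      idx <- seq_len(config$n_snp_sites)
      snp <- tidyr::expand_grid(i = idx, compartment = compartments())
      sites <- dplyr::bind_rows(sites, tibble::tibble(
        case_id = case_id,
        compartment = snp$compartment,
        mutation_id = sprintf("snp_%02d", snp$i),
        contig = "chrS", pos = 500L * snp$i,
        ref = bases[(snp$i - 1L) %% 4L + 1L],
        alt = bases[snp$i %% 4L + 1L],
        effect = "nonsynonymous", known_snp = TRUE, true_vaf = 0.5
      ))
    }

    n <- nrow(sites)
    vp <- error_adjusted_vaf(sites$true_vaf, config$error_rate)
    depth <- rdepth(n, config$depth_mean)
    depth_fwd <- stats::rbinom(n, depth, 0.5)
    depth_rev <- depth - depth_fwd
    alt_fwd <- stats::rbinom(n, depth_fwd, vp)
    alt_rev <- stats::rbinom(n, depth_rev, vp)

    out <- tibble::tibble(
      sample = paste(sites$case_id, sites$compartment, sep = "."),
      case_id = sites$case_id,
      compartment = sites$compartment,
      contig = sites$contig, pos = sites$pos,
      ref = sites$ref, alt = sites$alt,
      alt_fwd = alt_fwd, alt_rev = alt_rev,
      depth_fwd = depth_fwd, depth_rev = depth_rev,
      effect = sites$effect, known_snp = sites$known_snp,
      mutation_id = sites$mutation_id, true_vaf = sites$true_vaf
    )
    out
  })
}

#' Simulate amplicon deep-sequencing validation for one case
#'
#' One measurement per mutation and compartment: depth drawn from a Poisson
#' around `amplicon_depth_mean`, alt reads binomial at the error-adjusted
#' expected VAF. This is the validation stage whose VAFs drive lineage
#' classification.
#'
#' @inheritParams simulate_pileup
#' @return Tibble with columns `sample`, `mutation_id`, `compartment`,
#'   `alt_count`, `depth`, `vaf`, plus truth column `true_vaf`.
#' @export
simulate_amplicons <- function(tree, config, case_id = "case01",
                               seed = config$seed + 1L) {
  stopifnot(inherits(tree, "clone_tree"))
  validate_sim_config(config)
  withr::with_seed(seed, {
    mut <- tree$mutations
    grid <- tidyr::expand_grid(mutation_id = mut$id,
                               compartment = compartments())
    grid$true_vaf <- mapply(function(m, comp) expected_vaf(tree, m, comp),
                            grid$mutation_id, grid$compartment)
    n <- nrow(grid)
    vp <- error_adjusted_vaf(grid$true_vaf, config$error_rate)
    depth <- rdepth(n, config$amplicon_depth_mean)
    alt <- stats::rbinom(n, depth, vp)
    tibble::tibble(
      sample = case_id,
      mutation_id = grid$mutation_id,
      compartment = grid$compartment,
      alt_count = alt,
      depth = depth,
      vaf = alt / depth,
      true_vaf = grid$true_vaf
    )
  })
}

#' Simulate a whole synthetic cohort
#'
#' Applies the default architecture to `config$n_cases` cases and draws
#' pileup, amplicon and IgH colony data for each. Cases with a B-lineage
#' subclone receive one expanded IgH clone at `config$b_clone_fraction`
#' with V-segment germline identity around `config$igh_target_identity`;
#' otherwise the colony set is polyclonal background only.
#'
#' @param config A [simulation_config()].
#' @return List with elements `tree`, `cases` (tibble of case ids),
#'   `pileup`, `amplicons`, `colonies` and `truth` (mutation id to true
#'   lineage).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  validate_sim_config(config)
  tree <- build_default_architecture(config)
  case_ids <- sprintf("PTCLSIM%02d", seq_len(config$n_cases))
  germ <- germline_v_set()

  pile <- vector("list", config$n_cases)
  amp <- vector("list", config$n_cases)
  col <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    base <- config$seed + 7919L * i
    pile[[i]] <- simulate_pileup(tree, config, case_ids[i], seed = base)
    amp[[i]] <- simulate_amplicons(tree, config, case_ids[i], seed = base + 1L)
    fractions <- if (config$include_b_subclone) config$b_clone_fraction else numeric(0)
    col[[i]] <- simulate_igh_colonies(
      n_colonies = config$n_colonies,
      clone_fractions = fractions,
      target_identity = config$igh_target_identity,
      seed = base + 2L, germline = germ, sample_id = case_ids[i]
    )
  }

  list(
    tree = tree,
    cases = tibble::tibble(case_id = case_ids),
    pileup = dplyr::bind_rows(pile),
    amplicons = dplyr::bind_rows(amp),
    colonies = dplyr::bind_rows(col),
    truth = tree$mutations[, c("id", "gene", "truth_lineage")] |>
      dplyr::rename(mutation_id = "id")
  )
}
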