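#' Assayed cell compartments
#'
#' The three cell populations assayed in the workflow: bulk tumor DNA,
#' laser-microdissected PD1+ cells (enriched for TFH-phenotype tumor cells)
#' and laser-microdissected CD20+ infiltrating B cells.
#'
#' @return Character vector of compartment labels.
#' @export
compartments <- function() c("whole_tumor", "PD1pos", "CD20pos")

#' Default compartment composition for the simulated clonal hierarchy
#'
#' For each compartment, the cell fraction occupied by the ancestral
#' (epigenetic-regulator-mutated) clone and by its T-lineage and B-lineage
#' subclones. Microdissection enriches the PD1+ compartment for the T
#' subclone and depletes it from the CD20+ compartment; the B subclone is
#' confined to B-cell-containing compartments. Subclone fractions are nested
#' within the ancestral fraction, so `T + B <= ancestral` must hold.
#'
#' @return Named list (one element per compartment) of named numeric
#'   vectors with elements `ancestral`, `T`, `B`.
#' @export
default_purities <- function() {
  list(
    whole_tumor = c(ancestral = 0.65, T = 0.35, B = 0.15),
    PD1pos      = c(ancestral = 0.90, T = 0.80, B = 0.00),
    CD20pos     = c(ancestral = 0.50, T = 0.00, B = 0.40)
  )
}

validate_purities <- function(purities) {
  if (!is.list(purities) || !setequal(names(purities), compartments())) {
    stop("`compartment_purities` must be a named list with one entry per compartment: ",
         paste(compartments(), collapse = ", "), call. = FALSE)
  }
  for (comp in names(purities)) {
    p <- purities[[comp]]
    if (!is.numeric(p) || !all(c("ancestral", "T", "B") %in% names(p))) {
      stop("purity entry for ", comp, " must be a named numeric vector with ",
           "elements ancestral, T, B", call. = FALSE)
    }
    if (any(p < 0 | p > 1)) {
      stop("cell fractions for ", comp, " must lie in [0, 1]", call. = FALSE)
    }
    if (p[["T"]] + p[["B"]] > p[["ancestral"]] + 1e-12) {
      stop("subclone fractions in ", comp, " exceed the ancestral clone fraction",
           call. = FALSE)
    }
  }
  invisible(purities)
}

#' Configuration for the synthetic cohort simulator
#'
#' Bundles every tunable of the generative model: sequencing depths for the
#' discovery (targeted capture) and validation (amplicon deep sequencing)
#' stages, the per-base substitution error rate, compartment composition,
#' whether a B-lineage subclone (NOTCH1-style mutation) is present, decoy
#' site counts for the screening stage, and the IgH colony settings.
#'
#' @param depth_mean Mean total depth at the targeted-discovery stage
#'   (Poisson mean, reads).
#' @param amplicon_depth_mean Mean depth of amplicon deep-sequencing
#'   validation (Poisson mean, reads).
#' @param error_rate Per-base substitution probability, in `[0, 0.01]`.
#' @param compartment_purities Clone cell fractions per compartment; see
#'   [default_purities()].
#' @param include_b_subclone Simulate a B-lineage subclone carrying a
#'   NOTCH1-style mutation?
#' @param n_error_sites Error-only negative-control sites per compartment.
#' @param n_snp_sites Heterozygous germline known-SNP decoy sites.
#' @param n_cases Number of simulated cases in a cohort.
#' @param n_colonies IgH colonies picked per case (the study picked at
#'   least 12).
#' @param b_clone_fraction Fraction of colonies belonging to the expanded
#'   B clone in B-subclone cases.
#' @param igh_target_identity Target germline identity (percent) of the
#'   expanded B clone's V segment.
#' @param seed Integer seed; identical configurations (including seed)
#'   reproduce identical outputs.
#'
#' @return A list of class `"sim_config"`, validated.
#' @export
simulation_config <- function(depth_mean = 200,
                              amplicon_depth_mean = 1000,
                              error_rate = 0.001,
                              compartment_purities = default_purities(),
                              include_b_subclone = TRUE,
                              n_error_sites = 10,
                              n_snp_sites = 3,
                              n_cases = 19,
                              n_colonies = 12,
                              b_clone_fraction = 2 / 12,
                              igh_target_identity = 72,
                              seed = 1L) {
  cfg <- list(
    depth_mean = depth_mean,
    amplicon_depth_mean = amplicon_depth_mean,
    error_rate = error_rate,
    compartment_purities = compartment_purities,
    include_b_subclone = isTRUE(include_b_subclone),
    n_error_sites = n_error_sites,
    n_snp_sites = n_snp_sites,
    n_cases = n_cases,
    n_colonies = n_colonies,
    b_clone_fraction = b_clone_fraction,
    igh_target_identity = igh_target_identity,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(cfg$depth_mean) || cfg$depth_mean < 1) {
    stop("`depth_mean` must be a single number >= 1", call. = FALSE)
  }
  if (!num1(cfg$amplicon_depth_mean) || cfg$amplicon_depth_mean < 1) {
    stop("`amplicon_depth_mean` must be a single number >= 1", call. = FALSE)
  }
  if (!num1(cfg$error_rate) || cfg$error_rate < 0 || cfg$error_rate > 0.01) {
    stop("`error_rate` must lie in [0, 0.01]", call. = FALSE)
  }
  validate_purities(cfg$compartment_purities)
  for (fld in c("n_error_sites", "n_snp_sites", "n_cases", "n_colonies")) {
    if (!num1(cfg[[fld]]) || cfg[[fld]] < 0 || cfg[[fld]] != round(cfg[[fld]])) {
      stop("`", fld, "` must be a nonnegative integer", call. = FALSE)
    }
  }
  if (cfg$n_cases < 1) stop("`n_cases` must be >= 1", call. = FALSE)
  if (cfg$n_colonies < 1) stop("`n_colonies` must be >= 1", call. = FALSE)
  if (!num1(cfg$b_clone_fraction) || cfg$b_clone_fraction < 0 ||
      cfg$b_clone_fraction > 1) {
    stop("`b_clone_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!num1(cfg$igh_target_identity) || cfg$igh_target_identity <= 0 ||
      cfg$igh_target_identity > 100) {
    stop("`igh_target_identity` must lie in (0, 100]", call. = FALSE)
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  invisible(cfg)
}
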