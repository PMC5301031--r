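# Variant screening cascade for targeted-sequencing pileup summaries.
# Six rules, applied in a fixed order; a removed site reports the first
# rule it failed so the cascade is auditable:
#   1. VAF > 0.02 (strict)
#   2. alt reads > 6 and total depth > 10 (strict, i.e. alt >= 7, depth >= 11)
#   3. alt support on both strands (>= 1 read each)
#   4. not synonymous
#   5. not a known SNP (public/private database flag carried on the input)
#   6. VAF outside the germline window [0.45, 0.55] (inclusive)

SCREEN_REASONS <- c("low_vaf", "low_support", "low_depth", "single_strand",
                    "synonymous", "known_snp", "germline_window")

#' Variant allele frequency from stranded pileup counts
#'
#' Combined-strand VAF: `(alt_fwd + alt_rev) / (depth_fwd + depth_rev)`.
#'
#' @param alt_fwd,alt_rev Alt-supporting read counts per strand.
#' @param depth_fwd,depth_rev Total read counts per strand.
#' @return Numeric vector of VAFs in `[0, 1]`.
#' @export
compute_vaf <- function(alt_fwd, alt_rev, depth_fwd, depth_rev) {
  if (any(alt_fwd < 0 | alt_rev < 0 | depth_fwd < 0 | depth_rev < 0)) {
    stop("read counts must be nonnegative", call. = FALSE)
  }
  if (any(alt_fwd > depth_fwd | alt_rev > depth_rev)) {
    stop("alt reads cannot exceed depth on a strand", call. = FALSE)
  }
  total <- depth_fwd + depth_rev
  if (any(total < 1)) {
    stop("VAF undefined at zero total depth", call. = FALSE)
  }
  (alt_fwd + alt_rev) / total
}

#' Screen pileup sites through the variant-extraction cascade
#'
#' Applies the six screening rules in order to every input site. Each site
#' appears exactly once in the output, annotated with its VAF, a
#' `retained`/`removed` status and (for removed sites) the first failing
#' rule as `removal_reason`.
#'
#' @param sites Data frame of pileup sites with columns `alt_fwd`,
#'   `alt_rev`, `depth_fwd`, `depth_rev`, `effect`
#'   (`nonsynonymous`/`synonymous`) and `known_snp` (logical); any further
#'   columns (sample, contig, pos, ref, alt, ...) pass through.
#' @return The input tibble plus columns `vaf`, `status` and
#'   `removal_reason` (`NA` for retained sites), in input order.
#' @export
screen_variants <- function(sites) {
  sites <- tibble::as_tibble(sites)
  need <- c("alt_fwd", "alt_rev", "depth_fwd", "depth_rev", "effect",
            "known_snp")
  missing <- setdiff(need, names(sites))
  if (length(missing)) {
    stop("pileup input lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(sites) == 0) {
    sites$vaf <- numeric(0)
    sites$status <- character(0)
    sites$removal_reason <- character(0)
    return(sites)
  }
  if (!all(sites$effect %in% c("nonsynonymous", "synonymous"))) {
    stop("`effect` must be nonsynonymous or synonymous", call. = FALSE)
  }
  vaf <- compute_vaf(sites$alt_fwd, sites$alt_rev,
                     sites$depth_fwd, sites$depth_rev)
  alt <- sites$alt_fwd + sites$alt_rev
  depth <- sites$depth_fwd + sites$depth_rev

  reason <- dplyr::case_when(
    !(vaf > 0.02)                        ~ "low_vaf",
    !(alt > 6)                           ~ "low_support",
    !(depth > 10)                        ~ "low_depth",
    sites$alt_fwd < 1 | sites$alt_rev < 1 ~ "single_strand",
    sites$effect == "synonymous"         ~ "synonymous",
    sites$known_snp                      ~ "known_snp",
    vaf >= 0.45 & vaf <= 0.55            ~ "germline_window",
    .default = NA_character_
  )
  sites$vaf <- vaf
  sites$status <- ifelse(is.na(reason), "retained", "removed")
  sites$removal_reason <- reason
  sites
}
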