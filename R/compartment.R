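# Compartment-resolved lineage assignment. A validated mutation is
# classified from its amplicon deep-sequencing measurements in the two
# microdissected compartments:
#   detected in PD1+ and CD20+      -> multilineal (ancestral acquisition)
#   detected only in PD1+           -> T_specific (tumor-cell event)
#   detected only in CD20+          -> B_specific (infiltrating B cells)
#   detected in neither             -> undetected
#   inadequate depth in either      -> indeterminate
# The whole-tumor measurement never influences the call; it only feeds the
# PD1+ enrichment ratio.

#' Detection and enrichment thresholds
#'
#' The study reports compartment detection qualitatively; these thresholds
#' operationalize it and are calibrated so that error-only sites are
#' essentially never "detected" at amplicon depths. `enrichment_factor`
#' operationalizes "substantially higher" PD1+ VAF relative to whole tumor.
#'
#' @param min_vaf Minimum VAF for detection.
#' @param min_alt Minimum alt read count for detection.
#' @param min_depth Minimum depth for an informative (non-indeterminate)
#'   measurement.
#' @param enrichment_factor PD1+/whole-tumor VAF ratio regarded as
#'   substantial enrichment.
#' @return Named list of thresholds.
#' @export
detection_thresholds <- function(min_vaf = 0.02, min_alt = 5,
                                 min_depth = 100, enrichment_factor = 1.5) {
  th <- list(min_vaf = min_vaf, min_alt = min_alt, min_depth = min_depth,
             enrichment_factor = enrichment_factor)
  if (any(vapply(th, function(x) !is.numeric(x) || length(x) != 1 || x < 0,
                 logical(1)))) {
    stop("thresholds must be single nonnegative numbers", call. = FALSE)
  }
  th
}

#' Is a mutation detected in one compartment?
#'
#' @param alt_count,depth Amplicon read counts (vectorized).
#' @param thresholds A [detection_thresholds()] list.
#' @return Logical vector: `TRUE`/`FALSE` detection, `NA` when depth is
#'   below `min_depth` (indeterminate).
#' @export
detect_in_compartment <- function(alt_count, depth,
                                  thresholds = detection_thresholds()) {
  if (any(alt_count < 0 | depth < 0, na.rm = TRUE)) {
    stop("read counts must be nonnegative", call. = FALSE)
  }
  if (any(alt_count > depth, na.rm = TRUE)) {
    stop("alt_count cannot exceed depth", call. = FALSE)
  }
  vaf <- ifelse(depth > 0, alt_count / depth, 0)
  out <- vaf >= thresholds$min_vaf & alt_count >= thresholds$min_alt
  out[is.na(alt_count) | is.na(depth) | depth < thresholds$min_depth] <- NA
  out
}

#' Classify mutations as multilineal, T-specific or B-specific
#'
#' Vectorized over a table of amplicon measurements: every
#' (sample, mutation) pair receives exactly one lineage call from its PD1+
#' and CD20+ detection status, plus the PD1+/whole-tumor enrichment ratio
#' when a whole-tumor measurement exists.
#'
#' @param measurements Data frame with columns `sample`, `mutation_id`,
#'   `compartment` (one of [compartments()]), `alt_count`, `depth`; at most
#'   one row per sample x mutation x compartment.
#' @param thresholds A [detection_thresholds()] list.
#' @return Tibble with one row per sample x mutation: `call` (one of
#'   `multilineal`, `T_specific`, `B_specific`, `undetected`,
#'   `indeterminate`), `detected_pd1`, `detected_cd20`, `enrichment_ratio`
#'   (`NA` when whole-tumor VAF is 0 or unmeasured) and `enriched`.
#' @export
classify_lineages <- function(measurements,
                              thresholds = detection_thresholds()) {
  m <- tibble::as_tibble(measurements)
  need <- c("sample", "mutation_id", "compartment", "alt_count", "depth")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("amplicon input lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(m$compartment %in% compartments())) {
    stop("unknown compartment label in measurements", call. = FALSE)
  }
  if (anyDuplicated(m[, c("sample", "mutation_id", "compartment")])) {
    stop("duplicate measurement for a sample/mutation/compartment",
         call. = FALSE)
  }
  m$vaf <- ifelse(m$depth > 0, m$alt_count / m$depth, 0)
  m$det <- detect_in_compartment(m$alt_count, m$depth, thresholds)

  wide <- tidyr::pivot_wider(
    m[, c("sample", "mutation_id", "compartment", "vaf", "det")],
    names_from = "compartment", values_from = c("vaf", "det")
  )
  for (col in c("vaf_PD1pos", "vaf_CD20pos", "vaf_whole_tumor")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  for (col in c("det_PD1pos", "det_CD20pos")) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }

  pd1 <- wide$det_PD1pos
  cd20 <- wide$det_CD20pos
  call <- dplyr::case_when(
    is.na(pd1) | is.na(cd20) ~ "indeterminate",
    pd1 & cd20               ~ "multilineal",
    pd1 & !cd20              ~ "T_specific",
    !pd1 & cd20              ~ "B_specific",
    .default = "undetected"
  )
  ratio <- ifelse(!is.na(wide$vaf_whole_tumor) & wide$vaf_whole_tumor > 0,
                  wide$vaf_PD1pos / wide$vaf_whole_tumor, NA_real_)
  tibble::tibble(
    sample = wide$sample,
    mutation_id = wide$mutation_id,
    call = call,
    detected_pd1 = pd1,
    detected_cd20 = cd20,
    vaf_pd1 = wide$vaf_PD1pos,
    vaf_cd20 = wide$vaf_CD20pos,
    vaf_whole = wide$vaf_whole_tumor,
    enrichment_ratio = ratio,
    enriched = !is.na(ratio) & ratio >= thresholds$enrichment_factor
  )
}

#' Classify a single mutation
#'
#' Convenience wrapper around [classify_lineages()] for the measurements of
#' one mutation in one sample.
#'
#' @param measurements Data frame of measurements for one sample/mutation
#'   (columns `compartment`, `alt_count`, `depth`; `sample` and
#'   `mutation_id` optional).
#' @inheritParams classify_lineages
#' @return One-row tibble as in [classify_lineages()].
#' @export
classify_lineage <- function(measurements,
                             thresholds = detection_thresholds()) {
  m <- tibble::as_tibble(measurements)
  if (!"sample" %in% names(m)) m$sample <- "S1"
  if (!"mutation_id" %in% names(m)) m$mutation_id <- "mut1"
  if (dplyr::n_distinct(m$sample) > 1 || dplyr::n_distinct(m$mutation_id) > 1) {
    stop("classify_lineage() expects measurements of a single mutation",
         call. = FALSE)
  }
  classify_lineages(m, thresholds)
}

#' PD1+ enrichment ratio relative to whole tumor
#'
#' Ratio of a mutation's VAF in the microdissected PD1+ compartment to its
#' VAF in matched whole-tumor DNA. `NA` when the whole-tumor VAF is zero
#' (detected only after enrichment).
#'
#' @param pd1,whole One-row data frames (or lists) with fields
#'   `mutation_id`, `alt_count`, `depth` for the same mutation.
#' @param factor Ratio regarded as substantial enrichment.
#' @return One-row tibble with `mutation_id`, `ratio`, `enriched`.
#' @export
enrichment_ratio <- function(pd1, whole, factor = 1.5) {
  if (!identical(pd1$mutation_id, whole$mutation_id)) {
    stop("PD1+ and whole-tumor measurements are for different mutations",
         call. = FALSE)
  }
  vaf_pd1 <- pd1$alt_count / pd1$depth
  vaf_whole <- whole$alt_count / whole$depth
  ratio <- if (vaf_whole > 0) vaf_pd1 / vaf_whole else NA_real_
  tibble::tibble(
    mutation_id = pd1$mutation_id,
    ratio = ratio,
    enriched = !is.na(ratio) && ratio >= factor
  )
}

#' Per-sample gene summary of lineage calls
#'
#' Collapses mutation-level calls to gene level for one sample: a gene is
#' multilineal in the sample iff at least one of its mutations is called
#' multilineal (and likewise for T- and B-specific calls), mirroring
#' "at least one mutation in both compartments" case counting.
#'
#' @param calls Tibble of lineage calls for one sample (columns
#'   `mutation_id`, `call`).
#' @param gene_map Tibble mapping `mutation_id` to `gene`.
#' @return Tibble with one row per gene: `gene`, `multilineal`,
#'   `t_specific`, `b_specific` (logicals).
#' @export
aggregate_sample <- function(calls, gene_map) {
  calls <- tibble::as_tibble(calls)
  if ("sample" %in% names(calls) && dplyr::n_distinct(calls$sample) > 1) {
    stop("aggregate_sample() expects calls from a single sample",
         call. = FALSE)
  }
  unknown <- setdiff(calls$mutation_id, gene_map$mutation_id)
  if (length(unknown)) {
    stop("mutation ids missing from gene map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(calls, gene_map[, c("mutation_id", "gene")],
                   by = "mutation_id") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      multilineal = any(.data$call == "multilineal"),
      t_specific = any(.data$call == "T_specific"),
      b_specific = any(.data$call == "B_specific"),
      .groups = "drop"
    )
}
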