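#' Clonal hierarchy of a simulated case
#'
#' A clone tree holds the generative clonal structure of one simulated
#' tumor: a set of clone nodes (with lineage labels and per-compartment
#' cell fractions) and the mutations each node carries. The lineage of the
#' carrying node determines a mutation's true compartment distribution:
#' mutations of the ancestral clone are multilineal (present in both T and
#' B descendants), mutations of the T-lineage subclone are T-specific and
#' mutations of the B-lineage subclone are B-specific.
#'
#' @param nodes Tibble with columns `id`, `parent` (`NA` for the root) and
#'   `lineage` (one of `ancestral`, `T`, `B`).
#' @param fractions Tibble with columns `node`, `compartment`, `fraction`
#'   giving each node's cell fraction in each compartment.
#' @param mutations Tibble with columns `id`, `gene`, `effect`
#'   (`nonsynonymous`/`synonymous`), `zygosity` (`het`/`hom`), `node`, and
#'   site columns `contig`, `pos`, `ref`, `alt`.
#'
#' @return A validated object of class `"clone_tree"`; `mutations` gains a
#'   `truth_lineage` column derived from the carrying node's lineage.
#' @export
clone_tree <- function(nodes, fractions, mutations) {
  lineage_to_truth <- c(ancestral = "multilineal", T = "T_specific",
                        B = "B_specific")
  mutations$truth_lineage <-
    unname(lineage_to_truth[nodes$lineage[match(mutations$node, nodes$id)]])
  tree <- structure(
    list(nodes = tibble::as_tibble(nodes),
         fractions = tibble::as_tibble(fractions),
         mutations = tibble::as_tibble(mutations)),
    class = "clone_tree"
  )
  validate_clone_tree(tree)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree>", nrow(x$nodes), "clones,", nrow(x$mutations),
      "mutations\n")
  print(x$nodes)
  invisible(x)
}

validate_clone_tree <- function(tree) {
  nodes <- tree$nodes
  frac <- tree$fractions
  mut <- tree$mutations
  if (sum(is.na(nodes$parent)) != 1) {
    stop("clone tree must have exactly one root (parent NA)", call. = FALSE)
  }
  root <- nodes$id[is.na(nodes$parent)]
  if (nodes$lineage[nodes$id == root] != "ancestral") {
    stop("the root clone must have lineage 'ancestral'", call. = FALSE)
  }
  if (!all(stats::na.omit(nodes$parent) %in% nodes$id)) {
    stop("every non-root clone's parent must be a clone in the tree",
         call. = FALSE)
  }
  if (!all(nodes$lineage %in% c("ancestral", "T", "B"))) {
    stop("clone lineage must be one of ancestral, T, B", call. = FALSE)
  }
  if (any(frac$fraction < 0 | frac$fraction > 1)) {
    stop("cell fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!all(frac$compartment %in% compartments())) {
    stop("unknown compartment in fractions: ",
         paste(setdiff(frac$compartment, compartments()), collapse = ", "),
         call. = FALSE)
  }
  # every node needs a fraction in every compartment
  need <- expand.grid(node = nodes$id, compartment = compartments(),
                      stringsAsFactors = FALSE)
  have <- paste(frac$node, frac$compartment)
  if (!all(paste(need$node, need$compartment) %in% have)) {
    stop("every clone needs a cell fraction in every compartment",
         call. = FALSE)
  }
  get_frac <- function(node, comp) {
    frac$fraction[frac$node == node & frac$compartment == comp]
  }
  for (comp in compartments()) {
    for (i in seq_len(nrow(nodes))) {
      if (is.na(nodes$parent[i])) next
      child <- get_frac(nodes$id[i], comp)
      parent <- get_frac(nodes$parent[i], comp)
      if (child > parent + 1e-12) {
        stop("clone ", nodes$id[i], " exceeds its parent's cell fraction in ",
             comp, call. = FALSE)
      }
    }
    for (p in nodes$id) {
      kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == p]
      if (length(kids) > 1) {
        if (sum(vapply(kids, get_frac, numeric(1), comp = comp)) >
            get_frac(p, comp) + 1e-12) {
          stop("sibling subclones of ", p, " sum beyond the parent fraction in ",
               comp, call. = FALSE)
        }
      }
    }
  }
  if (!all(mut$node %in% nodes$id)) {
    stop("mutation assigned to unknown clone", call. = FALSE)
  }
  if (anyDuplicated(mut$id)) stop("duplicate mutation ids", call. = FALSE)
  if (!all(mut$effect %in% c("nonsynonymous", "synonymous"))) {
    stop("mutation effect must be nonsynonymous or synonymous", call. = FALSE)
  }
  if (!all(mut$zygosity %in% c("het", "hom"))) {
    stop("mutation zygosity must be het or hom", call. = FALSE)
  }
  invisible(tree)
}

#' Build the default multistep, multilineal clonal architecture
#'
#' Constructs the three-node hierarchy the simulator emulates: an ancestral
#' clone carrying TET2/DNMT3A-style epigenetic-regulator mutations (plus a
#' synonymous passenger), a T-lineage tumor subclone carrying G17V-RHOA- and
#' IDH2-style hotspot mutations, and (optionally) a B-lineage subclone
#' carrying a NOTCH1-style mutation. Per-compartment cell fractions come
#' from `config$compartment_purities`: the PD1+ compartment is enriched for
#' the T subclone and the CD20+ compartment depleted of it.
#'
#' @param config A [simulation_config()].
#' @return A [clone_tree()].
#' @export
build_default_architecture <- function(config = simulation_config()) {
  validate_sim_config(config)
  pur <- config$compartment_purities

  node_ids <- c("ancestral", "T_subclone")
  parents <- c(NA, "ancestral")
  lineages <- c("ancestral", "T")
  if (config$include_b_subclone) {
    node_ids <- c(node_ids, "B_subclone")
    parents <- c(parents, "ancestral")
    lineages <- c(lineages, "B")
  }
  nodes <- tibble::tibble(id = node_ids, parent = parents, lineage = lineages)

  key <- c(ancestral = "ancestral", T_subclone = "T", B_subclone = "B")
  fractions <- tidyr::expand_grid(node = node_ids,
                                  compartment = compartments())
  fractions$fraction <- mapply(
    function(n, comp) unname(pur[[comp]][[key[[n]]]]),
    fractions$node, fractions$compartment
  )

  mut <- tibble::tribble(
    ~id,          ~gene,     ~effect,          ~zygosity, ~node,
    ~contig, ~pos,       ~ref, ~alt,
    "TET2_m1",    "TET2",    "nonsynonymous",  "het", "ancestral",
    "chr4",  106155100L, "C",  "T",
    "TET2_m2",    "TET2",    "nonsynonymous",  "het", "ancestral",
    "chr4",  106157698L, "G",  "A",
    "DNMT3A_m1",  "DNMT3A",  "nonsynonymous",  "het", "ancestral",
    "chr2",  25457242L,  "C",  "T",
    "TET2_syn",   "TET2",    "synonymous",     "het", "ancestral",
    "chr4",  106164778L, "G",  "A",
    "RHOA_G17V",  "RHOA",    "nonsynonymous",  "het", "T_subclone",
    "chr3",  49412973L,  "C",  "A",
    "IDH2_R172",  "IDH2",    "nonsynonymous",  "het", "T_subclone",
    "chr15", 90631934L,  "C",  "T"
  )
  if (config$include_b_subclone) {
    mut <- dplyr::bind_rows(mut, tibble::tibble(
      id = "NOTCH1_m1", gene = "NOTCH1", effect = "nonsynonymous",
      zygosity = "het", node = "B_subclone",
      contig = "chr9", pos = 139399400L, ref = "G", alt = "A"
    ))
  }

  clone_tree(nodes, fractions, mut)
}

#' Expected variant allele frequency of a mutation in a compartment
#'
#' Standard clonal VAF accounting: the carrying clone's cell fraction in the
#' compartment times the allelic dosage (0.5 for a heterozygous mutation,
#' 1.0 for homozygous).
#'
#' @param tree A [clone_tree()].
#' @param mutation_id Mutation identifier in `tree$mutations`.
#' @param compartment One of [compartments()].
#' @return Expected VAF in `[0, 1]`.
#' @export
expected_vaf <- function(tree, mutation_id, compartment) {
  stopifnot(inherits(tree, "clone_tree"))
  if (!compartment %in% compartments()) {
    stop("unknown compartment: ", compartment, call. = FALSE)
  }
  m <- tree$mutations[tree$mutations$id == mutation_id, ]
  if (nrow(m) != 1) stop("unknown mutation id: ", mutation_id, call. = FALSE)
  f <- tree$fractions$fraction[tree$fractions$node == m$node &
                                 tree$fractions$compartment == compartment]
  dosage <- if (m$zygosity == "hom") 1.0 else 0.5
  unname(f) * dosage
}
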