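---
title: "Inferring clonal architecture from compartment-resolved variant data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring clonal architecture from compartment-resolved variant data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonarch)
```

## The model

Nodal T-cell lymphomas of TFH phenotype develop by multistep, multilineal
mutation acquisition. The generative model `clonarch` both simulates and
infers is a three-node clone tree:

* an **ancestral clone** — a premalignant progenitor carrying
  epigenetic-regulator mutations (TET2/DNMT3A-style) that differentiates
  into both T- and B-lineage descendants, so its mutations appear in the
  tumor compartment *and* in infiltrating B cells (**multilineal**);
* a **T-lineage tumor subclone** nested inside it, acquiring hotspot
  mutations (G17V-RHOA/IDH2-style) after T-lineage commitment
  (**T-specific**);
* optionally a **B-lineage subclone**, an expanded infiltrating B-cell
  clone carrying its own mutations (NOTCH1-style, **B-specific**).

Each clone has a cell fraction in each of the three assayed compartments
(`whole_tumor`, `PD1pos`, `CD20pos`), with two invariants enforced by
`clone_tree()`: a child's fraction never exceeds its parent's, and
sibling subclones never sum beyond the parent. The expected VAF of a
mutation in a compartment is the carrier clone's cell fraction times the
allelic dosage (0.5 heterozygous, 1.0 homozygous); a mutation's *truth
lineage* is fully determined by the lineage of its carrying node.

Inference inverts this model per mutation from amplicon measurements in
the two microdissected compartments:

| detected PD1+ | detected CD20+ | call |
|---|---|---|
| yes | yes | multilineal |
| yes | no  | T_specific |
| no  | yes | B_specific |
| no  | no  | undetected |
| either indeterminate | | indeterminate |

The whole-tumor measurement never influences the call; it only feeds the
PD1+ enrichment ratio (PD1+ VAF / whole-tumor VAF), whose default
"substantial" factor of 1.5 operationalizes a qualitative published
observation and is deliberately exposed as a parameter. An enrichment
failure (ratio near 1, as happens when PD1+ selection cannot purify the
tumor) is reported as a flag, never a call change.

## Parameters and defaults

**Screening cascade** (fixed rule set, `screen_variants()`): VAF > 0.02
strictly; alt reads > 6 *and* total depth > 10 strictly (i.e. ≥ 7 of
≥ 11 — the strict reading of "more than"); ≥ 1 alt read on each strand;
nonsynonymous; not flagged as a known SNP; VAF outside [0.45, 0.55]
inclusive (heterozygous-germline window — discovery had no matched
normals, so near-0.5 VAFs are presumed germline). Rules apply in that
order and a removed site reports the first failure, which makes the
cascade auditable. The SNP/annotation flags are input columns: database
annotation is upstream of this package's scope.

**Detection thresholds** (`detection_thresholds()`): min VAF 0.02, min
alt 5, min depth 100, all exposed. The source study reports compartment
detection qualitatively; these defaults were calibrated once against the
simulator's negative-control property (error-only sites at depth 100 and
error 0.001 must essentially never be "detected") and are not meant to be
tuned per dataset. Depth below `min_depth` yields an explicit
*indeterminate* state rather than a silent "absent": absence of evidence
is not evidence of absence, and published per-case tables likewise mark
unexamined cells as NA.

**Simulator** (`simulation_config()`): discovery depth 200×, validation
(amplicon) depth 1000×, per-base substitution error 0.001 — typical
operating points for targeted capture and amplicon deep sequencing.
Default compartment composition: whole tumor 65% ancestral / 35% T /
15% B; PD1+ 90% / 80% / 0%; CD20+ 50% / 0% / 40%. No quantitative
purities were published (PD1+ selection even failed in some cases), so
these are the package's own choice of a realistic microdissection: strong
but imperfect PD1+ enrichment, complete depletion of tumor cells from the
B-cell compartment. With heterozygous mutations these put every
present-mutation VAF at ≥ 0.15 and every absent-mutation VAF at 0, which
is what makes near-perfect lineage recovery the *expected* outcome at
validation depth — the recovery tests verify calibration, they do not
probe the hard regime. Cohort size defaults to 19 cases (the
microdissected subcohort size), with 12 IgH colonies per case and one
expanded B clone at 2/12 with 72% germline identity in B-subclone cases,
mirroring the published clonality table's scale.

## Count model and numerical choices

Read counts use the simplest model consistent with deep amplicon
counting: total depth ~ Poisson(mean) (floored at 1 so a VAF is always
defined), each read assigned a strand by a fair coin, and each read an
alt read with probability v′ = v(1−e) + (1−v)·e/3 — substitution errors
go to one specific alt base, hence e/3. The strand split is per-read
(alt_fwd ~ Binomial(depth_fwd, v′)) rather than a post-hoc binomial split
of the alt total: the marginals are identical but the per-read form
guarantees `alt_fwd ≤ depth_fwd` by construction. Overdispersion is
deliberately absent (default off): it would widen VAF spread without
changing any detection logic, and the recovery margins are large.

Other numerical choices:

* `percent()` rounds **half-up** to one decimal (6.25 → 6.3), matching
  the published tables; base R's half-even rounding would disagree, so it
  is implemented explicitly with a 10⁻⁹ guard against representation
  error.
* Germline identity uses global alignment (match +1, mismatch −1, linear
  gap −2, via Biostrings) against every reference; identity =
  100 × matches / aligned columns **including gap columns** — a
  conservative denominator, documented because IMGT's computation is not
  reproducible bit-exactly. Ties in best-reference score resolve to the
  first reference. Identity exactly 98.0 is *unmutated* (the cutoff is
  strictly "< 98%").
* Clone grouping keys on exact V/D/J labels plus the junction amino-acid
  string; a missing D segment is its own grouping value. Two identical
  colonies of twelve already constitute an expanded clone
  (`min_clone_size = 2`), since the published clonality table treats 2/12
  as clonal expansion. Monoclonality is established only by the
  direct-sequencing flag (subcloning is "not applicable" then) — after
  subcloning, any expanded clone over a unique background is oligoclonal.
* Degenerate inputs fail fast and loudly: zero total depth has no VAF,
  duplicate compartment measurements and unknown compartments or
  subtypes are input errors, and an empty colony set without the
  direct-monoclonal flag is an error rather than a silent polyclonal.

## The synthetic germline reference

The packaged IGHV reference (`germline_v_set()`) is five synthetic 300-nt
sequences generated once under a fixed seed — *not* IMGT alleles. They
make identity arithmetic exact and self-contained; they do not reproduce
IGHV family structure, allele polymorphism, or CDR/FR mutation hotspot
patterns. The expanded-clone simulator mutates exactly
`round((1 − identity/100) × 300)` positions to a *different* base, so the
realized identity equals the target up to alignment effects (±1 point in
practice).

## What the simulator does and does not emulate

It emulates: nested clone fractions under microdissection, stranded
binomial read sampling with substitution error, error-only and
known-SNP decoy sites for the screening stage, and IgH colony sets with
clonal expansion and tunable somatic hypermutation. It does **not**
emulate alignment artifacts, indel errors, copy-number change, FFPE
damage, contamination between dissected compartments, subclonal
structure beyond three nodes, or receptor-sequence biology
(productive/unproductive rearrangement, junction nucleotides). Passing
recovery tests therefore demonstrate that the inference logic is correct
and well-calibrated *under the stated generative model* — not that the
thresholds are optimal for any particular real assay.

## Reconstructed cohort matrix

The package ships the per-gene, per-subtype mutated-case counts of the
87-case cohort (and its 19-case microdissected subcohort) as plain TSV,
and `reconstruct_cohort_cases()` expands them into a deterministic
per-case matrix: within each subtype the first `n_lmd` cases are the
microdissected ones and each gene's mutations go to the first eligible
cases. Every marginal count — hence every percent cell of the two
frequency tables — is reproduced exactly; the co-occurrence structure
across genes is an artifact of the reconstruction, so only marginal
quantities (frequencies, the recurrent-gene fraction of the 71-gene
panel) should be read off it, never case-level co-mutation patterns.

## Problem sizes

The shipped analyses and checks use: 19-case simulated cohorts (7
mutations × 3 compartments each), lineage recovery over 1000 mutation
instances at 1000× amplicon depth, 10 000 random pileup sites for the
screening-oracle comparison, 1000 error-only sites for the negative
control, and 200 independent colony sets for the IgH round trip. These
sizes give binomial standard errors well below the margins being tested
while keeping any single run in seconds.

## Known limitations

* Threshold behavior near the detection limit is simulator-calibrated;
  the real assay's limit of detection was never published.
* No formal statistical test compares compartment VAFs (none was used in
  the source analysis); the classifier is a threshold rule, so extremely
  unbalanced depths can only be caught by the indeterminate state.
* The enrichment factor (1.5) is interpretive, not estimated.
* `classify_lineages()` assumes at most one measurement per compartment;
  replicate amplicon runs must be merged upstream.
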