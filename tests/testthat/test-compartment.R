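amp_row <- function(compartment, alt, depth, sample = "S1", mut = "m1") {
  tibble::tibble(sample = sample, mutation_id = mut,
                 compartment = compartment, alt_count = alt, depth = depth)
}

test_that("compartment detection applies VAF, alt and depth thresholds", {
  th <- detection_thresholds()
  expect_true(detect_in_compartment(300, 1000, th))
  expect_false(detect_in_compartment(0, 1000, th))
  expect_true(is.na(detect_in_compartment(30, 50, th)))  # depth < 100
  # threshold boundaries: vaf >= min_vaf and alt >= min_alt both required
  expect_false(detect_in_compartment(4, 1000, th))   # alt below min_alt
  expect_false(detect_in_compartment(10, 1000, th))  # vaf 0.01 < 0.02
  expect_true(detect_in_compartment(20, 1000, th))   # vaf 0.02, alt 20
  expect_error(detection_thresholds(min_vaf = -1), "nonnegative")
  expect_error(detect_in_compartment(10, 5), "exceed")
})

test_that("lineage calls map the PD1+/CD20+ detection pattern", {
  th <- detection_thresholds()
  t_spec <- rbind(amp_row("PD1pos", 400, 1000), amp_row("CD20pos", 0, 1000))
  expect_equal(classify_lineage(t_spec, th)$call, "T_specific")
  multi <- rbind(amp_row("PD1pos", 400, 1000), amp_row("CD20pos", 250, 1000))
  expect_equal(classify_lineage(multi, th)$call, "multilineal")
  b_spec <- rbind(amp_row("PD1pos", 0, 1000), amp_row("CD20pos", 300, 1000))
  expect_equal(classify_lineage(b_spec, th)$call, "B_specific")
  none <- rbind(amp_row("PD1pos", 0, 1000), amp_row("CD20pos", 0, 1000))
  expect_equal(classify_lineage(none, th)$call, "undetected")
  shallow <- rbind(amp_row("PD1pos", 30, 50), amp_row("CD20pos", 0, 1000))
  expect_equal(classify_lineage(shallow, th)$call, "indeterminate")
  # a missing required compartment is absence of evidence, not absence
  expect_equal(classify_lineage(amp_row("PD1pos", 400, 1000), th)$call,
               "indeterminate")
  dup <- rbind(amp_row("PD1pos", 1, 1000), amp_row("PD1pos", 2, 1000))
  expect_error(classify_lineage(dup, th), "duplicate")
})

test_that("whole-tumor measurements set enrichment but never the call", {
  th <- detection_thresholds()
  m <- rbind(amp_row("PD1pos", 400, 1000), amp_row("CD20pos", 0, 1000),
             amp_row("whole_tumor", 100, 1000))
  call <- classify_lineage(m, th)
  expect_equal(call$call, "T_specific")
  expect_equal(call$enrichment_ratio, 4.0)
  expect_true(call$enriched)
  # dropping whole_tumor changes only the enrichment fields
  call2 <- classify_lineage(m[m$compartment != "whole_tumor", ], th)
  expect_equal(call2$call, "T_specific")
  expect_true(is.na(call2$enrichment_ratio))
})

test_that("enrichment ratio handles equality and zero whole-tumor VAF", {
  pd1 <- amp_row("PD1pos", 100, 1000)
  whole_eq <- amp_row("whole_tumor", 100, 1000)
  r <- enrichment_ratio(pd1, whole_eq)
  expect_equal(r$ratio, 1.0)
  expect_false(r$enriched)
  whole0 <- amp_row("whole_tumor", 0, 1000)
  r0 <- enrichment_ratio(pd1, whole0)
  expect_true(is.na(r0$ratio))
  other <- amp_row("whole_tumor", 10, 1000, mut = "m2")
  expect_error(enrichment_ratio(pd1, other), "different mutations")
})

test_that("gene aggregation flags a gene by its best mutation", {
  calls <- tibble::tibble(
    sample = "S1",
    mutation_id = c("TET2_a", "TET2_b", "RHOA_a"),
    call = c("multilineal", "T_specific", "T_specific")
  )
  gm <- tibble::tibble(mutation_id = c("TET2_a", "TET2_b", "RHOA_a"),
                       gene = c("TET2", "TET2", "RHOA"))
  agg <- aggregate_sample(calls, gm)
  expect_true(agg$multilineal[agg$gene == "TET2"])
  expect_true(agg$t_specific[agg$gene == "TET2"])
  expect_false(agg$multilineal[agg$gene == "RHOA"])
  expect_true(agg$t_specific[agg$gene == "RHOA"])
  # all-undetected sample: every flag false
  und <- tibble::tibble(sample = "S1", mutation_id = "TET2_a",
                        call = "undetected")
  agg0 <- aggregate_sample(und, gm)
  expect_false(any(agg0$multilineal | agg0$t_specific | agg0$b_specific))
  expect_error(aggregate_sample(
    tibble::tibble(sample = "S1", mutation_id = "x", call = "undetected"),
    gm), "missing from gene map")
})

test_that("swapping compartments mirrors T-specific into B-specific", {
  th <- detection_thresholds()
  for (s in 1:20) {
    alt <- withr::with_seed(s, rbinom(1, 1000, 0.3))
    t_m <- rbind(amp_row("PD1pos", alt, 1000), amp_row("CD20pos", 0, 1000))
    b_m <- rbind(amp_row("PD1pos", 0, 1000), amp_row("CD20pos", alt, 1000))
    ct <- classify_lineage(t_m, th)$call
    cb <- classify_lineage(b_m, th)$call
    expect_equal(ct, "T_specific")
    expect_equal(cb, "B_specific")
  }
})

test_that("raising min_vaf only moves calls toward undetected", {
  rank <- function(det) ifelse(is.na(det), 0L, as.integer(det))
  for (s in 1:30) {
    alt <- withr::with_seed(s, rbinom(1, 1000, runif(1, 0, 0.2)))
    lo <- detect_in_compartment(alt, 1000, detection_thresholds(min_vaf = 0.02))
    hi <- detect_in_compartment(alt, 1000, detection_thresholds(min_vaf = 0.10))
    expect_lte(rank(hi), rank(lo))
  }
})

test_that("classification recovers simulated truth at validation settings", {
  rec <- recovery_experiment(n_mutations = 210, amplicon_depth = 1000,
                             error_rate = 0.001, seed = 7)
  expect_gte(rec$accuracy, 0.99)
  # ancestral mutations never degrade into lineage-specific calls here
  anc <- rec$calls[rec$calls$truth_lineage == "multilineal", ]
  expect_false(any(anc$call %in% c("T_specific", "B_specific")))
})
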