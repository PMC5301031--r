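test_that("default architecture encodes the multistep, multilineal model", {
  tree <- build_default_architecture(simulation_config())
  mut <- tree$mutations
  expect_equal(mut$truth_lineage[mut$id == "RHOA_G17V"], "T_specific")
  expect_equal(mut$truth_lineage[mut$id == "TET2_m1"], "multilineal")
  expect_equal(mut$truth_lineage[mut$id == "NOTCH1_m1"], "B_specific")

  no_b <- build_default_architecture(
    simulation_config(include_b_subclone = FALSE))
  expect_false(any(no_b$mutations$truth_lineage == "B_specific"))
})

test_that("clone tree invariants are enforced", {
  cfg <- simulation_config()
  # child exceeding parent fraction
  bad <- default_purities()
  bad$PD1pos["T"] <- 0.95  # > ancestral 0.90
  expect_error(build_default_architecture(
    simulation_config(compartment_purities = bad)), "exceed")
  # invalid purity map
  expect_error(simulation_config(compartment_purities = list(a = 1)),
               "compartment")
  tree <- build_default_architecture(cfg)
  # sibling subclone fractions never exceed the ancestral fraction
  for (comp in compartments()) {
    f <- tree$fractions[tree$fractions$compartment == comp, ]
    anc <- f$fraction[f$node == "ancestral"]
    expect_lte(sum(f$fraction[f$node != "ancestral"]), anc + 1e-12)
  }
})

test_that("expected VAF is carrier fraction times allelic dosage", {
  cfg <- simulation_config()
  tree <- build_default_architecture(cfg)
  # het mutation: half the carrier fraction
  expect_equal(expected_vaf(tree, "RHOA_G17V", "PD1pos"),
               0.5 * default_purities()$PD1pos[["T"]])
  # equal ancestral fractions give equal VAF in both microdissected
  # compartments when configured so
  pur <- default_purities()
  pur$PD1pos["ancestral"] <- 0.4
  pur$PD1pos["T"] <- 0.3
  pur$CD20pos["ancestral"] <- 0.4
  tree2 <- build_default_architecture(
    simulation_config(compartment_purities = pur))
  expect_equal(expected_vaf(tree2, "TET2_m1", "PD1pos"), 0.2)
  expect_equal(expected_vaf(tree2, "TET2_m1", "CD20pos"), 0.2)
  # zero fraction in a compartment means zero expected VAF everywhere below
  pur0 <- default_purities()
  pur0$CD20pos[] <- 0
  tree0 <- build_default_architecture(
    simulation_config(compartment_purities = pur0))
  for (m in tree0$mutations$id) {
    expect_equal(expected_vaf(tree0, m, "CD20pos"), 0)
  }
  expect_error(expected_vaf(tree, "RHOA_G17V", "CD8pos"), "compartment")
  expect_error(expected_vaf(tree, "nope", "PD1pos"), "mutation")
})

test_that("pileup counts follow the binomial count model", {
  cfg <- simulation_config(error_rate = 0, depth_mean = 10000,
                           n_error_sites = 0, n_snp_sites = 0)
  tree <- build_default_architecture(cfg)
  # TET2_m1 in CD20pos has expected VAF 0.25; over 200 replicates the mean
  # alt count must sit within 3 standard errors of depth * VAF
  alts <- depths <- numeric(200)
  for (i in 1:200) {
    p <- simulate_pileup(tree, cfg, seed = 1000 + i)
    row <- p[p$mutation_id == "TET2_m1" & p$compartment == "CD20pos", ]
    alts[i] <- row$alt_fwd + row$alt_rev
    depths[i] <- row$depth_fwd + row$depth_rev
  }
  v <- 0.25
  se <- sqrt(mean(depths) * v * (1 - v) / 200)
  expect_lt(abs(mean(alts) - mean(depths) * v), 3 * se)
})

test_that("error-free absent sites yield zero alt reads", {
  cfg <- simulation_config(error_rate = 0)
  tree <- build_default_architecture(cfg)
  p <- simulate_pileup(tree, cfg, seed = 7)
  zero <- p[p$true_vaf == 0, ]
  expect_gt(nrow(zero), 0)
  expect_true(all(zero$alt_fwd + zero$alt_rev == 0))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 42L, n_cases = 2)
  expect_identical(simulate_cohort(cfg)$pileup, simulate_cohort(cfg)$pileup)
  tree <- build_default_architecture(cfg)
  expect_identical(simulate_pileup(tree, cfg, seed = 9),
                   simulate_pileup(tree, cfg, seed = 9))
  expect_identical(
    simulate_igh_colonies(12, 2 / 12, 72, seed = 9),
    simulate_igh_colonies(12, 2 / 12, 72, seed = 9)
  )
})

test_that("pileup counts respect per-strand bounds and VAF never exceeds carrier fraction", {
  cfg <- simulation_config(seed = 11L)
  tree <- build_default_architecture(cfg)
  p <- simulate_pileup(tree, cfg, seed = 11)
  expect_true(all(p$alt_fwd <= p$depth_fwd))
  expect_true(all(p$alt_rev <= p$depth_rev))
  frac <- tree$fractions
  for (i in which(!is.na(p$true_vaf) & p$mutation_id %in% tree$mutations$id)) {
    m <- tree$mutations[tree$mutations$id == p$mutation_id[i], ]
    carrier <- frac$fraction[frac$node == m$node &
                               frac$compartment == p$compartment[i]]
    expect_lte(p$true_vaf[i], carrier + 1e-12)
  }
})

test_that("IgH colony simulator produces the configured clonal structure", {
  germ <- germline_v_set()
  col <- simulate_igh_colonies(12, 2 / 12, 72, seed = 21, germline = germ)
  expect_equal(nrow(col), 12)
  key <- paste(col$v_gene, col$d_gene, col$j_gene, col$junction_aa)
  expect_equal(sum(table(key) >= 2), 1)  # exactly one expanded group

  # target identity 100 leaves the V segment identical to germline
  col100 <- simulate_igh_colonies(6, 3 / 6, 100, seed = 3, germline = germ)
  clone <- col100[!is.na(col100$clone_id), ]
  expect_true(clone$v_sequence[1] %in% as.character(germ))

  # empty clone fractions: fully polyclonal, all junctions distinct
  poly <- simulate_igh_colonies(12, numeric(0), seed = 5, germline = germ)
  expect_equal(anyDuplicated(poly$junction_aa), 0L)

  expect_error(simulate_igh_colonies(12, 2 / 12, target_identity = 0),
               "target_identity")
  expect_error(simulate_igh_colonies(12, c(0.9, 0.5)), "sum")
})
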