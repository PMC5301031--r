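test_that("germline identity scores exact, mismatched and gapped queries", {
  germ <- germline_v_set()
  ref_name <- names(germ)[2]
  ref_seq <- as.character(germ[[2]])

  exact <- germline_identity(ref_seq, germ)
  expect_equal(exact$identity, 100.0)
  expect_equal(exact$best_ref, ref_name)

  # one mismatch in 300 gap-free columns
  s <- strsplit(ref_seq, "")[[1]]
  s[10] <- setdiff(c("A", "C", "G", "T"), s[10])[1]
  one_mm <- paste(s, collapse = "")
  expect_equal(germline_identity(one_mm, germ)$identity,
               hamming_identity(one_mm, ref_seq))

  # 3-nt deletion: gap columns count in the denominator
  del <- paste0(substr(ref_seq, 1, 100), substr(ref_seq, 104, 300))
  expect_equal(germline_identity(del, germ)$identity, 99.0)

  expect_error(germline_identity(ref_seq, Biostrings::DNAStringSet()),
               "empty")
  expect_error(germline_identity("", germ), "empty query")
})

test_that("heavily hypermutated V segments score near the target identity", {
  germ <- germline_v_set()
  ref_seq <- as.character(germ[[3]])
  q <- withr::with_seed(13, {
    s <- strsplit(ref_seq, "")[[1]]
    pos <- sample(300, 84)  # 28% of positions to a different base
    s[pos] <- vapply(s[pos],
                     function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
    paste(s, collapse = "")
  })
  # independent column-count oracle on the gap-free construction
  expect_equal(hamming_identity(q, ref_seq), 72.0)
  got <- germline_identity(q, germ)$identity
  expect_lt(abs(got - 72), 2)
})

test_that("hypermutation status is strict at the 98 percent boundary", {
  expect_equal(call_mutation_status(72.2), "mutated")
  expect_equal(call_mutation_status(97.9), "mutated")
  expect_equal(call_mutation_status(98.0), "unmutated")
  expect_equal(call_mutation_status(100.0), "unmutated")
  expect_error(call_mutation_status(101), "identity")
  # any gap-free query with > 2% mismatches must come out mutated
  germ <- germline_v_set()
  ref_seq <- as.character(germ[[1]])
  s <- strsplit(ref_seq, "")[[1]]
  pos <- 1:7  # 7/300 = 2.3% mismatches
  s[pos] <- vapply(s[pos],
                   function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                   character(1))
  id <- germline_identity(paste(s, collapse = ""), germ)$identity
  expect_equal(call_mutation_status(id), "mutated")
})

test_that("clone grouping is an exact partition by VDJ key", {
  col <- simulate_igh_colonies(12, 2 / 12, 72, seed = 31)
  clones <- group_clones(col)
  expect_equal(nrow(clones), 1)
  expect_equal(clones$size, 2)
  expect_setequal(clones$members[[1]],
                  col$colony_id[!is.na(col$clone_id)])

  two <- simulate_igh_colonies(12, c(2 / 12, 2 / 12), 72, seed = 32)
  expect_equal(nrow(group_clones(two)), 2)

  poly <- simulate_igh_colonies(12, numeric(0), seed = 33)
  expect_equal(nrow(group_clones(poly)), 0)

  # every colony belongs to exactly one group; sizes sum to colony count
  key <- paste(col$v_gene, col$d_gene, col$j_gene, col$junction_aa)
  expect_equal(sum(table(key)), nrow(col))
  expect_error(group_clones(col, min_clone_size = 1), "at least 2")
})

test_that("missing D segments group as their own value", {
  col <- tibble::tibble(
    sample = "S1", colony_id = c("c1", "c2", "c3"),
    v_gene = "V1-2", d_gene = c(NA, NA, "D2-2"), j_gene = "J1",
    junction_aa = "CARW", v_sequence = "ACGT"
  )
  clones <- group_clones(col)
  expect_equal(nrow(clones), 1)
  expect_equal(clones$size, 2)
  expect_true(is.na(clones$d_gene))
})

test_that("clonality calls follow direct sequencing then colony expansion", {
  germ <- germline_v_set()
  # direct sequencing already monoclonal: subcloning not applicable
  mono <- call_clonality(tibble::tibble(), direct_sequence_monoclonal = TRUE)
  expect_equal(mono$call, "monoclonal")

  oligo <- call_clonality(simulate_igh_colonies(12, 2 / 12, 72, seed = 41),
                          germline_refs = germ)
  expect_equal(oligo$call, "oligoclonal")
  expect_equal(oligo$clones$mutation_status[1], "mutated")
  expect_lt(oligo$clones$identity[1], 98)

  poly <- call_clonality(simulate_igh_colonies(12, numeric(0), seed = 42))
  expect_equal(poly$call, "polyclonal")

  expect_error(call_clonality(tibble::tibble()), "nothing to call")
})

test_that("simulate-and-call round trip recovers oligoclonality", {
  rt <- igh_roundtrip_experiment(n_seeds = 30, seed = 100)
  expect_gte(rt$oligoclonal_rate, 0.95)
  expect_true(all(rt$identities < 98, na.rm = TRUE))
})
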