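# Shared fixtures: random pileup generators, the independent brute-force
# screening oracle, and a direct column-count identity for gap-free
# alignments.

random_pileup_sites <- function(n, seed = 1) {
  withr::with_seed(seed, {
    depth_fwd <- sample(0:120, n, replace = TRUE)
    depth_rev <- sample(0:120, n, replace = TRUE)
    # keep total depth >= 1 so the VAF is defined
    depth_fwd[depth_fwd + depth_rev == 0] <- 1L
    # mix of low, boundary-scale and high alt counts
    alt_fwd <- pmin(depth_fwd, sample(0:15, n, replace = TRUE))
    alt_rev <- pmin(depth_rev, sample(0:15, n, replace = TRUE))
    # sprinkle in germline-like VAFs
    het <- sample(n, max(1, n %/% 10))
    alt_fwd[het] <- round(depth_fwd[het] / 2)
    alt_rev[het] <- round(depth_rev[het] / 2)
    tibble::tibble(
      sample = "S", contig = "chr1", pos = seq_len(n), ref = "A", alt = "T",
      alt_fwd = alt_fwd, alt_rev = alt_rev,
      depth_fwd = depth_fwd, depth_rev = depth_rev,
      effect = sample(c("nonsynonymous", "synonymous"), n, replace = TRUE,
                      prob = c(0.8, 0.2)),
      known_snp = sample(c(FALSE, TRUE), n, replace = TRUE,
                         prob = c(0.85, 0.15))
    )
  })
}

# one-expression brute-force filter: a site is retained iff all six rules
# hold simultaneously
oracle_retained <- function(sites) {
  with(sites, {
    vaf <- (alt_fwd + alt_rev) / (depth_fwd + depth_rev)
    vaf > 0.02 &
      (alt_fwd + alt_rev) > 6 & (depth_fwd + depth_rev) > 10 &
      alt_fwd >= 1 & alt_rev >= 1 &
      effect != "synonymous" & !known_snp &
      !(vaf >= 0.45 & vaf <= 0.55)
  })
}

# identity of two equal-length gap-free sequences by direct column counts
hamming_identity <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  stopifnot(length(a) == length(b))
  round(100 * mean(a == b), 1)
}

# a pileup site built from explicit counts, clean on every other rule
boundary_site <- function(alt_fwd, alt_rev, depth_fwd, depth_rev,
                          effect = "nonsynonymous", known_snp = FALSE) {
  tibble::tibble(alt_fwd = alt_fwd, alt_rev = alt_rev,
                 depth_fwd = depth_fwd, depth_rev = depth_rev,
                 effect = effect, known_snp = known_snp)
}
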