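test_that("base content and skew compute the defining ratios", {
  bc <- base_content("ATAT")
  expect_equal(unname(bc[c("A", "T")]), c(50, 50))
  expect_equal(attr(bc, "AT"), 100)
  expect_equal(unname(base_content("ACGT")), rep(25, 4), ignore_attr = TRUE)
  expect_equal(sum(base_content("ACGTNNN")), 100)  # N excluded
  expect_error(base_content("NNN"), "no unambiguous")
  expect_error(base_content(""), "non-empty")

  expect_equal(skew("AAAT")$at_skew, 0.5)
  expect_equal(skew("GGC")$gc_skew, 1 / 3)
  s <- skew("AAAA")
  expect_true(is.na(s$gc_skew))
  expect_equal(s$at_skew, 1)
})

test_that("skew is antisymmetric under reverse complement", {
  set.seed(11)
  for (i in 1:200) {
    x <- random_dna(sample(10:80, 1), prob = c(0.4, 0.1, 0.15, 0.35))
    s1 <- skew(x)
    s2 <- skew(revcomp(x))
    expect_equal(s2$at_skew, -s1$at_skew)
    expect_equal(s2$gc_skew, -s1$gc_skew)
  }
})

test_that("strand-set skew reads gene sets off the major strand", {
  # a record that is 'AT' repeated everywhere has zero skew for every basis
  s <- strrep("AT", 100)
  feats <- data.frame(name = PCG_names <- c("ND2", "ND3", "ND6", "COI", "COII",
                                            "COIII", "ATP6", "ATP8", "CytB",
                                            "ND1", "ND4", "ND4L", "ND5"),
                      ftype = "PCG",
                      strand = c(rep("major", 9), rep("minor", 4)),
                      start = seq(1, by = 15, length.out = 13),
                      end = seq(12, by = 15, length.out = 13),
                      stringsAsFactors = FALSE)
  rec <- suppressWarnings(mitogenome("flat", 200, feats, sequence = s,
                                     check_canonical = FALSE))
  for (basis in c("whole_genome", "all_PCG", "major_PCG", "minor_PCG")) {
    expect_equal(strand_set_skew(rec, basis)$at_skew, 0)
  }
  # missing basis gene is named in the error
  rec2 <- suppressWarnings(mitogenome("flat2", 200,
                                      feats[feats$name != "ND3", ],
                                      sequence = s, check_canonical = FALSE))
  expect_error(strand_set_skew(rec2, "major_PCG"), "ND3")
  # minor-strand gene sets are NOT reverse complemented: planted T-rich
  # minor spans show up as strongly negative AT skew
  sim <- simulate_mitogenome(sim_config(seed = 5, minor_at_skew = -0.5))
  expect_lt(strand_set_skew(sim$record, "minor_PCG")$at_skew, -0.4)
  expect_gt(strand_set_skew(sim$record, "major_PCG")$at_skew, 0.15)
})

test_that("codon usage applies the stop-exclusion counting convention", {
  rec <- suppressWarnings(mitogenome("one", 12,
    data.frame(name = "ND2", ftype = "PCG", strand = "major",
               start = 1L, end = 12L, stop_codon = "TAA",
               stringsAsFactors = FALSE),
    sequence = "TTATTATTATAA", check_canonical = FALSE))
  cu <- codon_usage(rec)
  expect_equal(unname(cu$counts["TTA"]), 3L)
  expect_equal(cu$total_codons, 3L)
  expect_equal(unname(cu$frequencies["TTA"]), 100)
  expect_equal(sum(cu$frequencies), 100, tolerance = 1e-9)
})

test_that("codon totals from coordinates match the sequence-level count", {
  # the convention (complete codons, minus a complete terminal stop, nothing
  # from a truncated stop) reproduces the published totals from coordinates
  expect_equal(expected_codon_total(example_mitogenome("Smarginella")), 3637L)
  expect_equal(expected_codon_total(example_mitogenome("Mpruinosa_H1")), 3657L)
  expect_equal(expected_codon_total(example_mitogenome("Mpruinosa_H3")), 3657L)
  # and agrees with the per-sequence count on a synthetic genome
  sim <- simulate_mitogenome(sim_config(seed = 31))
  cu <- codon_usage(sim$record)
  expect_equal(cu$total_codons, expected_codon_total(sim$record))
})

test_that("codon frequencies are invariant under genome rotation", {
  sim <- simulate_mitogenome(sim_config(seed = 13))
  cu <- codon_usage(sim$record)
  off <- valid_offsets(sim$record)
  rot <- rotate_mitogenome(sim$record, off[length(off) %/% 2])
  cu2 <- codon_usage(rot)
  expect_equal(cu2$counts, cu$counts)
  expect_equal(cu2$frequencies, cu$frequencies)
})

test_that("top-4 codon share of uniform-random codons is near 4/64", {
  set.seed(23)
  # uniform codons over all 64: expected share of any fixed four is 6.25%
  n <- 40000L
  codons <- paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                   sample(c("A", "C", "G", "T"), n, TRUE),
                   sample(c("A", "C", "G", "T"), n, TRUE))
  share <- 100 * mean(codons %in% c("TTA", "ATT", "TTT", "ATA"))
  expect_equal(share, 6.25, tolerance = 0.1)
})

test_that("start/stop table reports truncated stops and flags odd starts", {
  sim <- simulate_mitogenome(sim_config(seed = 17,
                                        start_codons = c(COI = "CTG")))
  st <- start_stop_table(sim$record)
  expect_equal(st$stop_codon[st$gene == "ATP6"], "T")
  expect_equal(st$start_codon[st$gene == "COI"], "CTG")
  expect_false(st$canonical_start[st$gene == "COI"])
  expect_true(st$canonical_start[st$gene == "ND5"])  # GTG counts as canonical
  expect_true(all(st$canonical_start[st$gene != "COI"]))

  rec <- suppressWarnings(mitogenome("tiny", 9,
    data.frame(name = "ND2", ftype = "PCG", strand = "major",
               start = 1L, end = 9L, stringsAsFactors = FALSE),
    sequence = "ATGAAATAA", check_canonical = FALSE))
  st2 <- start_stop_table(rec)
  expect_equal(st2$start_codon, "ATG")
  expect_equal(st2$stop_codon, "TAA")
})

test_that("per-gene composition report covers every feature", {
  sim <- simulate_mitogenome(sim_config(seed = 19))
  rep <- composition_report(sim$record)
  expect_equal(nrow(rep), nrow(sim$record$features))
  expect_true(all(abs(rowSums(rep[, c("A", "C", "G", "T")]) - 100) < 1e-9))
  expect_true(all(abs(rep$AT - (rep$A + rep$T)) < 1e-9))
})
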