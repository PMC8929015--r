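test_that("configs validate and reject infeasible targets", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, at_content = 0.99, at_skew = -0.9),
               "infeasible")
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$gene_order_type, "A")
})

test_that("generator output is deterministic and passes validation", {
  cfg <- sim_config(seed = 123)
  s1 <- simulate_mitogenome(cfg)
  s2 <- simulate_mitogenome(cfg)
  expect_identical(s1$record$sequence, s2$record$sequence)
  expect_identical(s1$record$features, s2$record$features)
  expect_identical(s1$truth$repeats, s2$truth$repeats)
  # a different seed gives a different genome
  s3 <- simulate_mitogenome(sim_config(seed = 124))
  expect_false(identical(s1$record$sequence, s3$record$sequence))
  # the record validates as a canonical 37+1 genome with no warnings
  expect_no_warning(
    mitogenome(s1$record$record_id, s1$record$genome_length,
               s1$record$features, sequence = s1$record$sequence))
  # every PCG is an open reading frame under table 5
  gc5 <- Biostrings::getGeneticCode("5")
  for (g in mitocomp:::PCG_NAMES) {
    cds <- extract_gene_sequence(s1$record, g)
    r <- nchar(cds) %% 3
    cds <- substr(cds, 1, nchar(cds) - r)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                             genetic.code = gc5))
    interior <- substr(aa, 1, nchar(aa) - 1)
    expect_false(grepl("\\*", interior))
    if (r == 0) expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  }
})

test_that("composition sampling hits AT and skew targets", {
  for (sd in c(201, 202)) {
    cfg <- sim_config(seed = sd, genome_length = 15000,
                      at_content = 0.75, at_skew = 0.2, gc_skew = -0.25)
    sim <- simulate_mitogenome(cfg)
    bc <- base_content(sim$record$sequence)
    sk <- skew(sim$record$sequence)
    expect_lt(abs(attr(bc, "AT") / 100 - 0.75), 0.02)
    expect_lt(abs(sk$at_skew - 0.2), 0.02)
    expect_lt(abs(sk$gc_skew - (-0.25)), 0.02)
  }
})

test_that("truth-table coordinates locate the planted features exactly", {
  sim <- simulate_mitogenome(sim_config(seed = 301))
  tr <- sim$truth
  # motif truth
  m <- substr(sim$record$sequence, tr$motif$position, tr$motif$position + 4L)
  expect_equal(m, tr$motif$sequence)
  expect_equal(tr$motif$mismatches, 0L)
  # repeat truth: the planted unit tiles the recorded span
  ctrl <- substr(sim$record$sequence, tr$control_region$start,
                 tr$control_region$end)
  for (k in seq_len(nrow(tr$repeats))) {
    span <- substr(ctrl, tr$repeats$start[k], tr$repeats$end[k])
    u <- tr$repeats$unit[k]
    expect_equal(substr(span, 1, nchar(u)), u)
    expect_equal(substr(span, nchar(u) + 1, 2 * nchar(u)), u)
  }
  # feature table in the truth equals the record's annotation
  expect_identical(tr$features, sim$record$features)
})

test_that("cds pair simulation honours its degenerate contracts", {
  p0 <- simulate_cds_pair(100, omega = 0.5, t = 0, seed = 1)
  expect_identical(p0$cds1, p0$cds2)
  # omega = 0: every accepted change is synonymous, so the two proteins are
  # identical; NG86 pathway averaging through multi-hit codons can still
  # attribute a small fractional Nd, so downstream Ka is near (not exactly) 0
  p1 <- simulate_cds_pair(200, omega = 0, t = 0.3, seed = 2)
  expect_equal(p1$nonsyn_events, 0L)
  gc5 <- Biostrings::getGeneticCode("5")
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), genetic.code = gc5, no.init.codon = TRUE))
  expect_identical(tr(p1$cds1), tr(p1$cds2))
  k <- pairwise_kaks(p1$cds1, p1$cds2)
  expect_lte(k$Ka, 0.01)
  expect_gt(k$Ks, 0)
  expect_lt(k$Ka / k$Ks, 0.05)
  # determinism
  expect_identical(simulate_cds_pair(100, 0.2, 0.2, seed = 3),
                   simulate_cds_pair(100, 0.2, 0.2, seed = 3))
})

test_that("population simulation plants the requested substitution load", {
  sim <- simulate_mitogenome(sim_config(seed = 401))
  # all-zero rates: identical copies
  pop0 <- simulate_population(sim$record, c(COI = 0), n = 3, seed = 1)
  for (r in pop0$records) expect_identical(r$sequence, sim$record$sequence)
  # a 1% rate on one gene: pairwise p-distance near 2% between two copies
  pop <- simulate_population(sim$record, c(COI = 0.01), n = 40, seed = 2)
  d <- vapply(seq(1, 39, by = 2), function(i) {
    p_distance(extract_gene_sequence(pop$records[[i]], "COI"),
               extract_gene_sequence(pop$records[[i + 1]], "COI"))
  }, numeric(1))
  # expectation: 2 * 0.01 * (1 - overlap correction) ~ 1.99%
  expect_lt(abs(mean(d) - 2), 0.35)
  # truth table records the planted counts
  expect_equal(nrow(pop$truth), 40L)
  expect_error(simulate_population(sim$record, c(nope = 0.1), 2, 1),
               "unknown gene")
})

test_that("configs round-trip through the flat key=value format", {
  cfg <- sim_config(seed = 7, genome_length = 15500, gene_order_type = "C",
                    at_content = 0.7, at_skew = 0.1, gc_skew = -0.2,
                    minor_at_skew = -0.4,
                    motif = list(upstream = "ND1", downstream = "trnS2",
                                 motif = "TAGTA", mismatches = 1L,
                                 placement = "spanning"))
  tmp <- withr::local_tempfile(fileext = ".cfg")
  write_sim_config(cfg, tmp)
  back <- read_sim_config(tmp)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$gene_order_type, "C")
  expect_equal(back$minor_at_skew, -0.4)
  expect_equal(back$motif, cfg$motif)
  expect_equal(vapply(back$repeats, `[[`, numeric(1), "copies"),
               vapply(cfg$repeats, `[[`, numeric(1), "copies"))
  expect_equal(vapply(back$repeats, `[[`, integer(1), "unit_length"),
               vapply(cfg$repeats, function(r) as.integer(r$unit_length),
                      integer(1)))
  # simulating from the round-tripped config is identical
  expect_identical(simulate_mitogenome(cfg)$record$sequence,
                   simulate_mitogenome(back)$record$sequence)
})
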