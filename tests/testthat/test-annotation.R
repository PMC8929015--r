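test_that("packaged coordinate tables load and validate", {
  h1 <- example_mitogenome("Mpruinosa_H1")
  h3 <- example_mitogenome("Mpruinosa_H3")
  sm <- example_mitogenome("Smarginella")
  expect_equal(h1$genome_length, 16312L)
  expect_equal(h3$genome_length, 16314L)
  expect_equal(sm$genome_length, 16126L)
  for (rec in list(h1, h3, sm)) {
    expect_equal(nrow(rec$features), 38L)
    expect_equal(sum(rec$features$ftype == "PCG"), 13L)
    expect_equal(sum(rec$features$ftype == "tRNA"), 22L)
    expect_equal(sum(rec$features$ftype == "rRNA"), 2L)
    expect_equal(sum(rec$features$ftype == "control"), 1L)
    expect_setequal(rec$features$name, canonical_gene_set())
  }
  # spot-checked published sizes; trnY abuts COI in S. marginella exactly as
  # the source table prints it (1296-1356 = 61 bp)
  expect_equal(unname(feature_lengths(h1)[c("trnI", "ATP6", "lrRNA", "AT_rich")]),
               c(65L, 652L, 1226L, 1788L))
  expect_equal(unname(feature_lengths(sm)[c("trnY", "ND5", "AT_rich")]),
               c(61L, 1680L, 1836L))
  # known 1-bp inconsistency in the source table: S. marginella lrRNA is
  # printed as 1205 bp but its coordinates 12294-13497 span 1204; the
  # coordinates are authoritative here
  expect_equal(unname(feature_lengths(sm)["lrRNA"]), 1204L)
})

test_that("feature tables round-trip field for field", {
  h1 <- example_mitogenome("Mpruinosa_H1")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(h1, tmp)
  back <- read_feature_table(tmp)
  expect_equal(back$genome_length, h1$genome_length)
  expect_equal(back$record_id, h1$record_id)
  expect_equal(back$features, h1$features)
})

test_that("feature-table validation catches malformed input", {
  tab <- c("#genome_length=100",
           "name\tftype\tstrand\tstart\tend\tanticodon\tstart_codon\tstop_codon",
           "trnI\ttRNA\tmajor\t1\t65\tGAT\t\t")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(tab, tmp)
  rec <- suppressWarnings(read_feature_table(tmp))
  expect_equal(nrow(rec$features), 1L)
  expect_equal(unname(feature_lengths(rec)), 65L)

  writeLines(c(tab, "trnI\ttRNA\tmajor\t70\t90\tGAT\t\t"), tmp)
  expect_error(suppressWarnings(read_feature_table(tmp)), "duplicate")

  writeLines(c(tab[1:2], "trnI\ttRNA\tmajor\t65\t1\tGAT\t\t"), tmp)
  expect_error(suppressWarnings(read_feature_table(tmp)), "start > end")

  writeLines(c(tab[1:2], "trnI\ttRNA\tmajor\t50\t120\tGAT\t\t"), tmp)
  expect_error(suppressWarnings(read_feature_table(tmp)), "outside")

  # FASTA length disagreement
  writeLines(tab, tmp)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", strrep("A", 99)), fa)
  expect_error(suppressWarnings(read_feature_table(tmp, fasta = fa)),
               "does not match")
})

test_that("GenBank flat files parse with strand, join and label normalization", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb_fixture_text(), gb)
  rec <- suppressWarnings(read_genbank(gb))
  expect_equal(rec$genome_length, 400L)
  expect_true(rec$circular)
  expect_equal(rec$organism, "Synthetica testis")
  f <- rec$features
  expect_setequal(f$name, c("ND2", "ATP8", "trnQ", "srRNA", "AT_rich"))
  expect_equal(f$strand[f$name == "trnQ"], "minor")
  expect_equal(f[f$name == "trnQ", c("start", "end")],
               data.frame(start = 120L, end = 185L),
               ignore_attr = TRUE)
  expect_equal(f$strand[f$name == "ND2"], "major")
  expect_equal(f$ftype[f$name == "AT_rich"], "control")
  expect_equal(nchar(rec$sequence), 400L)

  # empty FEATURES block: zero features and a warning
  empty <- c("LOCUS       EMPTY                    10 bp    DNA     circular INV 01-JAN-2024",
             "FEATURES             Location/Qualifiers",
             "ORIGIN",
             "        1 acgtacgtac",
             "//")
  writeLines(empty, gb)
  expect_warning(rec2 <- read_genbank(gb), "no features")
  expect_equal(nrow(rec2$features), 0L)

  # malformed location names the line
  bad <- gb_fixture_text()
  bad[8] <- "     CDS             10..&!"
  writeLines(bad, gb)
  expect_error(suppressWarnings(read_genbank(gb)), "line 8")

  # feature beyond sequence length
  bad <- gb_fixture_text()
  bad[8] <- "     CDS             10..480"
  writeLines(bad, gb)
  expect_error(suppressWarnings(read_genbank(gb)), "beyond")
})

test_that("gene-label normalization maps deposited label variants", {
  expect_equal(
    suppressMessages(normalize_gene_name(
      c("COX1", "cob", "NAD4L", "s-rRNA", "16S ribosomal RNA",
        "trnL(taa)", "trnL(tag)", "trnS(gct)", "tRNA-Trp", "D-loop",
        "mystery"))),
    c("COI", "CytB", "ND4L", "srRNA", "lrRNA",
      "trnL2", "trnL1", "trnS1", "trnW", "AT_rich", "mystery"))
})

test_that("extract_gene_sequence honours reading orientation", {
  rec <- suppressWarnings(mitogenome("t", 5,
    data.frame(name = "g1", ftype = "tRNA", strand = "major",
               start = 1L, end = 3L, stringsAsFactors = FALSE),
    sequence = "ATGCC", check_canonical = FALSE))
  expect_equal(extract_gene_sequence(rec, "g1"), "ATG")
  rec2 <- suppressWarnings(mitogenome("t", 5,
    data.frame(name = "g1", ftype = "tRNA", strand = "minor",
               start = 1L, end = 3L, stringsAsFactors = FALSE),
    sequence = "ATGCC", check_canonical = FALSE))
  expect_equal(extract_gene_sequence(rec2, "g1"), "CAT")
  expect_error(extract_gene_sequence(rec, "nope"), "unknown gene")
  # major-strand extract then reverse complement equals minor-strand extract
  set.seed(7)
  s <- random_dna(60)
  mk <- function(strand) suppressWarnings(mitogenome("t", 60,
    data.frame(name = "g", ftype = "rRNA", strand = strand,
               start = 11L, end = 40L, stringsAsFactors = FALSE),
    sequence = s, check_canonical = FALSE))
  expect_equal(revcomp(extract_gene_sequence(mk("major"), "g")),
               extract_gene_sequence(mk("minor"), "g"))
})

test_that("a planted GTG start codon survives extraction", {
  sim <- simulate_mitogenome(sim_config(seed = 21))
  nd5 <- extract_gene_sequence(sim$record, "ND5")
  expect_equal(substr(nd5, 1, 3), "GTG")
})

test_that("rotation refuses cuts inside features and round-trips", {
  h1 <- example_mitogenome("Mpruinosa_H1")
  expect_error(rotate_mitogenome(h1, 100), "inside feature")
  rot <- rotate_mitogenome(h1, 5970)  # inside the trnR/trnN spacer
  expect_equal(rot$genome_length, h1$genome_length)
  expect_equal(nrow(rot$features), 38L)
  back <- rotate_mitogenome(rot, h1$genome_length - 5970)
  expect_equal(back$features[order(back$features$name), ],
               h1$features[order(h1$features$name), ],
               ignore_attr = TRUE)
})
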