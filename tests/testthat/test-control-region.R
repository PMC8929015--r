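test_that("verbatim arrays are recovered with exact unit and copy number", {
  set.seed(61)
  unit <- random_dna(21)
  # pure construction: the pasted array is the whole sequence
  arr <- find_tandem_repeats(strrep(unit, 20))
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$unit_length, 21L)
  expect_equal(arr$copies, 20)
  expect_equal(arr$identity, 1)
  expect_equal(arr$consensus, unit)
  expect_false(arr$truncated_final)
  expect_equal(arr$start, 1L)
  expect_equal(arr$end, 420L)
  # with random flanks the boundaries stay within half a unit (chance
  # matches adjacent to a true array are indistinguishable from it)
  seq <- paste0(random_dna(150), strrep(unit, 20), random_dna(150))
  arr2 <- find_tandem_repeats(seq)
  arr2 <- arr2[arr2$unit_length == 21L, ]
  expect_equal(nrow(arr2), 1L)
  expect_lte(abs(arr2$copies - 20), 0.5)
  expect_lte(abs(arr2$start - 151L), 10L)
  expect_lte(abs(arr2$end - (150L + 21L * 20L)), 10L)
})

test_that("fractional final copies are reported to one decimal", {
  set.seed(62)
  unit <- random_dna(30)
  arr <- find_tandem_repeats(paste0(strrep(unit, 2), substr(unit, 1, 15)))
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$unit_length, 30L)
  expect_equal(arr$copies, 2.5)
  expect_true(arr$truncated_final)
})

test_that("a two-part triplication with truncated final unit is one array", {
  set.seed(63)
  a <- random_dna(30)
  b <- random_dna(30)
  # A+B pasted 3x, but the third copy lacks B: unit AB x 2.5
  arr <- find_tandem_repeats(paste0(a, b, a, b, a))
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$unit_length, 60L)
  expect_equal(arr$copies, 2.5)
  expect_true(arr$truncated_final)
})

test_that("finder agrees with the brute-force oracle", {
  set.seed(64)
  # random sequences (usually empty) and planted cases
  for (i in 1:12) {
    s <- random_dna(1000)
    got <- find_tandem_repeats(s)
    want <- oracle_tandem(s)
    expect_equal(got[, c("start", "end", "unit_length")], want,
                 ignore_attr = TRUE)
  }
  for (i in 1:8) {
    u <- random_dna(sample(12:40, 1))
    s <- paste0(random_dna(200), strrep(u, sample(3:8, 1)), random_dna(200))
    got <- find_tandem_repeats(s)
    want <- oracle_tandem(s)
    expect_equal(got[, c("start", "end", "unit_length")], want,
                 ignore_attr = TRUE)
  }
})

test_that("planted arrays are recovered across many random plantings", {
  set.seed(65)
  ok_unit <- 0L
  for (i in 1:100) {
    p <- sample(12:60, 1)
    copies <- sample(seq(2, 8, by = 0.5), 1)
    u <- random_dna(p)
    full <- floor(copies)
    arr_seq <- paste0(strrep(u, full), substr(u, 1, round((copies - full) * p)))
    lead <- sample(50:300, 1)
    s <- paste0(random_dna(lead), arr_seq, random_dna(sample(50:300, 1)))
    arr <- find_tandem_repeats(s)
    hit <- arr[arr$unit_length == p, , drop = FALSE]
    if (nrow(hit) == 1L &&
        abs(hit$copies - copies) <= 0.5 &&
        abs(hit$start - (lead + 1)) <= p / 2 &&
        abs(hit$end - (lead + nchar(arr_seq))) <= p / 2) {
      ok_unit <- ok_unit + 1L
    }
  }
  expect_gte(ok_unit, 95L)
})

test_that("finder output mirrors under sequence reversal", {
  set.seed(66)
  u <- random_dna(25)
  s <- paste0(random_dna(80), strrep(u, 5), random_dna(80))
  fwd <- find_tandem_repeats(s)
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  bwd <- find_tandem_repeats(rev_s)
  expect_equal(nrow(bwd), nrow(fwd))
  n <- nchar(s)
  expect_equal(sort(n - fwd$end + 1L), sort(bwd$start))
  expect_equal(bwd$unit_length, fwd$unit_length)
})

test_that("control-region architecture tiles the region and tracks AT content", {
  cfg <- sim_config(seed = 71)
  sim <- simulate_mitogenome(cfg)
  arch <- region_architecture(sim$record)
  segs <- arch$segments
  # four regions: repeat / nonrepeat / repeat / nonrepeat
  expect_equal(segs$label, c("repeat", "nonrepeat", "repeat", "nonrepeat"))
  # exact tiling
  expect_equal(segs$start[1], 1L)
  expect_equal(segs$end[nrow(segs)], arch$region_length)
  expect_true(all(segs$start[-1] == segs$end[-nrow(segs)] + 1L))
  expect_equal(sum(segs$length), arch$region_length)
  # detected arrays line up with the planted ones
  tr <- sim$truth$repeats
  expect_equal(arch$repeats$unit_length, tr$unit_length)
  expect_true(all(abs(arch$repeats$copies - tr$copies) <= 0.5))
  expect_true(all(abs(arch$repeats$start - tr$start) <= tr$unit_length / 2))
  # per-segment AT within 1 point of the planted sequences' own content
  ctrl <- substr(sim$record$sequence, sim$truth$control_region$start,
                 sim$truth$control_region$end)
  for (k in seq_len(nrow(tr))) {
    planted_at <- attr(base_content(substr(ctrl, tr$start[k], tr$end[k])), "AT")
    seg_at <- segs$AT[segs$label == "repeat"][k]
    expect_lt(abs(seg_at - planted_at), 1)
  }
  # repeat units are markedly less A+T rich than the nonrepeat core
  expect_lt(max(segs$AT[segs$label == "repeat"]),
            min(segs$AT[segs$label == "nonrepeat"]))
  # poly-runs include the planted 23 bp poly-A
  expect_true(any(arch$polyruns$pattern == "A" & arch$polyruns$length >= 23L))
})

test_that("a repeat-free region is a single nonrepeat segment", {
  set.seed(72)
  feats <- data.frame(name = c("g1", "AT_rich"),
                      ftype = c("tRNA", "control"), strand = "major",
                      start = c(1L, 101L), end = c(100L, 1100L),
                      stringsAsFactors = FALSE)
  rec <- suppressWarnings(mitogenome("nr", 1100, feats,
                                     sequence = random_dna(1100),
                                     check_canonical = FALSE))
  arch <- region_architecture(rec)
  expect_equal(arch$segments$label, "nonrepeat")
  expect_equal(arch$segments$length, 1000L)
  expect_error(region_architecture(suppressWarnings(
    mitogenome("noc", 100,
               data.frame(name = "g1", ftype = "tRNA", strand = "major",
                          start = 1L, end = 50L, stringsAsFactors = FALSE),
               sequence = random_dna(100), check_canonical = FALSE))),
    "no control")
})

test_that("repeat-unit comparison separates identical, variant and random units", {
  u <- "ACGTACGTACGTACGTACGT"
  same <- compare_repeat_units(c(u, u, u))
  expect_equal(unname(same$identity[upper.tri(same$identity)]), rep(1, 3))
  expect_true(same$alignable)
  expect_error(compare_repeat_units("ACGT"), "at least two")
  # random 60-mers: identity near background, not alignable
  set.seed(73)
  ids <- replicate(30, {
    compare_repeat_units(c(random_dna(60), random_dna(60)))$mean_identity
  })
  expect_lt(mean(ids), 0.5)
  expect_gt(mean(ids), 0.2)
  expect_false(compare_repeat_units(c(random_dna(60), random_dna(60)))$alignable)
  # planted variants: high identity, reflecting the planted divergence
  set.seed(74)
  base <- random_dna(40)
  variants <- vapply(1:4, function(i) {
    ch <- strsplit(base, "")[[1]]
    at <- sample(40, 3)
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                     character(1))
    paste(ch, collapse = "")
  }, character(1))
  cmp <- compare_repeat_units(variants)
  off <- cmp$identity[upper.tri(cmp$identity)]
  expect_true(all(off >= 0.8))
  expect_true(cmp$alignable)
})
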