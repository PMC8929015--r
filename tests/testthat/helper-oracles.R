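# Independent oracles and fixture builders shared by the test files.

# --- NG86 site-count oracle ------------------------------------------------
# Enumerates the 9 single-nucleotide mutations of a codon and classifies
# them by translating through Biostrings, independently of the package's
# cached lookup tables. S = 3 * syn / (9 - mutations-to-stop).
oracle_ng86_sites <- function(codon) {
  gc5 <- Biostrings::getGeneticCode("5")
  tr <- function(c) as.character(Biostrings::translate(
    Biostrings::DNAString(c), genetic.code = gc5, no.init.codon = TRUE))
  bases <- c("A", "C", "G", "T")
  aa0 <- tr(codon)
  syn <- 0L
  stops <- 0L
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      aa <- tr(mut)
      if (aa == "*") stops <- stops + 1L
      else if (aa == aa0) syn <- syn + 1L
    }
  }
  S <- 3 * syn / (9 - stops)
  c(S = S, N = 3 - S)
}

# --- signed circular adjacency oracle --------------------------------------
oracle_adjacencies <- function(ord) {
  n <- nrow(ord)
  flip <- function(s) ifelse(s == "+", "-", "+")
  out <- character(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    fwd <- sprintf("%s[%s]->%s[%s]", ord$name[i], ord$orient[i],
                   ord$name[j], ord$orient[j])
    rev <- sprintf("%s[%s]->%s[%s]", ord$name[j], flip(ord$orient[j]),
                   ord$name[i], flip(ord$orient[i]))
    out[i] <- if (fwd < rev) fwd else rev
  }
  out
}

oracle_breakpoint <- function(a, b) {
  length(setdiff(oracle_adjacencies(a$order), oracle_adjacencies(b$order)))
}

random_signed_order <- function(labels) {
  ord <- data.frame(name = sample(labels),
                    orient = sample(c("+", "-"), length(labels), replace = TRUE),
                    stringsAsFactors = FALSE)
  mitocomp:::canonicalize_order(ord)
}

# --- tandem-repeat oracle --------------------------------------------------
# Naive reimplementation of the documented detection rule: exact-run seeds
# of at least one unit, whole-unit block extension at >= min_identity, then
# exact-match tail extension and end trimming; candidate resolution by
# (span, identity, smaller unit).
oracle_tandem <- function(s, min_unit = 10, max_unit = 200, min_copies = 2,
                          min_identity = 0.85, exclude_homopolymer = TRUE) {
  ch <- strsplit(toupper(s), "")[[1]]
  n <- length(ch)
  cands <- list()
  for (p in min_unit:min(max_unit, n %/% 2)) {
    m <- logical(n - p)
    for (j in seq_len(n - p)) m[j] <- ch[j + p] == ch[j]
    seen <- logical(length(m))
    j <- 1L
    while (j <= length(m)) {
      if (!m[j]) { j <- j + 1L; next }
      k <- j
      while (k < length(m) && m[k + 1L]) k <- k + 1L
      if (k - j + 1L >= p && !seen[j]) {
        A <- j; B <- k
        while (B + p <= length(m) && mean(m[(B + 1L):(B + p)]) >= min_identity) B <- B + p
        while (B < length(m) && m[B + 1L]) B <- B + 1L
        while (A - p >= 1L && mean(m[(A - p):(A - 1L)]) >= min_identity) A <- A - p
        while (A > 1L && m[A - 1L]) A <- A - 1L
        while (B > A && !m[B]) B <- B - 1L
        while (A < B && !m[A]) A <- A + 1L
        seen[A:B] <- TRUE
        span <- B + p - A + 1L
        idv <- mean(m[A:B])
        if (span >= p * min_copies && idv >= min_identity) {
          cands[[length(cands) + 1L]] <- data.frame(
            start = A, end = B + p, unit_length = p, span = span,
            identity = idv)
        }
      }
      j <- k + 1L
    }
  }
  if (!length(cands)) {
    return(data.frame(start = integer(), end = integer(),
                      unit_length = integer()))
  }
  cd <- do.call(rbind, cands)
  cd <- cd[order(-cd$span, -cd$identity, cd$unit_length), , drop = FALSE]
  keep <- logical(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    ok <- TRUE
    for (j2 in which(keep)) {
      if (cd$start[i] <= cd$end[j2] && cd$end[i] >= cd$start[j2]) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  cd <- cd[keep, , drop = FALSE]
  if (exclude_homopolymer && nrow(cd)) {
    mono <- vapply(seq_len(nrow(cd)), function(i) {
      u <- ch[cd$start[i]:min(cd$start[i] + cd$unit_length[i] - 1L, cd$end[i])]
      length(unique(u)) == 1L
    }, logical(1))
    cd <- cd[!mono, , drop = FALSE]
  }
  cd <- cd[order(cd$start), c("start", "end", "unit_length"), drop = FALSE]
  rownames(cd) <- NULL
  cd
}

# --- misc builders ---------------------------------------------------------
random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Valid rotation offsets of a record (cut points not inside any feature).
valid_offsets <- function(rec) {
  f <- rec$features
  inside <- unique(unlist(Map(function(s, e) s:(e - 1L), f$start, f$end)))
  setdiff(0:(rec$genome_length - 1L), inside)
}

# Mirror an annotation onto the reverse-complement strand.
revcomp_record <- function(rec) {
  L <- rec$genome_length
  f <- rec$features
  f2 <- f
  f2$start <- L - f$end + 1L
  f2$end <- L - f$start + 1L
  f2$strand <- ifelse(f$strand == "major", "minor", "major")
  seq2 <- if (is.null(rec$sequence)) NULL else revcomp(rec$sequence)
  suppressWarnings(mitogenome(paste0(rec$record_id, "_rc"), L, f2,
                              sequence = seq2, circular = rec$circular,
                              check_canonical = FALSE))
}

# A small all-Watson-Crick cloverleaf with canonical dimensions; callers
# mutate specific positions to plant wobbles/mismatches.
make_cloverleaf <- function(name = "trnX") {
  n <- 72L
  ch <- rep("A", n)
  pairing <- list(
    acceptor = cbind(1:7, 72:66),
    DHU = cbind(10:13, 25:22),
    anticodon = cbind(28:32, 44:40),
    TPsiC = cbind(50:54, 65:61)
  )
  for (arm in names(pairing)) {
    pr <- pairing[[arm]]
    for (k in seq_len(nrow(pr))) {
      ch[pr[k, 1]] <- "G"
      ch[pr[k, 2]] <- "C"
    }
  }
  list(sequence = paste(ch, collapse = ""), pairing = pairing,
       name = name)
}

gb_fixture_text <- function() {
  c(
    "LOCUS       SYNTEST                  400 bp    DNA     circular INV 01-JAN-2024",
    "DEFINITION  synthetic test record (constructed in the test helper).",
    "ACCESSION   SYNTEST",
    "SOURCE      synthetic",
    "  ORGANISM  Synthetica testis",
    "FEATURES             Location/Qualifiers",
    "     source          1..400",
    "     CDS             10..108",
    "                     /gene=\"nad2\"",
    "     CDS             join(110..115)",
    "                     /gene=\"atp8\"",
    "     tRNA            complement(120..185)",
    "                     /product=\"tRNA-Gln\"",
    "     rRNA            200..320",
    "                     /gene=\"s-rRNA\"",
    "     misc_feature    330..395",
    "                     /note=\"A+T-rich region\"",
    "ORIGIN",
    gb_origin_lines(),
    "//"
  )
}

gb_origin_lines <- function() {
  set.seed(404)
  s <- random_dna(400)
  starts <- seq(1, 400, by = 60)
  vapply(starts, function(i) {
    chunk <- substr(s, i, min(i + 59, 400))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", i, tolower(paste(groups, collapse = " ")))
  }, character(1))
}
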