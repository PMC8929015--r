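# Seeded generator of annotated circular mitogenomes and codon-sequence
# pairs/populations, with machine-readable truth tables. Everything other
# modules assume — circular 1-based coordinates on two strands, biased A/T
# composition with controllable skews, open reading frames under the
# invertebrate mitochondrial code, a planted junction motif, tandem-repeat
# arrays flanking a nonrepeat control-region core, and the A/B/B'/C gene
# orders — is produced here with exact planted coordinates.

# Template gene lengths (bp) for the synthetic genome. PCG lengths are
# multiples of 3 (ATP6 is 3k+1: it carries the truncated "T" stop); tRNAs
# are 65 bp except the DHU-truncated trnS1 (54) and trnV (73), so the
# shortest/longest pattern of real genomes is reproduced.
.template_lengths <- c(
  ND2 = 978L, COI = 1545L, COII = 678L, ATP8 = 156L, ATP6 = 652L,
  COIII = 783L, ND3 = 351L, ND5 = 1683L, ND4 = 1332L, ND4L = 273L,
  ND6 = 501L, CytB = 1125L, ND1 = 951L,
  lrRNA = 1226L, srRNA = 717L
)

.template_anticodons <- c(
  trnI = "GAT", trnQ = "TTG", trnM = "CAT", trnW = "TCA", trnC = "GCA",
  trnY = "GTA", trnL2 = "TAA", trnK = "CTT", trnD = "GTC", trnG = "TCC",
  trnA = "TGC", trnR = "TCG", trnN = "GTT", trnS1 = "GCT", trnE = "TTC",
  trnF = "GAA", trnH = "GTG", trnT = "TGT", trnP = "TGG", trnS2 = "TGA",
  trnL1 = "TAG", trnV = "TAC")

.default_start_codons <- c(
  ND2 = "ATT", COI = "ATC", COII = "ATA", ATP8 = "ATT", ATP6 = "ATG",
  COIII = "ATG", ND3 = "ATG", ND5 = "GTG", ND4 = "ATG", ND4L = "ATG",
  ND6 = "ATA", CytB = "ATG", ND1 = "ATG")

base_probs <- function(at, at_skew, gc_skew) {
  gc <- 1 - at
  p <- c(A = at * (1 + at_skew) / 2, C = gc * (1 - gc_skew) / 2,
         G = gc * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
  p[NUC]
}

#' Simulation configuration
#'
#' Bundles and validates every knob of [simulate_mitogenome()]. Composition
#' defaults reflect the flatid study system: whole-genome A+T 0.766, a
#' slight A-skew (0.25) and a moderate C-skew (-0.26) on the major strand;
#' the control region carries a triplicated two-part repeat whose final copy
#' lacks its second half (unit 60 bp x 2.5 copies) near the srRNA end and a
#' 21 bp x 20 array near the trnI end, with repeat units markedly less
#' A+T-rich (0.64) than the nonrepeat core (0.88).
#'
#' @param seed integer seed (mandatory; the generator is deterministic)
#' @param genome_length target genome size in bp (the control-region core is
#'   sized to meet it; the realised length is reported in the truth table)
#' @param gene_order_type "A", "B", "B'" or "C"
#' @param at_content,at_skew,gc_skew composition targets (fractions;
#'   skews dimensionless in \[-1, 1\])
#' @param minor_at_skew optional AT-skew target, on major-strand letters,
#'   for the spans of minor-strand genes (emulates the T-rich minor strand);
#'   `NULL` keeps a single genome-wide target
#' @param motif `NULL` or list(upstream, downstream, motif, mismatches,
#'   placement) with placement one of "within_spacer",
#'   "within_upstream_3prime", "within_downstream_5prime", "spanning"
#' @param repeats list of control-region arrays, each
#'   list(unit_length, copies, identity)
#' @param repeat_at,core_at A+T targets for repeat units and nonrepeat core
#' @param start_codons named overrides of PCG start codons
#' @param truncated_stop_gene PCG given a truncated "T" stop (its template
#'   length must be 1 mod 3)
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(seed,
                       genome_length = 16000L,
                       gene_order_type = c("A", "B", "B'", "C"),
                       at_content = 0.766,
                       at_skew = 0.25,
                       gc_skew = -0.26,
                       minor_at_skew = NULL,
                       motif = list(upstream = "ND1", downstream = "trnS2",
                                    motif = "TAGTA", mismatches = 0L,
                                    placement = "within_spacer"),
                       repeats = list(list(unit_length = 60L, copies = 2.5,
                                           identity = 1),
                                      list(unit_length = 21L, copies = 20,
                                           identity = 1)),
                       repeat_at = 0.64,
                       core_at = 0.88,
                       start_codons = character(0),
                       truncated_stop_gene = "ATP6") {
  if (missing(seed)) stop("seed is mandatory: the generator never runs unseeded")
  gene_order_type <- match.arg(gene_order_type)
  stopifnot(at_content > 0, at_content < 1,
            abs(at_skew) <= 1, abs(gc_skew) <= 1)
  for (tgt in list(c(at_content, at_skew, gc_skew),
                   if (!is.null(minor_at_skew)) c(at_content, minor_at_skew, gc_skew))) {
    if (is.null(tgt)) next
    p <- base_probs(tgt[1], tgt[2], tgt[3])
    if (any(p < 0) || max(p) > 0.9) {
      stop("infeasible composition target (base probabilities ",
           paste(sprintf("%s=%.3f", names(p), p), collapse = ", "), ")")
    }
  }
  if (!is.null(motif)) {
    motif$placement <- match.arg(motif$placement,
                                 c("within_spacer", "within_upstream_3prime",
                                   "within_downstream_5prime", "spanning"))
    motif$mismatches <- as.integer(motif$mismatches %||% 0L)
  }
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 gene_order_type = gene_order_type, at_content = at_content,
                 at_skew = at_skew, gc_skew = gc_skew,
                 minor_at_skew = minor_at_skew, motif = motif,
                 repeats = repeats, repeat_at = repeat_at, core_at = core_at,
                 start_codons = start_codons,
                 truncated_stop_gene = truncated_stop_gene),
            class = "sim_config")
}

# Exact-proportion sampling: a multiset with counts n*p (largest-remainder
# rounding) in random order. Composition targets are then met by
# construction, with only rounding error, while the arrangement stays
# random and seeded.
multiset_counts <- function(n, p) {
  p <- p / sum(p)
  k <- floor(n * p)
  rem <- n - sum(k)
  if (rem > 0L) {
    frac <- n * p - k
    k[order(frac, decreasing = TRUE)[seq_len(rem)]] <- k[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  k
}

sample_bases <- function(n, p) {
  if (n <= 0L) return("")
  k <- multiset_counts(n, p)
  paste(sample(rep(NUC, times = k)), collapse = "")
}

# Sense-codon sampling distribution whose expected base composition matches
# the target despite the exclusion of stop codons: per-position base
# probabilities are solved analytically from the targets, then refined by a
# short fixed deterministic calibration (no stochastic fitting).
codon_distribution <- function(p_target) {
  sense <- sense_codons5()
  mat <- do.call(rbind, strsplit(sense, ""))
  q <- p_target
  for (it in 1:12) {
    w <- q[mat[, 1]] * q[mat[, 2]] * q[mat[, 3]]
    w <- w / sum(w)
    expected <- vapply(NUC, function(b) sum(w * rowSums(mat == b)) / 3, numeric(1))
    q <- q * (p_target / pmax(expected, 1e-9))
    q <- q / sum(q)
  }
  w <- q[mat[, 1]] * q[mat[, 2]] * q[mat[, 3]]
  stats::setNames(w / sum(w), sense)
}

sample_codons <- function(n, cw) {
  if (n <= 0L) return(character(0))
  k <- multiset_counts(n, cw)
  sample(rep(names(cw), times = k))
}

make_pcg <- function(name, len, start_codon, truncated, cw,
                     final_codon = NULL) {
  if (truncated) {
    n_int <- (len - 3L - 1L) %/% 3L
    stop_part <- "T"
  } else {
    n_int <- (len - 3L - 3L) %/% 3L
    stop_part <- "TAA"
  }
  interior <- sample_codons(n_int, cw)
  if (!is.null(final_codon) && n_int >= 1L) interior[n_int] <- final_codon
  paste0(start_codon, paste(interior, collapse = ""), stop_part)
}

#' Simulate an annotated circular mitogenome
#'
#' Builds a 37-gene + control-region genome in the requested arrangement
#' type, with composition sampled to the configured targets, every PCG an
#' open reading frame under translation table 5 (one gene with a truncated
#' "T" stop), a motif planted at the configured junction, and tandem-repeat
#' arrays in the control region — all with exact coordinates recorded in the
#' truth table.
#'
#' @param cfg a [sim_config()]
#' @return list with `record` (a [mitogenome()]) and `truth` (list of planted
#'   coordinates and realised parameters)
#' @export
simulate_mitogenome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p_major <- base_probs(cfg$at_content, cfg$at_skew, cfg$gc_skew)
  cw_major <- codon_distribution(p_major)
  comp <- function(p) stats::setNames(p[c("T", "G", "C", "A")], NUC)
  p_minor_major_strand <- if (is.null(cfg$minor_at_skew)) p_major else
    base_probs(cfg$at_content, cfg$minor_at_skew, cfg$gc_skew)
  # reading-orientation distribution for minor-strand genes: the reverse
  # complement of the reading sequence is what lands on the major strand
  cw_minor <- codon_distribution(comp(p_minor_major_strand))
  p_minor_plain <- comp(p_minor_major_strand)

  ref <- reference_gene_order(cfg$gene_order_type)
  order_tab <- ref$order
  if (length(ref$duplications)) {
    # expand duplicated tRNAs into consecutive copies
    rows <- list()
    for (i in seq_len(nrow(order_tab))) {
      rows[[length(rows) + 1L]] <- order_tab[i, ]
      nm <- order_tab$name[i]
      k <- ref$duplications[nm]
      if (!is.na(k) && k > 1L) {
        for (extra in seq_len(k - 1L)) rows[[length(rows) + 1L]] <- order_tab[i, ]
      }
    }
    order_tab <- do.call(rbind, rows)
    rownames(order_tab) <- NULL
  }

  start_codons <- .default_start_codons
  if (length(cfg$start_codons)) start_codons[names(cfg$start_codons)] <- cfg$start_codons

  motif <- cfg$motif
  pieces <- character(0)
  feat_rows <- list()
  pos <- 0L
  spacer_default <- 2L
  motif_junction_spacer <- 10L
  for (i in seq_len(nrow(order_tab))) {
    nm <- order_tab$name[i]
    orient <- order_tab$orient[i]
    # spacer ahead of this feature (larger at the motif junction so every
    # placement class has room)
    sp_len <- spacer_default
    if (!is.null(motif) && i > 1L &&
        nm %in% c(motif$upstream, motif$downstream) &&
        order_tab$name[i - 1L] %in% c(motif$upstream, motif$downstream)) {
      sp_len <- motif_junction_spacer
    }
    if (i > 1L && sp_len > 0L) {
      pieces <- c(pieces, sample_bases(sp_len, p_major))
      pos <- pos + sp_len
    }
    is_minor <- orient == "-"
    if (nm %in% PCG_NAMES) {
      len <- .template_lengths[[nm]]
      truncated <- identical(nm, cfg$truncated_stop_gene)
      cw <- if (is_minor) cw_minor else cw_major
      final_codon <- NULL
      if (!is.null(motif) && identical(nm, motif$upstream) &&
          motif$placement == "within_upstream_3prime" && is_minor &&
          identical(toupper(motif$motif), "TAGTA")) {
        # reading tail ...TAC TAA reverse-complements to TTAGTA on the major
        # strand: the motif sits inside the gene's 3' end without breaking
        # the reading frame
        final_codon <- "TAC"
      }
      reading <- make_pcg(nm, len, start_codons[[nm]], truncated, cw, final_codon)
      seq_major <- if (is_minor) revcomp(reading) else reading
      stop_codon <- if (truncated) "T" else "TAA"
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        name = nm, ftype = "PCG", strand = if (is_minor) "minor" else "major",
        start = pos + 1L, end = pos + len, anticodon = NA_character_,
        start_codon = start_codons[[nm]], stop_codon = stop_codon,
        stringsAsFactors = FALSE)
      pieces <- c(pieces, seq_major)
      pos <- pos + len
    } else if (nm %in% c("srRNA", "lrRNA")) {
      len <- .template_lengths[[nm]]
      p <- if (is_minor) p_minor_plain else p_major
      s <- sample_bases(len, p)
      if (is_minor) s <- revcomp(s)
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        name = nm, ftype = "rRNA", strand = if (is_minor) "minor" else "major",
        start = pos + 1L, end = pos + len, anticodon = NA_character_,
        start_codon = NA_character_, stop_codon = NA_character_,
        stringsAsFactors = FALSE)
      pieces <- c(pieces, s)
      pos <- pos + len
    } else {
      len <- if (nm == "trnS1") 54L else if (nm == "trnV") 73L else 65L
      p <- if (is_minor) p_minor_plain else p_major
      s <- sample_bases(len, p)
      if (is_minor) s <- revcomp(s)
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        name = nm, ftype = "tRNA", strand = if (is_minor) "minor" else "major",
        start = pos + 1L, end = pos + len,
        anticodon = .template_anticodons[[nm]] %||% NA_character_,
        start_codon = NA_character_, stop_codon = NA_character_,
        stringsAsFactors = FALSE)
      pieces <- c(pieces, s)
      pos <- pos + len
    }
  }

  # --- control region ------------------------------------------------------
  p_repeat <- base_probs(cfg$repeat_at, cfg$at_skew, cfg$gc_skew)
  p_core <- base_probs(cfg$core_at, cfg$at_skew, cfg$gc_skew)
  build_array <- function(spec) {
    unit <- sample_bases(spec$unit_length, p_repeat)
    identity <- spec$identity %||% 1
    full <- floor(spec$copies)
    frac_len <- round((spec$copies - full) * spec$unit_length)
    copies <- character(full)
    for (k in seq_len(full)) {
      u <- unit
      if (identity < 1 && k > 1L) {
        ch <- seq_chars(u)
        nmut <- stats::rbinom(1L, length(ch), 1 - identity)
        if (nmut > 0L) {
          at <- sample(length(ch), nmut)
          ch[at] <- vapply(ch[at], function(b) sample(setdiff(NUC, b), 1L),
                           character(1))
        }
        u <- paste(ch, collapse = "")
      }
      copies[k] <- u
    }
    s <- paste(copies, collapse = "")
    if (frac_len > 0L) s <- paste0(s, substr(unit, 1L, frac_len))
    list(seq = s, unit = unit)
  }
  arrays <- lapply(cfg$repeats, build_array)
  array_lens <- vapply(arrays, function(a) nchar(a$seq), integer(1))
  tail_len <- 40L
  fixed <- pos + sum(array_lens) + tail_len
  core_len <- max(cfg$genome_length - fixed, 150L)
  polyA <- strrep("A", 23L)
  polyT <- strrep("T", 10L)
  polyAT <- strrep("AT", 6L)
  core_fill <- core_len - nchar(polyA) - nchar(polyT) - nchar(polyAT)
  if (core_fill < 30L) stop("genome_length target too small for the control region")
  thirds <- c(core_fill %/% 3L, core_fill %/% 3L,
              core_fill - 2L * (core_fill %/% 3L))
  core <- paste0(sample_bases(thirds[1], p_core), polyA,
                 sample_bases(thirds[2], p_core), polyT,
                 sample_bases(thirds[3], p_core), polyAT)
  tail_seq <- paste0(sample_bases(tail_len - 10L, p_core), strrep("A", 10L))
  n_arr <- length(arrays)
  ctrl_parts <- character(0)
  truth_repeats <- list()
  local_pos <- 0L
  for (k in seq_len(n_arr)) {
    if (k == n_arr && n_arr > 1L) {
      ctrl_parts <- c(ctrl_parts, core)
      local_pos <- local_pos + nchar(core)
    }
    ctrl_parts <- c(ctrl_parts, arrays[[k]]$seq)
    truth_repeats[[k]] <- data.frame(
      start = local_pos + 1L, end = local_pos + array_lens[k],
      unit_length = cfg$repeats[[k]]$unit_length,
      copies = cfg$repeats[[k]]$copies,
      unit = arrays[[k]]$unit, stringsAsFactors = FALSE)
    local_pos <- local_pos + array_lens[k]
  }
  if (n_arr <= 1L) {
    ctrl_parts <- c(ctrl_parts, core)
    local_pos <- local_pos + nchar(core)
  }
  ctrl_parts <- c(ctrl_parts, tail_seq)
  ctrl_seq <- paste(ctrl_parts, collapse = "")
  feat_rows[[length(feat_rows) + 1L]] <- data.frame(
    name = "AT_rich", ftype = "control", strand = "major",
    start = pos + 1L, end = pos + nchar(ctrl_seq), anticodon = NA_character_,
    start_codon = NA_character_, stop_codon = NA_character_,
    stringsAsFactors = FALSE)
  ctrl_start <- pos + 1L
  pos <- pos + nchar(ctrl_seq)

  genome <- paste(pieces, collapse = "")
  genome <- paste0(genome, ctrl_seq)
  features <- do.call(rbind, feat_rows)

  # --- motif planting ------------------------------------------------------
  truth_motif <- NULL
  if (!is.null(motif)) {
    up <- features[features$name == motif$upstream, ][1, ]
    dn <- features[features$name == motif$downstream, ][1, ]
    left <- if (up$start <= dn$start) up else dn
    right <- if (up$start <= dn$start) dn else up
    m <- toupper(motif$motif)
    mlen <- nchar(m)
    planted <- m
    if (motif$mismatches > 0L) {
      ch <- seq_chars(planted)
      at <- sample(mlen, motif$mismatches)
      ch[at] <- vapply(ch[at], function(b) sample(setdiff(NUC, b), 1L),
                       character(1))
      planted <- paste(ch, collapse = "")
    }
    place_at <- switch(motif$placement,
      within_spacer = left$end + ((right$start - left$end - 1L - mlen) %/% 2L) + 1L,
      within_upstream_3prime = NA_integer_,  # handled during PCG build
      within_downstream_5prime = {
        # inside the named downstream feature, at its junction-facing end
        if (dn$start == right$start) dn$start else dn$end - mlen + 1L
      },
      spanning = left$end - 2L)
    if (motif$placement == "within_upstream_3prime") {
      # the codon trick placed revcomp(motif) at the reading tail of the
      # upstream gene; locate it on the major strand
      hit_start <- if (up$strand == "minor") up$start + 1L else up$end - mlen
      truth_pos <- hit_start
      planted <- substr(genome, truth_pos, truth_pos + mlen - 1L)
      if (!identical(planted, m)) {
        stop("internal error: in-frame motif planting failed (",
             planted, " != ", m, ")")
      }
    } else {
      substr(genome, place_at, place_at + mlen - 1L) <- planted
      truth_pos <- place_at
    }
    truth_motif <- list(position = truth_pos, strand = "+",
                        mismatches = motif$mismatches,
                        placement = motif$placement, sequence = planted)
  }

  rec <- mitogenome(record_id = sprintf("sim_%s_%d", cfg$gene_order_type, cfg$seed),
                    organism = "synthetic flatid-like mitogenome",
                    genome_length = nchar(genome), features = features,
                    sequence = genome, circular = TRUE)
  truth <- list(config = unclass(cfg),
                genome_length = nchar(genome),
                gene_order_type = cfg$gene_order_type,
                control_region = list(start = ctrl_start, end = nchar(genome)),
                repeats = do.call(rbind, truth_repeats),
                motif = truth_motif,
                features = features)
  list(record = rec, truth = truth)
}

#' Write / read a simulation truth table as JSON
#'
#' @param truth the truth list from [simulate_mitogenome()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Simulate a pair of coding sequences at a given dN/dS
#'
#' The ancestor is sampled uniformly from sense codons; the descendant is
#' evolved by single-nucleotide proposals accepted with probability 1 when
#' synonymous and `omega` when nonsynonymous; proposals creating stop codons
#' are rejected. Realised synonymous/nonsynonymous substitution counts are
#' returned as truth.
#'
#' @param length_codons number of codons (>= 50 recommended)
#' @param omega nonsynonymous relative acceptance probability (dN/dS)
#' @param t expected number of proposals per nucleotide site
#' @param seed integer seed
#' @return list(cds1, cds2, syn_events, nonsyn_events, proposals)
#' @export
simulate_cds_pair <- function(length_codons, omega, t, seed) {
  stopifnot(length_codons >= 1L, omega >= 0, t >= 0)
  set.seed(seed)
  sense <- sense_codons5()
  stops <- stop_codons5()
  gc5 <- genetic_code5()
  anc <- sample(sense, length_codons, replace = TRUE)
  der <- anc
  L <- 3L * length_codons
  n_events <- stats::rpois(1L, t * L)
  syn <- 0L; nonsyn <- 0L
  for (e in seq_len(n_events)) {
    site <- sample.int(L, 1L)
    ci <- (site - 1L) %/% 3L + 1L
    within <- (site - 1L) %% 3L + 1L
    cod <- seq_chars(der[ci])
    newb <- sample(setdiff(NUC, cod[within]), 1L)
    cod2 <- cod
    cod2[within] <- newb
    cand <- paste(cod2, collapse = "")
    if (cand %in% stops) next
    if (gc5[[der[ci]]] == gc5[[cand]]) {
      der[ci] <- cand
      syn <- syn + 1L
    } else if (stats::runif(1L) < omega) {
      der[ci] <- cand
      nonsyn <- nonsyn + 1L
    }
  }
  list(cds1 = paste(anc, collapse = ""), cds2 = paste(der, collapse = ""),
       syn_events = syn, nonsyn_events = nonsyn, proposals = n_events)
}

#' Simulate a conspecific population from a base record
#'
#' Each of `n` copies receives independent per-gene substitutions: within
#' each named gene span, every site mutates with the gene's per-site
#' probability (substitution to a uniformly random different base, applied
#' on the major strand).
#'
#' @param base a [mitogenome()] record with sequence
#' @param per_gene_mut_rates named numeric vector of per-site rates in
#'   \[0, 1\]
#' @param n number of individuals
#' @param seed integer seed
#' @return list with `records` (list of n records) and `truth` (data.frame
#'   record/gene/substitutions)
#' @export
simulate_population <- function(base, per_gene_mut_rates, n, seed) {
  if (is.null(base$sequence)) stop("base record has no sequence")
  stopifnot(all(per_gene_mut_rates >= 0), n >= 1L)
  set.seed(seed)
  missing <- setdiff(names(per_gene_mut_rates), base$features$name)
  if (length(missing)) stop("rate given for unknown gene(s): ",
                            paste(missing, collapse = ", "))
  truth <- list()
  records <- vector("list", n)
  for (k in seq_len(n)) {
    ch <- seq_chars(base$sequence)
    for (g in names(per_gene_mut_rates)) {
      f <- base$features[base$features$name == g, ][1, ]
      span <- f$start:f$end
      hit <- span[stats::runif(length(span)) < per_gene_mut_rates[[g]]]
      for (i in hit) ch[i] <- sample(setdiff(NUC, ch[i]), 1L)
      truth[[length(truth) + 1L]] <- data.frame(
        record = paste0(base$record_id, "_ind", k), gene = g,
        substitutions = length(hit), stringsAsFactors = FALSE)
    }
    records[[k]] <- suppressWarnings(mitogenome(
      record_id = paste0(base$record_id, "_ind", k),
      organism = base$organism, genome_length = base$genome_length,
      features = base$features, sequence = paste(ch, collapse = ""),
      circular = base$circular, check_canonical = FALSE))
  }
  list(records = records, truth = do.call(rbind, truth))
}

#' Write / read a simulation config as a flat key=value file
#'
#' Only scalar fields are serialised; the motif and repeat specs use dotted
#' keys (`motif.placement=...`, `repeat1.unit_length=...`).
#'
#' @param cfg a [sim_config()]
#' @param path file path
#' @return `path` invisibly / a [sim_config()]
#' @export
write_sim_config <- function(cfg, path) {
  kv <- c(seed = cfg$seed, genome_length = cfg$genome_length,
          gene_order_type = cfg$gene_order_type,
          at_content = cfg$at_content, at_skew = cfg$at_skew,
          gc_skew = cfg$gc_skew, repeat_at = cfg$repeat_at,
          core_at = cfg$core_at,
          truncated_stop_gene = cfg$truncated_stop_gene)
  if (!is.null(cfg$minor_at_skew)) kv["minor_at_skew"] <- cfg$minor_at_skew
  if (!is.null(cfg$motif)) {
    kv["motif.upstream"] <- cfg$motif$upstream
    kv["motif.downstream"] <- cfg$motif$downstream
    kv["motif.motif"] <- cfg$motif$motif
    kv["motif.mismatches"] <- cfg$motif$mismatches
    kv["motif.placement"] <- cfg$motif$placement
  }
  for (k in seq_along(cfg$repeats)) {
    kv[sprintf("repeat%d.unit_length", k)] <- cfg$repeats[[k]]$unit_length
    kv[sprintf("repeat%d.copies", k)] <- cfg$repeats[[k]]$copies
    kv[sprintf("repeat%d.identity", k)] <- cfg$repeats[[k]]$identity %||% 1
  }
  writeLines(paste0(names(kv), "=", kv), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  num <- function(k, default = NULL) {
    if (k %in% names(vals)) as.numeric(vals[[k]]) else default
  }
  motif <- NULL
  if ("motif.motif" %in% names(vals)) {
    motif <- list(upstream = vals[["motif.upstream"]],
                  downstream = vals[["motif.downstream"]],
                  motif = vals[["motif.motif"]],
                  mismatches = as.integer(num("motif.mismatches", 0)),
                  placement = vals[["motif.placement"]])
  }
  reps <- list()
  k <- 1L
  while (sprintf("repeat%d.unit_length", k) %in% names(vals)) {
    reps[[k]] <- list(unit_length = as.integer(num(sprintf("repeat%d.unit_length", k))),
                      copies = num(sprintf("repeat%d.copies", k)),
                      identity = num(sprintf("repeat%d.identity", k), 1))
    k <- k + 1L
  }
  sim_config(seed = as.integer(num("seed")),
             genome_length = as.integer(num("genome_length", 16000)),
             gene_order_type = vals[["gene_order_type"]] %||% "A",
             at_content = num("at_content", 0.766),
             at_skew = num("at_skew", 0.25),
             gc_skew = num("gc_skew", -0.26),
             minor_at_skew = num("minor_at_skew", NULL),
             motif = motif,
             repeats = if (length(reps)) reps else
               list(list(unit_length = 60L, copies = 2.5, identity = 1),
                    list(unit_length = 21L, copies = 20, identity = 1)),
             repeat_at = num("repeat_at", 0.64),
             core_at = num("core_at", 0.88),
             truncated_stop_gene = vals[["truncated_stop_gene"]] %||% "ATP6")
}
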