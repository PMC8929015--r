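# Nucleotide composition, AT/GC skew, codon usage and start/stop codons.
#
# Skew conventions: AT skew = (A - T)/(A + T), GC skew = (G - C)/(G + C),
# always computed from major-strand letters; a gene set encoded on the minor
# strand is deliberately NOT reverse-complemented, so the strong T-skew of
# minor-strand coding regions is visible as such. N bases are excluded from
# all denominators.

base_counts <- function(seq) {
  ch <- seq_chars(toupper(seq))
  c(A = sum(ch == "A"), C = sum(ch == "C"), G = sum(ch == "G"), T = sum(ch == "T"))
}

#' Base composition as percentages
#'
#' @param seq nucleotide string
#' @return named numeric vector (A, C, G, T) of percentages over non-N
#'   positions, with an `AT` attribute giving A% + T%
#' @export
#' @examples
#' base_content("ACGT")
base_content <- function(seq) {
  if (!is_nonempty_string(seq)) stop("sequence must be a non-empty string")
  n <- base_counts(seq)
  tot <- sum(n)
  if (tot == 0L) stop("sequence has no unambiguous A/C/G/T positions")
  pct <- 100 * n / tot
  attr(pct, "AT") <- unname(pct["A"] + pct["T"])
  pct
}

#' AT and GC skew of a sequence
#'
#' @param seq nucleotide string
#' @return list of class `skew_pair` with elements `at_skew` and `gc_skew`;
#'   a component is `NA` when its denominator (A+T or G+C) is zero
#' @export
#' @examples
#' skew("AAAT")  # at_skew (3-1)/4 = 0.5
skew <- function(seq) {
  if (!is_nonempty_string(seq)) stop("sequence must be a non-empty string")
  n <- base_counts(seq)
  at <- if (n["A"] + n["T"] > 0) unname((n["A"] - n["T"]) / (n["A"] + n["T"])) else NA_real_
  gc <- if (n["G"] + n["C"] > 0) unname((n["G"] - n["C"]) / (n["G"] + n["C"])) else NA_real_
  structure(list(at_skew = at, gc_skew = gc), class = "skew_pair")
}

#' @export
print.skew_pair <- function(x, ...) {
  cat(sprintf("AT skew: %s   GC skew: %s\n",
              format(x$at_skew, digits = 4), format(x$gc_skew, digits = 4)))
  invisible(x)
}

basis_gene_set <- function(rec, basis) {
  switch(basis,
         whole_genome = NULL,
         all_PCG = PCG_NAMES,
         major_PCG = MAJOR_PCGS,
         minor_PCG = MINOR_PCGS,
         stop("unknown basis '", basis, "'"))
}

#' Skew of a named gene set, read off the major strand
#'
#' Concatenates the basis genes in genome order as they lie on the major
#' strand (no reverse complementing) and applies [skew()]. This is the
#' statistic used to contrast the A-skew of major-strand coding sequence with
#' the pronounced T-skew of minor-strand coding sequence.
#'
#' @param rec a [mitogenome()] record with sequence
#' @param basis one of "whole_genome", "all_PCG", "major_PCG", "minor_PCG"
#' @return a `skew_pair`
#' @export
strand_set_skew <- function(rec, basis = c("whole_genome", "all_PCG",
                                           "major_PCG", "minor_PCG")) {
  basis <- match.arg(basis)
  if (is.null(rec$sequence)) stop("record ", rec$record_id, " has no sequence")
  genes <- basis_gene_set(rec, basis)
  if (is.null(genes)) {
    s <- skew(rec$sequence)
  } else {
    missing <- setdiff(genes, rec$features$name)
    if (length(missing)) {
      stop("basis '", basis, "' gene(s) missing from record ",
           rec$record_id, ": ", paste(missing, collapse = ", "))
    }
    f <- rec$features[rec$features$name %in% genes, ]
    f <- f[order(f$start), ]
    s <- skew(paste(substring(rec$sequence, f$start, f$end), collapse = ""))
  }
  s$basis <- basis
  s
}

# Complete codons of one PCG in reading orientation, applying the counting
# convention: a trailing remainder (truncated stop, 1-2 nt) is dropped; a
# complete terminal stop codon (TAA/TAG under table 5) is excluded.
pcg_codons <- function(cds, stop_codon = NA_character_) {
  r <- nchar(cds) %% 3L
  if (r > 0L) {
    truncated_ok <- !is.na(stop_codon) && nchar(stop_codon) %in% c(1L, 2L)
    if (!truncated_ok) {
      warning("coding sequence length not a multiple of 3; trailing ",
              r, " nt dropped", call. = FALSE)
    }
    cds <- substr(cds, 1L, nchar(cds) - r)
  }
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character(0))
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  if (codons[n] %in% stop_codons5()) codons <- codons[-n]
  codons
}

#' Expected codon total from coordinates alone
#'
#' The number of codons [codon_usage()] will count, derivable from the
#' annotation without sequence: per PCG, the number of complete codons minus
#' one when the annotated stop codon is a complete triplet (a truncated
#' "T"/"TA" stop contributes nothing and its remainder is dropped).
#'
#' @param rec a [mitogenome()] record
#' @return integer codon count
#' @export
expected_codon_total <- function(rec) {
  f <- rec$features[rec$features$ftype == "PCG", ]
  len <- f$end - f$start + 1L
  complete_stop <- !is.na(f$stop_codon) & nchar(f$stop_codon) == 3L
  sum(len %/% 3L - as.integer(complete_stop))
}

#' Codon usage over all protein-coding genes
#'
#' Each PCG is extracted in reading orientation; internal complete codons are
#' counted, complete terminal stop codons are excluded, and truncated
#' terminal codons are discarded. The invertebrate mitochondrial code
#' (translation table 5) supplies the amino-acid column of the table.
#'
#' @param rec a [mitogenome()] record with sequence and annotated PCGs
#' @return object of class `codon_usage`: list with `counts` (named length-64
#'   integer), `total_codons`, and `frequencies` (percentages)
#' @export
codon_usage <- function(rec) {
  if (is.null(rec$sequence)) stop("record ", rec$record_id, " has no sequence")
  f <- rec$features[rec$features$ftype == "PCG", ]
  if (!nrow(f)) stop("record ", rec$record_id, " has no annotated PCGs")
  all_codons <- sort(names(genetic_code5()))
  counts <- stats::setNames(integer(64L), all_codons)
  for (i in seq_len(nrow(f))) {
    cds <- extract_gene_sequence(rec, f$name[i])
    cc <- pcg_codons(cds, f$stop_codon[i])
    cc <- cc[!grepl("[^ACGT]", cc)]
    tab <- table(cc)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  total <- sum(counts)
  freq <- if (total > 0L) 100 * counts / total else counts * 0
  structure(list(counts = counts, total_codons = total, frequencies = freq),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, n = 8L, ...) {
  cat("<codon_usage> total codons:", x$total_codons, "\n")
  top <- sort(x$frequencies, decreasing = TRUE)[seq_len(min(n, 64L))]
  aa <- translate_codon5(names(top))
  cat("  top codons:\n")
  for (i in seq_along(top)) {
    cat(sprintf("    %s (%s)  %6d  %5.2f%%\n", names(top)[i], aa[i],
                x$counts[names(top)[i]], top[i]))
  }
  invisible(x)
}

#' Codon usage as a data frame
#'
#' @param x a `codon_usage` object
#' @param ... unused
#' @return data.frame (codon, amino_acid, count, frequency)
#' @export
as.data.frame.codon_usage <- function(x, ...) {
  data.frame(codon = names(x$counts),
             amino_acid = translate_codon5(names(x$counts)),
             count = as.integer(x$counts),
             frequency = as.numeric(x$frequencies),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Observed start and stop codons of every PCG
#'
#' Reports the first triplet and the terminal codon (the annotated truncated
#' "T"/"TA" remainder when the gene length is not a multiple of 3), and flags
#' starts that are neither ATN nor GTG (e.g. the unconventional CTG).
#'
#' @param rec a [mitogenome()] record with sequence
#' @return data.frame (gene, start_codon, stop_codon, canonical_start)
#' @export
start_stop_table <- function(rec) {
  if (is.null(rec$sequence)) stop("record ", rec$record_id, " has no sequence")
  f <- rec$features[rec$features$ftype == "PCG", ]
  out <- lapply(seq_len(nrow(f)), function(i) {
    cds <- extract_gene_sequence(rec, f$name[i])
    if (nchar(cds) < 6L) stop("PCG ", f$name[i], " is shorter than 6 nt")
    start <- substr(cds, 1L, 3L)
    r <- nchar(cds) %% 3L
    stopc <- if (r > 0L) substr(cds, nchar(cds) - r + 1L, nchar(cds))
             else substr(cds, nchar(cds) - 2L, nchar(cds))
    data.frame(gene = f$name[i], start_codon = start, stop_codon = stopc,
               canonical_start = grepl("^AT[ACGT]$|^GTG$", start),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-gene composition report
#'
#' One row per feature with length, base percentages, A+T content and both
#' skews, computed from the major-strand letters of each span.
#'
#' @param rec a [mitogenome()] record with sequence
#' @return data.frame (gene, ftype, strand, length, A, C, G, T, AT, at_skew,
#'   gc_skew)
#' @export
composition_report <- function(rec) {
  if (is.null(rec$sequence)) stop("record ", rec$record_id, " has no sequence")
  f <- rec$features
  rows <- lapply(seq_len(nrow(f)), function(i) {
    s <- substr(rec$sequence, f$start[i], f$end[i])
    bc <- base_content(s)
    sk <- skew(s)
    data.frame(gene = f$name[i], ftype = f$ftype[i], strand = f$strand[i],
               length = nchar(s),
               A = unname(bc["A"]), C = unname(bc["C"]),
               G = unname(bc["G"]), T = unname(bc["T"]),
               AT = attr(bc, "AT"),
               at_skew = sk$at_skew, gc_skew = sk$gc_skew,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
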